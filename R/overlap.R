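#' Overlap indices between two VOI masks
#'
#' Computes the five volume-overlap indices for a (baseline, recurrence)
#' mask pair sharing one grid: Dice \code{2|A^R|/(|A|+|R|)}, Jaccard
#' \code{|A^R|/|AuR|}, overlap fraction \code{|A^R|/min(|A|,|R|)}, and the
#' two directed fractions \code{|A^R|/|A|} and \code{|A^R|/|R|}. All five
#' are 0 for disjoint masks and 1 for identical masks. A ratio whose
#' denominator is an empty mask is defined as 0, with a warning.
#'
#' @param maskA,maskR \linkS4class{VoiMask}s on the same grid; at least one
#'   must be non-empty.
#' @param caseId,method,positionGroup provenance columns copied into the
#'   result (optional).
#' @return A one-row data frame with columns \code{case_id},
#'   \code{position_group}, \code{method}, \code{a_label}, \code{r_label},
#'   the five indices (\code{dice}, \code{jaccard}, \code{of},
#'   \code{common_over_a}, \code{common_over_r}) and the component volumes
#'   \code{vol_a_cc}, \code{vol_r_cc}, \code{vol_common_cc}.
#' @examples
#' g <- volumeGeometry(c(4L, 4L, 4L), c(1, 1, 1))
#' a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE
#' computeOverlap(voiMask(a, g, "A_40"), voiMask(a, g, "R_40"))
#' @export
computeOverlap <- function(maskA, maskR, caseId = NA_character_,
                           method = NA_character_,
                           positionGroup = NA_character_) {
    stopifnot(is(maskA, "VoiMask"), is(maskR, "VoiMask"))
    if (!geometriesMatch(maskA, maskR))
        stop("masks are not on the same grid")
    nA <- sum(maskA@mask)
    nR <- sum(maskR@mask)
    if (nA == 0L && nR == 0L)
        stop("both masks are empty; overlap is undefined")
    nC <- sum(maskA@mask & maskR@mask)
    ratio <- function(num, den, what) {
        if (den == 0L) {
            warning("empty denominator for ", what, "; index defined as 0")
            0
        } else num / den
    }
    dice <- 2 * nC / (nA + nR)
    jaccard <- nC / (nA + nR - nC)
    commonOverA <- ratio(nC, nA, "common volume / baseline volume")
    commonOverR <- ratio(nC, nR, "common volume / recurrence volume")
    of <- ratio(nC, min(nA, nR), "overlap fraction")
    vcc <- .voxelVolumeCc(maskA@geometry)
    data.frame(case_id = caseId, position_group = positionGroup,
               method = method, a_label = maskA@label, r_label = maskR@label,
               dice = dice, jaccard = jaccard, of = of,
               common_over_a = commonOverA, common_over_r = commonOverR,
               vol_a_cc = nA * vcc, vol_r_cc = nR * vcc,
               vol_common_cc = nC * vcc, stringsAsFactors = FALSE)
}

#' All pairwise overlaps of one case under one registration method
#'
#' One row per (baseline threshold, recurrence threshold) pair. With the
#' default 7 baseline and 2 recurrence thresholds this is 14 rows, i.e.
#' 70 index values; across both registration methods, 140 per case.
#'
#' @param aMasks named list of baseline \linkS4class{VoiMask}s, already
#'   mapped into the comparison grid of the given method.
#' @param rMasks named list of recurrence \linkS4class{VoiMask}s on the same
#'   grid.
#' @param method \code{"RR"} or \code{"ER"}.
#' @param caseId,positionGroup provenance columns.
#' @return A data frame with one row per (A, R) pair (see
#'   \code{\link{computeOverlap}} for columns).
#' @export
overlapMatrix <- function(aMasks, rMasks, method, caseId = NA_character_,
                          positionGroup = NA_character_) {
    rows <- list()
    for (a in aMasks)
        for (r in rMasks)
            rows[[length(rows) + 1L]] <-
                computeOverlap(a, r, caseId = caseId, method = method,
                               positionGroup = positionGroup)
    do.call(rbind, rows)
}

.agreementLevels <- c("poor", "fair", "moderate", "good", "very good")

#' Qualitative agreement band of an overlap value
#'
#' Bands an index value in [0,1] into poor / fair / moderate / good /
#' very good agreement. Published band edges are stated to two decimals
#' (0-0.20, 0.21-0.40, 0.41-0.60, 0.61-0.80, 0.81-1.00); continuous values
#' are banded with half-open intervals at 0.205, 0.405, 0.605 and 0.805 so
#' that values agree with the printed bands after rounding to two decimals.
#'
#' @param value numeric vector of index values in [0,1].
#' @return A factor with levels poor < fair < moderate < good < very good.
#' @examples
#' classifyAgreement(c(0, 0.38, 0.64, 1))
#' @export
classifyAgreement <- function(value) {
    if (any(!is.finite(value)) || any(value < 0 | value > 1))
        stop("agreement values must lie in [0, 1]")
    cut(value, breaks = c(-Inf, 0.205, 0.405, 0.605, 0.805, Inf),
        labels = .agreementLevels, right = FALSE, ordered_result = TRUE)
}
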