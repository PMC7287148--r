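## Subgroup aggregation (NTP-RR, NTP-ER, TP-RR, TP-ER) and the study's
## nonparametric comparisons: Wilcoxon signed-rank for paired within-case
## contrasts (ER vs RR), Mann-Whitney U for independent groups (TP vs NTP,
## relapse vs controlled uptake). p-values are reported raw, without
## multiple-testing correction, at the conventional 0.05 level; the number
## of tests performed is returned alongside.

.checkSubgroupLabels <- function(results) {
    badPos <- setdiff(unique(results$position_group), c("TP", "NTP"))
    if (length(badPos))
        stop("unknown position group label(s): ", paste(badPos, collapse = ", "))
    badMet <- setdiff(unique(results$method), c("RR", "ER"))
    if (length(badMet))
        stop("unknown method label(s): ", paste(badMet, collapse = ", "))
}

## Exact Wilcoxon / Mann-Whitney for small samples without ties, normal
## approximation with continuity and tie correction otherwise.
.wilcoxP <- function(x, y = NULL, paired = FALSE) {
    if (paired) {
        d <- x - y
        d <- d[d != 0]
        if (!length(d))
            return(list(statistic = 0, p = 1, n = 0L))
        exact <- length(d) <= 25L && !anyDuplicated(abs(d))
        wt <- wilcox.test(d, exact = exact, correct = TRUE)
        list(statistic = unname(wt$statistic), p = wt$p.value,
             n = length(d))
    } else {
        if (identical(sort(x), sort(y)) ||
            (length(unique(c(x, y))) == 1L))
            return(list(statistic = length(x) * length(y) / 2, p = 1,
                        n = length(x) + length(y)))
        exact <- length(x) <= 25L && length(y) <= 25L &&
            !anyDuplicated(c(x, y))
        wt <- wilcox.test(x, y, exact = exact, correct = TRUE)
        list(statistic = unname(wt$statistic), p = wt$p.value,
             n = length(x) + length(y))
    }
}

#' Subgroup summaries of overlap indices
#'
#' Aggregates per-case overlap results into the four position/method
#' subgroups (NTP-RR, NTP-ER, TP-RR, TP-ER under defaults): mean, SD and n
#' of every index in every (baseline threshold, recurrence threshold) cell,
#' with the agreement band of the mean.
#'
#' @param results data frame of overlap rows (concatenated
#'   \code{\link{overlapMatrix}} output across cases).
#' @return A long-format data frame: \code{subgroup},
#'   \code{position_group}, \code{method}, \code{a_label}, \code{r_label},
#'   \code{index}, \code{mean}, \code{sd} (NA for a single case), \code{n},
#'   \code{band}.
#' @export
summarizeSubgroups <- function(results) {
    if (!is.data.frame(results) || nrow(results) == 0L)
        stop("results must be a non-empty data frame")
    .checkSubgroupLabels(results)
    long <- do.call(rbind, lapply(.overlapIndexCols, function(ix) {
        data.frame(position_group = results$position_group,
                   method = results$method, a_label = results$a_label,
                   r_label = results$r_label, index = ix,
                   value = results[[ix]], stringsAsFactors = FALSE)
    }))
    agg <- aggregate(value ~ position_group + method + a_label + r_label + index,
                     data = long, FUN = function(v)
                         c(mean = mean(v), sd = if (length(v) > 1L) sd(v) else NA_real_,
                           n = length(v)))
    out <- data.frame(subgroup = paste(agg$position_group, agg$method, sep = "-"),
                      position_group = agg$position_group, method = agg$method,
                      a_label = agg$a_label, r_label = agg$r_label,
                      index = agg$index,
                      mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                      n = as.integer(agg$value[, "n"]),
                      stringsAsFactors = FALSE)
    out$band <- as.character(classifyAgreement(out$mean))
    out[order(out$subgroup, out$index, out$r_label, out$a_label), ]
}

#' Compare registration methods within one position group
#'
#' Paired Wilcoxon signed-rank test of ER versus RR index values, per
#' (index, baseline threshold, recurrence threshold) cell, across the cases
#' of one position group. Every case must contribute both methods.
#'
#' @param results data frame of overlap rows.
#' @param positionGroup \code{"TP"} or \code{"NTP"}.
#' @return A data frame with one row per cell: index, thresholds, per-method
#'   mean and SD, mean paired difference (ER - RR), the signed-rank
#'   statistic, raw \code{p_value}, n (non-zero pairs) and test name; the
#'   number of tests performed is attached as attribute \code{n_tests}.
#' @export
compareMethods <- function(results, positionGroup) {
    .checkSubgroupLabels(results)
    res <- results[results$position_group == positionGroup, ]
    if (nrow(res) == 0L) stop("no results for position group ", positionGroup)
    if (!all(c("RR", "ER") %in% unique(res$method)))
        stop("paired method comparison needs both RR and ER results for ",
             "every case; for independent groups use comparePositions()")
    rows <- list()
    for (ix in .overlapIndexCols) {
        for (rl in unique(res$r_label)) {
            for (al in unique(res$a_label)) {
                cell <- res[res$a_label == al & res$r_label == rl, ]
                rr <- cell[cell$method == "RR", ]
                er <- cell[cell$method == "ER", ]
                rr <- rr[order(rr$case_id), ]
                er <- er[order(er$case_id), ]
                if (!identical(rr$case_id, er$case_id))
                    stop("unpaired input: case sets differ between RR and ER ",
                         "in cell ", al, "/", rl,
                         "; use comparePositions() for independent groups")
                w <- .wilcoxP(er[[ix]], rr[[ix]], paired = TRUE)
                rows[[length(rows) + 1L]] <- data.frame(
                    contrast = paste0("ER-vs-RR within ", positionGroup),
                    index = ix, a_label = al, r_label = rl,
                    n_pairs = nrow(rr), n_nonzero = w$n,
                    mean_rr = mean(rr[[ix]]), sd_rr = sd(rr[[ix]]),
                    mean_er = mean(er[[ix]]), sd_er = sd(er[[ix]]),
                    mean_diff = mean(er[[ix]] - rr[[ix]]),
                    statistic = w$statistic, p_value = w$p,
                    test = "Wilcoxon signed-rank", stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "n_tests") <- nrow(out)
    out
}

#' Compare position groups under one registration method
#'
#' Mann-Whitney U test of TP versus NTP index values, per (index, baseline
#' threshold, recurrence threshold) cell, within one registration method.
#'
#' @param results data frame of overlap rows.
#' @param method \code{"RR"} or \code{"ER"}.
#' @return A data frame with one row per cell: index, thresholds, per-group
#'   mean and SD and n, the U statistic, raw \code{p_value} and test name;
#'   attribute \code{n_tests} gives the number of tests.
#' @export
comparePositions <- function(results, method) {
    .checkSubgroupLabels(results)
    res <- results[results$method == method, ]
    if (nrow(res) == 0L) stop("no results for method ", method)
    rows <- list()
    for (ix in .overlapIndexCols) {
        for (rl in unique(res$r_label)) {
            for (al in unique(res$a_label)) {
                cell <- res[res$a_label == al & res$r_label == rl, ]
                tp <- cell[cell$position_group == "TP", ix]
                ntp <- cell[cell$position_group == "NTP", ix]
                if (length(tp) < 2L || length(ntp) < 2L)
                    stop("each position group needs at least 2 cases ",
                         "(cell ", al, "/", rl, ")")
                w <- .wilcoxP(tp, ntp, paired = FALSE)
                rows[[length(rows) + 1L]] <- data.frame(
                    contrast = paste0("TP-vs-NTP under ", method),
                    index = ix, a_label = al, r_label = rl,
                    n_tp = length(tp), n_ntp = length(ntp),
                    mean_tp = mean(tp), sd_tp = sd(tp),
                    mean_ntp = mean(ntp), sd_ntp = sd(ntp),
                    mean_diff = mean(tp) - mean(ntp),
                    statistic = w$statistic, p_value = w$p,
                    test = "Mann-Whitney U", stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "n_tests") <- nrow(out)
    out
}

#' Compare baseline uptake between outcome groups
#'
#' Mann-Whitney U tests of MTV and TLG between each relapse group (LR, DR,
#' or their union) present in the data and the controlled (CR) group.
#'
#' @param metrics data frame with columns \code{case_id}, \code{group}
#'   (\code{"CR"}, \code{"LR"}, \code{"DR"}), \code{mtv_cc}, \code{tlg_g}.
#' @return A data frame with one row per (metric, contrast): group means
#'   and SDs, U statistic, raw \code{p_value}.
#' @export
compareUptakeGroups <- function(metrics) {
    stopifnot(is.data.frame(metrics),
              all(c("group", "mtv_cc", "tlg_g") %in% names(metrics)))
    groups <- unique(metrics$group)
    if (!"CR" %in% groups || length(groups) < 2L)
        stop("need a CR group and at least one relapse group, each with >= 2 cases")
    cr <- metrics[metrics$group == "CR", ]
    relGroups <- setdiff(groups, "CR")
    if (length(relGroups) > 1L) relGroups <- c(relGroups, "LR+DR")
    rows <- list()
    for (g in relGroups) {
        rel <- if (g == "LR+DR") metrics[metrics$group != "CR", ]
               else metrics[metrics$group == g, ]
        if (nrow(rel) < 2L || nrow(cr) < 2L)
            stop("each outcome group needs at least 2 cases")
        for (m in c("mtv_cc", "tlg_g")) {
            w <- .wilcoxP(rel[[m]], cr[[m]], paired = FALSE)
            rows[[length(rows) + 1L]] <- data.frame(
                metric = m, contrast = paste0(g, "-vs-CR"),
                n_relapse = nrow(rel), n_cr = nrow(cr),
                mean_relapse = mean(rel[[m]]), sd_relapse = sd(rel[[m]]),
                mean_cr = mean(cr[[m]]), sd_cr = sd(cr[[m]]),
                statistic = w$statistic, p_value = w$p,
                test = "Mann-Whitney U", stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "n_tests") <- nrow(out)
    out
}
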