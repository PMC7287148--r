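## Relative-SUVmax VOI delineation: voxels inside the search region with
## SUV >= x * SUVmax(region), restricted to the 26-connected component that
## contains the SUVmax voxel so remote physiological uptake cannot inflate
## the VOI.

#' Delineate a relative-SUVmax sub-volume
#'
#' Finds SUVmax within the search region, thresholds the region at
#' \code{thresholdFraction * SUVmax} (inclusive), and keeps the 26-connected
#' component containing the SUVmax voxel. A tie for the SUVmax voxel is
#' broken deterministically to the lowest linear index (a message reports
#' the tie). Masks are invariant to positive rescaling of the PET values.
#'
#' @param pet a PET \linkS4class{ScalarVolume} (SUV).
#' @param region search region, a 2 x 3 lo/hi matrix in world mm (see
#'   \code{\link{regionBox}}).
#' @param thresholdFraction relative threshold x in (0,1).
#' @param label VOI label; default built from the fraction (e.g.
#'   \code{"A_40"}).
#' @param role \code{"A"} (baseline) or \code{"R"} (recurrence), used for
#'   the default label.
#' @return A \linkS4class{VoiMask}.
#' @examples
#' case <- generateCase(phantomConfig("TP", noiseSd = 0, ctNoiseSd = 0))
#' reg <- maskBoundingBox(case@trueLesionA, marginMm = 10)
#' delineateVoi(case@petA, reg, 0.4)
#' @export
delineateVoi <- function(pet, region, thresholdFraction, label = NULL,
                         role = "A") {
    stopifnot(is(pet, "ScalarVolume"))
    if (length(thresholdFraction) != 1L || thresholdFraction <= 0 ||
        thresholdFraction >= 1)
        stop("thresholdFraction must be a single value in (0,1)")
    geom <- pet@geometry
    inRegion <- .regionIndicator(geom, region)
    if (!any(inRegion)) stop("search region contains no voxel centers")
    vals <- as.numeric(pet@data)
    regionVals <- vals[inRegion]
    suvMax <- max(regionVals)
    if (suvMax <= 0) stop("search region has no positive uptake (all-zero region)")
    maxIdx <- which(inRegion & vals == suvMax)
    if (length(maxIdx) > 1L)
        message("SUVmax tie (", length(maxIdx),
                " voxels); using lowest linear index")
    seed <- maxIdx[1]
    candidate <- inRegion & vals >= thresholdFraction * suvMax
    comp <- .cppConnComp26(candidate, geom@dim, seed - 1L)
    if (is.null(label))
        label <- sprintf("%s_%d", role, round(100 * thresholdFraction))
    voiMask(array(comp, geom@dim), geom, label = label,
            thresholdFraction = thresholdFraction,
            reference = if (role == "R") "PET_R" else "PET_A")
}

#' Delineate all study VOIs for one case
#'
#' Produces the baseline sub-volumes (default A_30..A_90) on the baseline
#' PET and the recurrence sub-volumes (default R_40, R_70) on the recurrence
#' PET — 7 + 2 = 9 masks per case under the default configuration.
#'
#' @param petA,petR baseline and recurrence PET \linkS4class{ScalarVolume}s.
#' @param regionA,regionR lesion search regions (2 x 3 lo/hi matrices, mm).
#' @param study a \linkS4class{StudyConfig} supplying the threshold grids.
#' @return A list with elements \code{A} and \code{R}, each a named list of
#'   \linkS4class{VoiMask}.
#' @export
delineateAll <- function(petA, petR, regionA, regionR, study = studyConfig()) {
    aMasks <- lapply(study@baselineThresholds / 100, function(x)
        delineateVoi(petA, regionA, x, role = "A"))
    names(aMasks) <- sprintf("A_%d", round(study@baselineThresholds))
    rMasks <- lapply(study@recurrenceThresholds / 100, function(x)
        delineateVoi(petR, regionR, x, role = "R"))
    names(rMasks) <- sprintf("R_%d", round(study@recurrenceThresholds))
    list(A = aMasks, R = rMasks)
}

#' Uptake metrics of a baseline lesion
#'
#' SUVmax over the search region; metabolic tumor volume as the volume of
#' the 40\%-SUVmax sub-volume (MTV = volume of A_40); SUVmean within that
#' sub-volume; and total lesion glycolysis TLG = SUVmean x MTV.
#'
#' @inheritParams delineateVoi
#' @param region lesion search region (2 x 3 lo/hi matrix, mm).
#' @return An \linkS4class{UptakeMetrics}.
#' @export
computeUptakeMetrics <- function(pet, region) {
    a40 <- delineateVoi(pet, region, 0.4, label = "A_40")
    inRegion <- .regionIndicator(pet@geometry, region)
    suvMax <- max(pet@data[inRegion])
    suvMean <- mean(pet@data[a40@mask])
    mtv <- volumeCc(a40)
    new("UptakeMetrics", suvMax = suvMax, suvMean = suvMean, mtvCc = mtv,
        tlgG = suvMean * mtv)
}
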