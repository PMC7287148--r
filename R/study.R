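#' Configure a synthetic study
#'
#' Defines the cohort composition (15 TP + 28 NTP local-relapse cases by
#' default, optional controlled / distant-relapse groups for uptake
#' contrasts), the baseline and recurrence threshold grids, the registration
#' methods, and the per-group phantom parameter ranges from which each
#' case's geometry and misalignment are drawn.
#'
#' @param baselineThresholds baseline VOI thresholds, \% of SUVmax
#'   (default 30..90 by 10).
#' @param recurrenceThresholds recurrence VOI thresholds, \% of SUVmax
#'   (default 40 and 70).
#' @param methods registration methods to run, subset of
#'   \code{c("RR", "ER")}.
#' @param nTP,nNTP local-relapse cases scanned in treatment / non-treatment
#'   position (defaults 15 and 28).
#' @param nCR,nDR optional controlled and distant-relapse cases (baseline
#'   session only; used for MTV/TLG group contrasts). Default 0.
#' @param tpRigidMaxDeg,tpRigidMaxMm per-axis repositioning bounds for TP
#'   cases (uniform in \code{[-max, max]}).
#' @param ntpRigidDegRange,ntpRigidMmRange range of the total rotation /
#'   translation magnitude for NTP cases (split evenly across axes with
#'   random signs).
#' @param ntpDeformAmpRange,deformWavelengthRange deformation amplitude and
#'   wavelength ranges (mm) for NTP cases; TP cases are undeformed.
#' @param recurrenceOffsetRange range (mm) of the recurrence-centroid offset
#'   magnitude (random direction).
#' @param recurrenceRadiusRange range (mm) of the recurrence lesion radius.
#' @param mtvMeanCrCc,mtvMeanLrCc,mtvMeanDrCc,mtvSdCc group means and common
#'   SD (cc) of the baseline metabolic tumor volume distribution from which
#'   lesion radii are derived (truncated normal).
#' @param noiseSd,ctNoiseSd noise levels passed to every case (SUV / HU).
#' @param gridShape,spacingMm grid geometry passed to every case.
#' @param seed master seed; all per-case seeds and parameter draws derive
#'   from it deterministically.
#' @return A validated \linkS4class{StudyConfig}.
#' @examples
#' studyConfig(nTP = 2L, nNTP = 2L)
#' @export
studyConfig <- function(baselineThresholds = seq(30, 90, by = 10),
                        recurrenceThresholds = c(40, 70),
                        methods = c("RR", "ER"),
                        nTP = 15L, nNTP = 28L, nCR = 0L, nDR = 0L,
                        tpRigidMaxDeg = 2, tpRigidMaxMm = 2,
                        ntpRigidDegRange = c(5, 8),
                        ntpRigidMmRange = c(5, 9),
                        ntpDeformAmpRange = c(4, 6),
                        deformWavelengthRange = c(50, 75),
                        recurrenceOffsetRange = c(4, 12),
                        recurrenceRadiusRange = c(8, 12),
                        mtvMeanCrCc = 6.4, mtvMeanLrCc = 9.1,
                        mtvMeanDrCc = 9.8, mtvSdCc = 3,
                        noiseSd = 0.3, ctNoiseSd = 10,
                        gridShape = c(64L, 64L, 48L), spacingMm = c(2, 2, 3),
                        seed = 1L) {
    new("StudyConfig",
        baselineThresholds = as.numeric(baselineThresholds),
        recurrenceThresholds = as.numeric(recurrenceThresholds),
        methods = methods,
        nTP = as.integer(nTP), nNTP = as.integer(nNTP),
        nCR = as.integer(nCR), nDR = as.integer(nDR),
        tpRigidMaxDeg = tpRigidMaxDeg, tpRigidMaxMm = tpRigidMaxMm,
        ntpRigidDegRange = as.numeric(ntpRigidDegRange),
        ntpRigidMmRange = as.numeric(ntpRigidMmRange),
        ntpDeformAmpRange = as.numeric(ntpDeformAmpRange),
        deformWavelengthRange = as.numeric(deformWavelengthRange),
        recurrenceOffsetRange = as.numeric(recurrenceOffsetRange),
        recurrenceRadiusRange = as.numeric(recurrenceRadiusRange),
        mtvMeanCrCc = mtvMeanCrCc, mtvMeanLrCc = mtvMeanLrCc,
        mtvMeanDrCc = mtvMeanDrCc, mtvSdCc = mtvSdCc,
        noiseSd = noiseSd, ctNoiseSd = ctNoiseSd,
        gridShape = as.integer(gridShape), spacingMm = as.numeric(spacingMm),
        seed = as.integer(seed))
}

## Truncated-normal draw by rejection (bounds keep lesions inside the grid).
.rtruncnorm1 <- function(mean, sd, lo, hi) {
    repeat {
        x <- rnorm(1, mean, sd)
        if (x >= lo && x <= hi) return(x)
    }
}

.randomUnitVector <- function() {
    repeat {
        v <- rnorm(3)
        n <- sqrt(sum(v^2))
        if (n > 1e-6) return(v / n)
    }
}

.mtvToRadiusMm <- function(mtvCc) (3 * mtvCc * 1000 / (4 * pi))^(1 / 3)

## One case's parameter draws; assumes the cohort-level RNG stream is active.
.drawCaseConfig <- function(study, group, positionGroup, caseId) {
    caseSeed <- sample.int(.Machine$integer.max - 1L, 1L)
    caseAnatomySeed <- sample.int(.Machine$integer.max - 1L, 1L)
    mtvMean <- switch(group, CR = study@mtvMeanCrCc, DR = study@mtvMeanDrCc,
                      study@mtvMeanLrCc)
    mtv <- .rtruncnorm1(mtvMean, study@mtvSdCc, 2, 14)
    lesionRadius <- .mtvToRadiusMm(mtv)
    hotspotRadius <- runif(1, 0.35, 0.55) * lesionRadius
    recurrenceRadius <- runif(1, study@recurrenceRadiusRange[1],
                              study@recurrenceRadiusRange[2])
    offset <- runif(1, study@recurrenceOffsetRange[1],
                    study@recurrenceOffsetRange[2]) * .randomUnitVector()
    suvCore <- runif(1, 8, 16)
    suvRim <- suvCore * runif(1, 0.45, 0.6)
    center <- c(8, -20, 0) + c(runif(2, -4, 4), runif(1, -6, 6))
    if (positionGroup == "TP") {
        rotDeg <- runif(3, -study@tpRigidMaxDeg, study@tpRigidMaxDeg)
        transMm <- runif(3, -study@tpRigidMaxMm, study@tpRigidMaxMm)
        amp <- 0; wl <- mean(study@deformWavelengthRange); phase <- c(0, 0, 0)
    } else {
        rotMag <- runif(1, study@ntpRigidDegRange[1], study@ntpRigidDegRange[2])
        transMag <- runif(1, study@ntpRigidMmRange[1], study@ntpRigidMmRange[2])
        rotDeg <- sample(c(-1, 1), 3, replace = TRUE) * rotMag / sqrt(3)
        transMm <- sample(c(-1, 1), 3, replace = TRUE) * transMag / sqrt(3)
        amp <- runif(1, study@ntpDeformAmpRange[1], study@ntpDeformAmpRange[2])
        wl <- runif(1, study@deformWavelengthRange[1],
                    study@deformWavelengthRange[2])
        phase <- runif(3, 0, 2 * pi)
    }
    phantomConfig(positionGroup,
                  gridShape = study@gridShape, spacingMm = study@spacingMm,
                  lesionCenterMm = center, lesionRadiusMm = lesionRadius,
                  hotspotRadiusMm = hotspotRadius,
                  suvBackground = 1, suvRim = suvRim, suvCore = suvCore,
                  recurrenceOffsetMm = offset,
                  recurrenceRadiusMm = recurrenceRadius,
                  recurrenceCoreRadiusMm = 0.5 * recurrenceRadius,
                  rigidErrorDeg = rotDeg, rigidErrorMm = transMm,
                  deformationAmplitudeMm = amp, deformationWavelengthMm = wl,
                  deformationPhase = phase,
                  noiseSd = study@noiseSd, ctNoiseSd = study@ctNoiseSd,
                  seed = caseSeed, anatomySeed = caseAnatomySeed,
                  caseId = caseId)
}

#' Per-case phantom configurations of a study
#'
#' Deterministically expands a \linkS4class{StudyConfig} into the list of
#' per-case \linkS4class{PhantomConfig}s (local-relapse cases, plus
#' controlled / distant-relapse cases when configured). Two calls with the
#' same study seed produce identical configurations, including the
#' case-id-to-seed mapping.
#'
#' @param study a \linkS4class{StudyConfig}.
#' @param groups which outcome groups to expand; any of \code{"LR"},
#'   \code{"CR"}, \code{"DR"}.
#' @return Named list of \linkS4class{PhantomConfig}; names are case ids.
#' @export
cohortConfigs <- function(study = studyConfig(), groups = c("LR", "CR", "DR")) {
    validObject(study)
    set.seed(study@seed)
    configs <- list()
    specs <- list(
        list(group = "LR", pos = "TP", n = study@nTP, tag = "LR_TP"),
        list(group = "LR", pos = "NTP", n = study@nNTP, tag = "LR_NTP"),
        list(group = "CR", pos = "TP", n = study@nCR, tag = "CR"),
        list(group = "DR", pos = "TP", n = study@nDR, tag = "DR"))
    for (sp in specs) {
        if (sp$n < 1L) next
        for (i in seq_len(sp$n)) {
            id <- sprintf("%s_%02d", sp$tag, i)
            cfg <- .drawCaseConfig(study, sp$group, sp$pos, id)
            if (sp$group %in% groups) configs[[id]] <- cfg
        }
    }
    configs
}

#' Generate a synthetic cohort
#'
#' Generates all local-relapse phantom cases of a study (default 43: 15 in
#' treatment position, 28 in non-treatment position), each from a per-case
#' seed derived deterministically from the study seed.
#'
#' @param study a \linkS4class{StudyConfig}.
#' @return Named list of \linkS4class{PhantomCase}.
#' @examples
#' cohort <- generateCohort(studyConfig(nTP = 1L, nNTP = 1L))
#' length(cohort)
#' @export
generateCohort <- function(study = studyConfig()) {
    lapply(cohortConfigs(study, groups = "LR"), generateCase)
}
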