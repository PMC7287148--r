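## End-to-end study: simulate -> segment -> register -> overlap -> stats.
## Cases are generated, processed and discarded one at a time so a full
## 43-case cohort stays within a desktop memory budget; everything is a
## pure function of the study configuration (master seed included).

.caseFocusRegion <- function(case, marginMm = 25) {
    a <- maskBoundingBox(case@trueLesionA, marginMm)
    r <- maskBoundingBox(case@trueLesionR, marginMm)
    b <- .gridBounds(case@ctR@geometry)
    regionBox(pmax(pmin(a["lo", ], r["lo", ]), b["lo", ]),
              pmin(pmax(a["hi", ], r["hi", ]), b["hi", ]))
}

## Segment, register and measure one case; returns overlap rows plus
## per-case uptake metrics and registration transforms.
.processCase <- function(case, study, control = registrationControl(),
                         keepTransforms = FALSE) {
    regionA <- maskBoundingBox(case@trueLesionA, marginMm = 12)
    regionR <- maskBoundingBox(case@trueLesionR, marginMm = 12)
    masks <- delineateAll(case@petA, case@petR, regionA, regionR, study)
    uptake <- computeUptakeMetrics(case@petA, regionA)

    focus <- .caseFocusRegion(case)
    transforms <- list()
    if ("RR" %in% study@methods || "ER" %in% study@methods)
        transforms$RR <- registerRigid(case@ctR, case@ctA, focus, control)
    if ("ER" %in% study@methods)
        transforms$ER <- registerElastic(case@ctR, case@ctA, transforms$RR,
                                         focus, control)

    targetGeom <- case@petR@geometry
    rows <- list()
    for (m in study@methods) {
        mapped <- lapply(masks$A, applyTransform, transform = transforms[[m]],
                         target = targetGeom)
        rows[[m]] <- overlapMatrix(mapped, masks$R, method = m,
                                   caseId = case@caseId,
                                   positionGroup = case@positionGroup)
    }
    list(overlaps = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         uptake = data.frame(case_id = case@caseId, group = "LR",
                             position_group = case@positionGroup,
                             suv_max = uptake@suvMax, suv_mean = uptake@suvMean,
                             mtv_cc = uptake@mtvCc, tlg_g = uptake@tlgG,
                             stringsAsFactors = FALSE),
         transforms = if (keepTransforms) transforms else NULL,
         nVois = length(masks$A) + length(masks$R))
}

#' Run a full synthetic overlap study
#'
#' Generates the configured cohort, delineates all baseline and recurrence
#' sub-volumes, registers every case with the configured methods, computes
#' the overlap index table, aggregates subgroup summaries and runs the
#' method and position comparisons (and, when controlled/distant-relapse
#' cases are configured, the MTV/TLG group contrasts). Deterministic given
#' the configuration; progress is logged to stderr.
#'
#' @param study a \linkS4class{StudyConfig}.
#' @param control registration tuning, see \code{\link{registrationControl}}.
#' @param outDir optional output directory; when given, the overlap table
#'   (CSV), the uptake table (CSV) and the report (JSON) are written there.
#' @param writeVolumes when \code{TRUE} (and \code{outDir} is given), each
#'   case's volumes, masks and sidecar are also written under
#'   \code{outDir/cases/<case_id>/}.
#' @param verbose log per-case progress to stderr.
#' @return A \linkS4class{StudyReport}.
#' @examples
#' \donttest{
#' rep <- runStudy(studyConfig(nTP = 1L, nNTP = 1L, noiseSd = 0))
#' rep
#' }
#' @export
runStudy <- function(study = studyConfig(), control = registrationControl(),
                     outDir = NULL, writeVolumes = FALSE, verbose = TRUE) {
    validObject(study)
    t0 <- Sys.time()
    configs <- cohortConfigs(study)
    lrIds <- names(configs)[startsWith(names(configs), "LR_")]
    overlapRows <- list()
    uptakeRows <- list()
    nVois <- 0L
    log <- function(...) if (verbose) message(sprintf(...))

    for (id in names(configs)) {
        stage <- "simulate"
        res <- tryCatch({
            case <- generateCase(configs[[id]])
            if (id %in% lrIds) {
                stage <- "process"
                out <- .processCase(case, study, control)
            } else {
                ## controlled / distant-relapse cases: baseline uptake only
                stage <- "uptake"
                regionA <- maskBoundingBox(case@trueLesionA, marginMm = 12)
                um <- computeUptakeMetrics(case@petA, regionA)
                out <- list(overlaps = NULL, nVois = 0L, transforms = NULL,
                            uptake = data.frame(
                                case_id = id,
                                group = sub("_.*", "", id),
                                position_group = case@positionGroup,
                                suv_max = um@suvMax, suv_mean = um@suvMean,
                                mtv_cc = um@mtvCc, tlg_g = um@tlgG,
                                stringsAsFactors = FALSE))
            }
            if (writeVolumes && !is.null(outDir))
                writePhantomCase(case, file.path(outDir, "cases", id))
            out
        }, error = function(e)
            stop("case ", id, " failed at stage '", stage, "': ",
                 conditionMessage(e), call. = FALSE))
        overlapRows[[id]] <- res$overlaps
        uptakeRows[[id]] <- res$uptake
        nVois <- nVois + res$nVois
        log("[%s] done (%.1f s elapsed)", id,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
    }

    overlaps <- do.call(rbind, c(overlapRows, list(make.row.names = FALSE)))
    uptake <- do.call(rbind, c(uptakeRows, list(make.row.names = FALSE)))

    comparisons <- list()
    summaries <- summarizeSubgroups(overlaps)
    if (all(c("RR", "ER") %in% study@methods)) {
        for (pg in intersect(c("NTP", "TP"), unique(overlaps$position_group)))
            comparisons[[paste0("methods_", pg)]] <- compareMethods(overlaps, pg)
    }
    nPerGroup <- table(unique(overlaps[c("case_id", "position_group")])$position_group)
    if (all(c("TP", "NTP") %in% names(nPerGroup)) && all(nPerGroup >= 2L)) {
        for (m in study@methods)
            comparisons[[paste0("positions_", m)]] <- comparePositions(overlaps, m)
    }
    if (sum(uptake$group == "CR") >= 2L && sum(uptake$group != "CR") >= 2L)
        comparisons$uptake <- compareUptakeGroups(uptake)

    nCases <- length(lrIds)
    counts <- c(nCases = nCases, nScans = 2L * nCases, nVois = nVois,
                nIndexValues = nCases * length(study@baselineThresholds) *
                    length(study@recurrenceThresholds) * 5L *
                    length(study@methods))
    stopifnot(nrow(overlaps) * 5L == counts["nIndexValues"])

    report <- new("StudyReport", counts = setNames(as.integer(counts),
                                                   names(counts)),
                  overlaps = overlaps, summaries = summaries,
                  comparisons = comparisons, uptake = uptake,
                  provenance = list(
                      seed = study@seed,
                      methods = study@methods,
                      baseline_thresholds = study@baselineThresholds,
                      recurrence_thresholds = study@recurrenceThresholds,
                      package_version = as.character(packageVersion("hotspotOverlap")),
                      elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeOverlapTable(overlaps, file.path(outDir, "overlap_indices.csv"))
        write.csv(uptake, file.path(outDir, "uptake_metrics.csv"),
                  row.names = FALSE)
        writeStudyReport(report, file.path(outDir, "report.json"))
    }
    report
}

#' Write a study report as JSON
#'
#' @param report a \linkS4class{StudyReport}.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
writeStudyReport <- function(report, path) {
    stopifnot(is(report, "StudyReport"))
    jsonlite::write_json(
        list(counts = as.list(report@counts),
             provenance = report@provenance,
             subgroup_summaries = report@summaries,
             comparisons = lapply(report@comparisons, function(df) {
                 list(n_tests = attr(df, "n_tests"), table = df)
             }),
             uptake = report@uptake),
        path, digits = NA, auto_unbox = TRUE, dataframe = "rows")
    invisible(path)
}
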