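#' @useDynLib hotspotOverlap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats aggregate optim rnorm runif sd var wilcox.test setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

.oneOf <- function(x, choices) length(x) == 1L && !is.na(x) && x %in% choices

#' Regular 3D grid geometry
#'
#' Physical layout of a voxel grid: voxel counts, per-axis spacing (mm),
#' world coordinate of the first voxel center (mm) and direction cosines.
#' Voxel indices are 0-based and refer to voxel centers, so
#' \code{world = origin + direction \%*\% (index * spacing)}.
#'
#' @slot dim integer(3), voxel counts per axis.
#' @slot spacing numeric(3), voxel size in mm, strictly positive.
#' @slot origin numeric(3), world coordinate (mm) of voxel (0,0,0).
#' @slot direction 3x3 orthonormal direction-cosine matrix.
#' @export
setClass("VolumeGeometry",
    representation(dim = "integer", spacing = "numeric", origin = "numeric",
                   direction = "matrix"),
    prototype(dim = c(1L, 1L, 1L), spacing = c(1, 1, 1), origin = c(0, 0, 0),
              direction = diag(3)))

setValidity("VolumeGeometry", function(object) {
    msg <- character()
    if (length(object@dim) != 3L || any(object@dim < 1L))
        msg <- c(msg, "dim must be 3 positive integers")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be 3 finite values (mm)")
    D <- object@direction
    if (!is.numeric(D) || !identical(dim(D), c(3L, 3L)) ||
        max(abs(crossprod(D) - diag(3))) > 1e-6)
        msg <- c(msg, "direction must be a 3x3 orthonormal matrix")
    if (length(msg)) msg else TRUE
})

#' A scalar 3D image volume
#'
#' Holds a PET (SUV) or CT (HU) image together with its physical geometry.
#'
#' @slot data 3D numeric array, column-major, matching \code{geometry@dim}.
#' @slot geometry a \linkS4class{VolumeGeometry}.
#' @slot modality one of \code{"PET"}, \code{"CT"}, \code{"OTHER"}. PET data
#'   must be non-negative (SUV).
#' @export
setClass("ScalarVolume",
    representation(data = "array", geometry = "VolumeGeometry",
                   modality = "character"),
    prototype(data = array(0, c(1, 1, 1)), modality = "OTHER"))

setValidity("ScalarVolume", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "data must be a 3D array")
    else if (!identical(dim(object@data), as.integer(object@geometry@dim)))
        msg <- c(msg, "data dimensions do not match geometry")
    if (!.oneOf(object@modality, c("PET", "CT", "OTHER")))
        msg <- c(msg, "modality must be PET, CT or OTHER")
    else if (object@modality == "PET" && any(object@data < -1e-9, na.rm = TRUE))
        msg <- c(msg, "PET (SUV) data must be non-negative")
    if (anyNA(object@data)) msg <- c(msg, "data must not contain NA")
    if (length(msg)) msg else TRUE
})

#' A binary volume of interest
#'
#' A sub-volume mask (e.g. a relative-SUVmax VOI such as A_40, or a
#' ground-truth lesion extent) tied to a named reference grid.
#'
#' @slot mask 3D logical array.
#' @slot geometry the \linkS4class{VolumeGeometry} of the reference grid.
#' @slot label VOI label such as \code{"A_40"} or \code{"R_70"}.
#' @slot thresholdFraction the relative-SUVmax fraction used to delineate the
#'   VOI, in (0,1), or \code{NA} for ground-truth masks.
#' @slot reference name of the scan the mask lives on (e.g. \code{"PET_A"}).
#' @export
setClass("VoiMask",
    representation(mask = "array", geometry = "VolumeGeometry",
                   label = "character", thresholdFraction = "numeric",
                   reference = "character"),
    prototype(mask = array(FALSE, c(1, 1, 1)), label = "mask",
              thresholdFraction = NA_real_, reference = ""))

setValidity("VoiMask", function(object) {
    msg <- character()
    if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
        msg <- c(msg, "mask must be a 3D logical array")
    else if (!identical(dim(object@mask), as.integer(object@geometry@dim)))
        msg <- c(msg, "mask dimensions do not match geometry")
    if (anyNA(object@mask)) msg <- c(msg, "mask must not contain NA")
    tf <- object@thresholdFraction
    if (length(tf) != 1L || (!is.na(tf) && (tf <= 0 || tf >= 1)))
        msg <- c(msg, "thresholdFraction must be in (0,1) or NA")
    if (length(msg)) msg else TRUE
})

#' A 6-parameter rigid transform
#'
#' Maps world points by \code{p' = R (p - center) + center + translation},
#' with \code{R} the ZYX Euler rotation built from \code{rotation}. As
#' produced by \code{\link{registerRigid}} the transform maps recurrence-scan
#' coordinates to baseline-scan coordinates, so resampling the baseline image
#' at transformed recurrence-grid points carries it onto the recurrence grid.
#'
#' @slot rotation numeric(3), Euler angles (rad) about x, y, z.
#' @slot translation numeric(3), mm.
#' @slot center numeric(3), rotation center, mm.
#' @export
setClass("RigidTransform",
    representation(rotation = "numeric", translation = "numeric",
                   center = "numeric"),
    prototype(rotation = c(0, 0, 0), translation = c(0, 0, 0),
              center = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
    if (length(object@rotation) != 3L || length(object@translation) != 3L ||
        length(object@center) != 3L ||
        any(!is.finite(c(object@rotation, object@translation, object@center))))
        "rotation, translation and center must each be 3 finite values"
    else TRUE
})

#' A free-form deformation composed with a rigid initialization
#'
#' The total mapping of a fixed-grid world point x is
#' \code{T(x) = init(x) + displacement(x)} (mm). The displacement is stored
#' densely on the fixed grid; it is zero where the registration had no
#' support. With a zero field the transform reproduces \code{init} exactly.
#'
#' @slot displacement 4D numeric array \code{c(dim, 3)} of per-voxel
#'   displacement vectors in mm, on the fixed grid.
#' @slot geometry the fixed-grid \linkS4class{VolumeGeometry}.
#' @slot init the rigid initialization it composes with.
#' @slot controlSpacing control-point spacing (mm) of the free-form model
#'   that produced the field (\code{NA} for analytic / ground-truth fields).
#' @export
setClass("DeformationField",
    representation(displacement = "array", geometry = "VolumeGeometry",
                   init = "RigidTransform", controlSpacing = "numeric"),
    prototype(displacement = array(0, c(1, 1, 1, 3)),
              controlSpacing = NA_real_))

setValidity("DeformationField", function(object) {
    msg <- character()
    d <- dim(object@displacement)
    if (length(d) != 4L || d[4] != 3L)
        msg <- c(msg, "displacement must be a 4D array with last extent 3")
    else if (!identical(d[1:3], as.integer(object@geometry@dim)))
        msg <- c(msg, "displacement grid does not match geometry")
    if (any(!is.finite(object@displacement)))
        msg <- c(msg, "displacement must be finite everywhere")
    if (length(msg)) msg else TRUE
})

#' Configuration of one synthetic PET/CT phantom case
#'
#' Defines the anatomy, lesion geometry, uptake levels, inter-session
#' misalignment and noise of one synthetic patient. See
#' \code{\link{phantomConfig}} for field semantics and defaults.
#'
#' @export
setClass("PhantomConfig",
    representation(
        gridShape = "integer", spacingMm = "numeric",
        lesionCenterMm = "numeric", lesionRadiusMm = "numeric",
        hotspotRadiusMm = "numeric", suvBackground = "numeric",
        suvRim = "numeric", suvCore = "numeric",
        recurrenceOffsetMm = "numeric", recurrenceRadiusMm = "numeric",
        recurrenceCoreRadiusMm = "numeric",
        rigidErrorDeg = "numeric", rigidErrorMm = "numeric",
        deformationAmplitudeMm = "numeric", deformationWavelengthMm = "numeric",
        deformationPhase = "numeric",
        noiseSd = "numeric", ctNoiseSd = "numeric",
        positionGroup = "character", seed = "integer",
        anatomySeed = "integer", caseId = "character"))

setValidity("PhantomConfig", function(object) {
    msg <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
        msg <- c(msg, "gridShape must be 3 integers >= 8")
    if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
        msg <- c(msg, "spacingMm must be 3 positive values")
    if (!(object@suvCore > object@suvRim && object@suvRim > object@suvBackground &&
          object@suvBackground >= 0))
        msg <- c(msg, "need suvCore > suvRim > suvBackground >= 0")
    for (r in c(object@lesionRadiusMm, object@hotspotRadiusMm,
                object@recurrenceRadiusMm, object@recurrenceCoreRadiusMm))
        if (!(is.finite(r) && r > 0)) {
            msg <- c(msg, "all radii must be > 0")
            break
        }
    if (object@hotspotRadiusMm > object@lesionRadiusMm)
        msg <- c(msg, "hotspotRadiusMm must not exceed lesionRadiusMm")
    if (object@recurrenceCoreRadiusMm > object@recurrenceRadiusMm)
        msg <- c(msg, "recurrenceCoreRadiusMm must not exceed recurrenceRadiusMm")
    if (object@noiseSd < 0 || object@ctNoiseSd < 0)
        msg <- c(msg, "noise SDs must be >= 0")
    if (object@deformationAmplitudeMm < 0)
        msg <- c(msg, "deformationAmplitudeMm must be >= 0")
    if (object@deformationAmplitudeMm > 0) {
        slope <- 2 * pi * object@deformationAmplitudeMm / object@deformationWavelengthMm
        if (slope >= 0.9)
            msg <- c(msg, "deformation too steep: amplitude * 2*pi / wavelength must be < 0.9 to stay invertible")
    }
    if (!.oneOf(object@positionGroup, c("TP", "NTP")))
        msg <- c(msg, "positionGroup must be 'TP' or 'NTP'")
    if (length(object@rigidErrorDeg) != 3L || length(object@rigidErrorMm) != 3L)
        msg <- c(msg, "rigidErrorDeg and rigidErrorMm must have length 3")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed must be a single integer")
    if (length(msg)) msg else TRUE
})

#' One synthetic patient: two PET/CT sessions with ground truth
#'
#' @slot petA,ctA baseline session \linkS4class{ScalarVolume}s.
#' @slot petR,ctR recurrence session \linkS4class{ScalarVolume}s.
#' @slot trueRigid ground-truth rigid mapping from recurrence-grid to
#'   baseline-grid coordinates (the direction \code{\link{registerRigid}}
#'   estimates); the inverse of the simulated patient repositioning.
#' @slot trueDeformation ground-truth residual (non-rigid) displacement on
#'   the recurrence grid, composing with \code{trueRigid}; the zero field
#'   when the case was simulated without deformation.
#' @slot trueLesionA,trueLesionR ground-truth lesion extents.
#' @slot positionGroup \code{"TP"} or \code{"NTP"}.
#' @slot caseId character identifier.
#' @slot config the \linkS4class{PhantomConfig} that produced the case.
#' @export
setClass("PhantomCase",
    representation(petA = "ScalarVolume", ctA = "ScalarVolume",
                   petR = "ScalarVolume", ctR = "ScalarVolume",
                   trueRigid = "RigidTransform",
                   trueDeformation = "DeformationField",
                   trueLesionA = "VoiMask", trueLesionR = "VoiMask",
                   positionGroup = "character", caseId = "character",
                   config = "PhantomConfig"))

setValidity("PhantomCase", function(object) {
    msg <- character()
    if (!identical(object@petA@geometry@dim, object@ctA@geometry@dim) ||
        !identical(object@petR@geometry@dim, object@ctR@geometry@dim))
        msg <- c(msg, "PET and CT of one session must share grid geometry")
    if (!.oneOf(object@positionGroup, c("TP", "NTP")))
        msg <- c(msg, "positionGroup must be 'TP' or 'NTP'")
    if (length(msg)) msg else TRUE
})

#' Uptake metrics of a baseline lesion
#'
#' SUVmax over the search region, and SUVmean / metabolic tumor volume /
#' total lesion glycolysis computed on the 40\%-SUVmax sub-volume
#' (MTV = volume of A_40; TLG = SUVmean x MTV).
#'
#' @slot suvMax,suvMean SUV.
#' @slot mtvCc metabolic tumor volume, cc.
#' @slot tlgG total lesion glycolysis, g.
#' @export
setClass("UptakeMetrics",
    representation(suvMax = "numeric", suvMean = "numeric",
                   mtvCc = "numeric", tlgG = "numeric"))

setValidity("UptakeMetrics", function(object) {
    msg <- character()
    if (object@suvMean > object@suvMax + 1e-9)
        msg <- c(msg, "suvMean must not exceed suvMax")
    if (object@mtvCc < 0) msg <- c(msg, "mtvCc must be >= 0")
    if (abs(object@tlgG - object@suvMean * object@mtvCc) >
        1e-9 * max(1, abs(object@tlgG)))
        msg <- c(msg, "tlgG must equal suvMean * mtvCc")
    if (length(msg)) msg else TRUE
})

#' Study-level configuration
#'
#' Cohort composition, threshold grids, registration methods and per-group
#' phantom parameter ranges for a full synthetic study. See
#' \code{\link{studyConfig}}.
#'
#' @export
setClass("StudyConfig",
    representation(
        baselineThresholds = "numeric", recurrenceThresholds = "numeric",
        methods = "character",
        nTP = "integer", nNTP = "integer", nCR = "integer", nDR = "integer",
        tpRigidMaxDeg = "numeric", tpRigidMaxMm = "numeric",
        ntpRigidDegRange = "numeric", ntpRigidMmRange = "numeric",
        ntpDeformAmpRange = "numeric", deformWavelengthRange = "numeric",
        recurrenceOffsetRange = "numeric", recurrenceRadiusRange = "numeric",
        mtvMeanCrCc = "numeric", mtvMeanLrCc = "numeric", mtvMeanDrCc = "numeric",
        mtvSdCc = "numeric",
        noiseSd = "numeric", ctNoiseSd = "numeric",
        gridShape = "integer", spacingMm = "numeric",
        seed = "integer"))

setValidity("StudyConfig", function(object) {
    msg <- character()
    bt <- object@baselineThresholds; rt <- object@recurrenceThresholds
    if (length(bt) < 1L || any(diff(bt) <= 0) || any(bt <= 0 | bt >= 100))
        msg <- c(msg, "baselineThresholds must be strictly increasing, in (0,100)")
    if (length(rt) < 1L || any(diff(rt) <= 0) || any(rt <= 0 | rt >= 100))
        msg <- c(msg, "recurrenceThresholds must be strictly increasing, in (0,100)")
    if (length(object@methods) < 1L ||
        !all(object@methods %in% c("RR", "ER")))
        msg <- c(msg, "methods must be a non-empty subset of {RR, ER}")
    if (any(c(object@nTP, object@nNTP, object@nCR, object@nDR) < 0L))
        msg <- c(msg, "cohort counts must be >= 0")
    if (object@nTP + object@nNTP < 1L)
        msg <- c(msg, "need at least one local-relapse case (nTP + nNTP >= 1)")
    if (length(msg)) msg else TRUE
})

#' Machine-readable report of one full study run
#'
#' @slot counts named integer vector: \code{nCases}, \code{nScans},
#'   \code{nVois}, \code{nIndexValues}. Always satisfy
#'   \code{nScans = 2 nCases}, \code{nVois = nCases (|A|+|R|)},
#'   \code{nIndexValues = nCases |A| |R| 5 |methods|}.
#' @slot overlaps data frame of per-case overlap results (one row per
#'   case/method/threshold pair; five index columns).
#' @slot summaries subgroup summary table (see \code{\link{summarizeSubgroups}}).
#' @slot comparisons list of statistical comparison tables.
#' @slot uptake data frame of per-case uptake metrics with outcome group.
#' @slot provenance list: study config, master seed, package version.
#' @export
setClass("StudyReport",
    representation(counts = "integer", overlaps = "data.frame",
                   summaries = "data.frame", comparisons = "list",
                   uptake = "data.frame", provenance = "list"))
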