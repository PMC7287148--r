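## Synthetic head-and-neck PET/CT phantom: a piecewise-constant CT anatomy
## (air, soft-tissue and muscle ellipsoids, a bone column, an airway) and a
## two-compartment FDG lesion (high-uptake core inside a rim) on a uniform
## physiological background. The recurrence session re-images the same
## anatomy after a rigid repositioning error and, for NTP cases, a smooth
## sinusoidal tissue deformation, with the baseline lesion replaced by a
## partially overlapping recurrence lesion.

#' Configure a synthetic phantom case
#'
#' Defaults depend on \code{positionGroup}: treatment-position (TP) cases get
#' a small rigid repositioning error (<= 2 mm, <= 2 deg per axis) and no
#' deformation; non-treatment-position (NTP) cases get a larger rigid error
#' plus a smooth sinusoidal deformation. All lengths in mm, uptake in SUV,
#' CT levels in HU.
#'
#' @param positionGroup \code{"TP"} or \code{"NTP"}.
#' @param gridShape integer(3) voxel counts (default 64 x 64 x 48).
#' @param spacingMm numeric(3) voxel size (default 2 x 2 x 3 mm).
#' @param lesionCenterMm baseline lesion center, world mm.
#' @param lesionRadiusMm baseline lesion (rim) radius.
#' @param hotspotRadiusMm high-uptake core radius (<= lesion radius).
#' @param suvBackground,suvRim,suvCore uptake levels; must satisfy
#'   \code{suvCore > suvRim > suvBackground >= 0}.
#' @param recurrenceOffsetMm numeric(3) displacement of the recurrence lesion
#'   centroid from the (deformed, repositioned) baseline hotspot centroid.
#' @param recurrenceRadiusMm,recurrenceCoreRadiusMm recurrence lesion and
#'   core radii.
#' @param rigidErrorDeg,rigidErrorMm rotations (deg, about x/y/z through the
#'   grid center) and translations (mm) of the patient between sessions.
#' @param deformationAmplitudeMm,deformationWavelengthMm,deformationPhase
#'   amplitude (mm), wavelength (mm) and per-axis phases (rad) of the
#'   divergence-free sinusoidal deformation applied after the rigid motion.
#' @param noiseSd additive Gaussian noise SD on PET, SUV (clipped at 0).
#' @param ctNoiseSd additive Gaussian noise SD on CT, HU.
#' @param seed integer RNG seed for the noise stream; identical config and
#'   seed give bit-identical cases.
#' @param anatomySeed seed of the internal-structure layout (a distinct
#'   substream, so noise realizations can vary under a fixed anatomy);
#'   derived from \code{seed} when \code{NULL}.
#' @param caseId identifier string.
#' @return A validated \linkS4class{PhantomConfig}.
#' @examples
#' cfg <- phantomConfig("TP", noiseSd = 0)
#' @export
phantomConfig <- function(positionGroup = c("TP", "NTP"),
                          gridShape = c(64L, 64L, 48L),
                          spacingMm = c(2, 2, 3),
                          lesionCenterMm = c(8, -20, 0),
                          lesionRadiusMm = 13,
                          hotspotRadiusMm = 6,
                          suvBackground = 1, suvRim = 6, suvCore = 12,
                          recurrenceOffsetMm = c(4, 3, 0),
                          recurrenceRadiusMm = 10,
                          recurrenceCoreRadiusMm = 5,
                          rigidErrorDeg = NULL, rigidErrorMm = NULL,
                          deformationAmplitudeMm = NULL,
                          deformationWavelengthMm = 80,
                          deformationPhase = c(0, 2, 4),
                          noiseSd = 0.3, ctNoiseSd = 10,
                          seed = 1L, anatomySeed = NULL, caseId = "case") {
    positionGroup <- match.arg(positionGroup)
    if (is.null(anatomySeed))
        anatomySeed <- (as.integer(seed) + 99991L) %% .Machine$integer.max
    if (is.null(rigidErrorDeg))
        rigidErrorDeg <- if (positionGroup == "TP") c(1, -1, 1.5) else c(4, -3, 3)
    if (is.null(rigidErrorMm))
        rigidErrorMm <- if (positionGroup == "TP") c(1, -1.5, 1) else c(4, -3, 3)
    if (is.null(deformationAmplitudeMm))
        deformationAmplitudeMm <- if (positionGroup == "TP") 0 else 4
    new("PhantomConfig",
        gridShape = as.integer(gridShape), spacingMm = as.numeric(spacingMm),
        lesionCenterMm = as.numeric(lesionCenterMm),
        lesionRadiusMm = lesionRadiusMm, hotspotRadiusMm = hotspotRadiusMm,
        suvBackground = suvBackground, suvRim = suvRim, suvCore = suvCore,
        recurrenceOffsetMm = as.numeric(recurrenceOffsetMm),
        recurrenceRadiusMm = recurrenceRadiusMm,
        recurrenceCoreRadiusMm = recurrenceCoreRadiusMm,
        rigidErrorDeg = as.numeric(rigidErrorDeg),
        rigidErrorMm = as.numeric(rigidErrorMm),
        deformationAmplitudeMm = deformationAmplitudeMm,
        deformationWavelengthMm = deformationWavelengthMm,
        deformationPhase = as.numeric(deformationPhase),
        noiseSd = noiseSd, ctNoiseSd = ctNoiseSd,
        positionGroup = positionGroup, seed = as.integer(seed),
        anatomySeed = as.integer(anatomySeed), caseId = caseId)
}

## ---- analytic anatomy -------------------------------------------------

.inEllipsoid <- function(P, center, semi) {
    ((P[, 1] - center[1]) / semi[1])^2 +
    ((P[, 2] - center[2]) / semi[2])^2 +
    ((P[, 3] - center[3]) / semi[3])^2 <= 1
}

.inSphere <- function(P, center, r) {
    (P[, 1] - center[1])^2 + (P[, 2] - center[2])^2 +
        (P[, 3] - center[3])^2 <= r * r
}

.inCylinderXY <- function(P, centerXY, r) {
    (P[, 1] - centerXY[1])^2 + (P[, 2] - centerXY[2])^2 <= r * r
}

## Small-scale piecewise-constant internal structures (fat pockets, vessels,
## nodes) scattered through the soft tissue: a fixed draw per anatomy seed.
## Their edges, distributed through the neck in all orientations, carry the
## intensity information that drives registration, as vessel and fat
## interfaces do on a contrast-enhanced CT.
.anatomyStructures <- function(anatomySeed, n = 60L) {
    set.seed(anatomySeed)
    centers <- matrix(NA_real_, n, 3)
    k <- 0L
    while (k < n) {
        p <- c(runif(1, -50, 50), runif(1, -45, 45), runif(1, -75, 75))
        if (.inEllipsoid(rbind(p), c(0, 0, 0), c(50, 45, 76))) {
            k <- k + 1L
            centers[k, ] <- p
        }
    }
    ## smooth intra-tissue HU texture: sinusoidal components with random
    ## directions and random phases at two spatial scales (a coarse set
    ## that survives pyramid smoothing, a fine set for precision)
    dirs <- matrix(rnorm(18), 6, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    lambda <- c(runif(3, 30, 50), runif(3, 16, 26))
    list(centers = centers, radii = runif(n, 3, 8),
         hu = sample(c(-100, 150), n, replace = TRUE),
         texAmp = c(12, 12, 12, 8, 8, 8),
         texK = 2 * pi / lambda * dirs,
         texPhase = runif(6, 0, 2 * pi))
}

## Smooth heterogeneity of the soft tissue (glands, muscle fascicles, fat
## infiltration): moves with the anatomy, so it carries the dense intensity
## information that anchors deformable registration away from organ edges.
.softTissueTexture <- function(P, structures) {
    t <- 0
    for (i in seq_along(structures$texAmp))
        t <- t + structures$texAmp[i] *
            sin(P %*% structures$texK[i, ] + structures$texPhase[i])
    as.numeric(t)
}

## CT anatomy in HU, without any lesion. Piecewise constant.
.ctBackgroundAt <- function(P, structures) {
    hu <- rep(-1000, nrow(P))
    body <- .inEllipsoid(P, c(0, 0, 0), c(55, 50, 80))
    hu[body] <- 40
    hu[body & .inEllipsoid(P, c(-12, 8, 0), c(28, 24, 70))] <- 60
    for (i in seq_along(structures$radii))
        hu[body & .inSphere(P, structures$centers[i, ], structures$radii[i])] <-
            structures$hu[i]
    hu[body & .inCylinderXY(P, c(22, 0), 7)] <- -800
    ## cervical spine: vertebral bodies (700 HU) separated by disc spaces
    ## (120 HU) every 22 mm, so the bone column carries axial structure
    spine <- body & .inCylinderXY(P, c(-25, 0), 9)
    vertebra <- (P[, 3] %% 22) < 16
    hu[spine & vertebra] <- 700
    hu[spine & !vertebra] <- 120
    soft <- hu > -200 & hu < 200
    hu[soft] <- hu[soft] + .softTissueTexture(P[soft, , drop = FALSE],
                                              structures)
    hu
}

## PET physiological background in SUV, without any lesion.
.petBackgroundAt <- function(P, suvBackground) {
    suv <- rep(0, nrow(P))
    body <- .inEllipsoid(P, c(0, 0, 0), c(55, 50, 80))
    suv[body] <- suvBackground
    suv[body & .inCylinderXY(P, c(22, 0), 7)] <- 0
    suv
}

## Paint a heterogeneous soft-tissue lesion into a CT vector: a
## contrast-enhancing rim (90 HU) around a hypodense core (45 HU), as
## necrotic-center tumors present on contrast CT. Restricted to soft-tissue
## voxels so bone and airway keep their densities.
.ctPaintLesion <- function(hu, P, center, r, rCore, structures) {
    soft <- hu > -200 & hu < 200
    les <- .inSphere(P, center, r) & soft
    hu[les] <- 90
    hu[.inSphere(P, center, rCore) & soft] <- 45
    hu[les] <- hu[les] + .softTissueTexture(P[les, , drop = FALSE], structures)
    hu
}

## Paint a two-compartment FDG lesion into a PET vector.
.petPaintLesion <- function(suv, P, center, rOuter, rCore, suvRim, suvCore) {
    suv[.inSphere(P, center, rOuter)] <- suvRim
    suv[.inSphere(P, center, rCore)] <- suvCore
    suv
}

## ---- inter-session motion --------------------------------------------

## Divergence-free sinusoidal displacement (mm) at points P: each component
## depends only on one *other* axis, so the Jacobian has zero diagonal and
## the field is exactly divergence-free and invertible while
## 2*pi*A/lambda < 1.
.sinDisplacement <- function(P, amplitude, wavelength, phase) {
    if (amplitude == 0) return(matrix(0, nrow(P), 3))
    k <- 2 * pi / wavelength
    cbind(amplitude * sin(k * P[, 3] + phase[1]),
          amplitude * sin(k * P[, 1] + phase[2]),
          amplitude * sin(k * P[, 2] + phase[3]))
}

## Invert y -> y + d(y) by fixed-point iteration: given x, find z with
## z + d(z) = x. Contraction factor 2*pi*A/lambda < 0.9 by config validity.
.invertSinDisplacement <- function(X, amplitude, wavelength, phase,
                                   iterations = 25L) {
    if (amplitude == 0) return(X)
    Z <- X
    for (i in seq_len(iterations))
        Z <- X - .sinDisplacement(Z, amplitude, wavelength, phase)
    Z
}

## Forward patient motion of the case: rigid repositioning then deformation.
.forwardMotion <- function(cfg) {
    rigidTransform(rotation = cfg@rigidErrorDeg,
                   translation = cfg@rigidErrorMm,
                   center = c(0, 0, 0), degrees = TRUE)
}

.checkSphereInGrid <- function(center, r, geom, what) {
    b <- .gridBounds(geom)
    if (any(center - r < b["lo", ]) || any(center + r > b["hi", ]))
        stop(what, " (center ", paste(signif(center, 4), collapse = ", "),
             " mm, radius ", signif(r, 4), " mm) extends outside the grid")
}

#' Generate one synthetic phantom case
#'
#' Produces the four volumes (baseline and recurrence PET+CT), ground-truth
#' lesion masks and ground-truth transforms for one synthetic patient. The
#' recurrence session re-images the baseline anatomy after the configured
#' rigid repositioning and (NTP) sinusoidal deformation, replaces the lesion
#' with a recurrence lesion offset from the repositioned hotspot centroid,
#' and adds independent Gaussian noise to each volume.
#'
#' The stored \code{trueRigid}/\code{trueDeformation} map recurrence-grid
#' coordinates to baseline coordinates — the direction
#' \code{\link{registerRigid}} and \code{\link{registerElastic}} estimate —
#' and are exact (the patient motion is inverted analytically).
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return A \linkS4class{PhantomCase}.
#' @examples
#' case <- generateCase(phantomConfig("TP", noiseSd = 0, ctNoiseSd = 0))
#' case
#' @export
generateCase <- function(config) {
    validObject(config)
    cfg <- config
    geom <- volumeGeometry(cfg@gridShape, cfg@spacingMm)
    W <- .gridWorldCoords(geom)

    .checkSphereInGrid(cfg@lesionCenterMm, cfg@lesionRadiusMm, geom,
                       "baseline lesion")

    ## baseline session
    structures <- .anatomyStructures(cfg@anatomySeed)
    ctA <- .ctPaintLesion(.ctBackgroundAt(W, structures), W,
                          cfg@lesionCenterMm, cfg@lesionRadiusMm,
                          cfg@hotspotRadiusMm, structures)
    petA <- .petPaintLesion(.petBackgroundAt(W, cfg@suvBackground), W,
                            cfg@lesionCenterMm, cfg@lesionRadiusMm,
                            cfg@hotspotRadiusMm, cfg@suvRim, cfg@suvCore)

    ## forward motion and its pullback on the recurrence grid
    M <- .forwardMotion(cfg)
    Minv <- invertRigid(M)
    Z <- .invertSinDisplacement(W, cfg@deformationAmplitudeMm,
                                cfg@deformationWavelengthMm,
                                cfg@deformationPhase)
    Y <- transformPoints(Minv, Z)          # material baseline coords
    YR <- transformPoints(Minv, W)         # rigid-only pullback

    ## recurrence lesion center: forward image of the hotspot centroid
    ## (lesion and hotspot are concentric) plus the configured offset
    cHot <- cfg@lesionCenterMm
    fwd <- transformPoints(M, rbind(cHot))[1, ]
    fwd <- fwd + .sinDisplacement(rbind(fwd), cfg@deformationAmplitudeMm,
                                  cfg@deformationWavelengthMm,
                                  cfg@deformationPhase)[1, ]
    cRec <- fwd + cfg@recurrenceOffsetMm
    .checkSphereInGrid(cRec, cfg@recurrenceRadiusMm, geom, "recurrence lesion")

    ctR <- .ctPaintLesion(.ctBackgroundAt(Y, structures), W, cRec,
                          cfg@recurrenceRadiusMm, cfg@recurrenceCoreRadiusMm,
                          structures)
    petR <- .petPaintLesion(.petBackgroundAt(Y, cfg@suvBackground), W,
                            cRec, cfg@recurrenceRadiusMm,
                            cfg@recurrenceCoreRadiusMm,
                            cfg@suvRim, cfg@suvCore)

    ## independent noise per volume, one seeded stream, fixed draw order
    set.seed(cfg@seed)
    n <- nrow(W)
    if (cfg@noiseSd > 0) petA <- pmax(petA + rnorm(n, 0, cfg@noiseSd), 0)
    if (cfg@ctNoiseSd > 0) ctA <- ctA + rnorm(n, 0, cfg@ctNoiseSd)
    if (cfg@noiseSd > 0) petR <- pmax(petR + rnorm(n, 0, cfg@noiseSd), 0)
    if (cfg@ctNoiseSd > 0) ctR <- ctR + rnorm(n, 0, cfg@ctNoiseSd)

    d <- cfg@gridShape
    asVol <- function(v, modality)
        new("ScalarVolume", data = array(v, d), geometry = geom,
            modality = modality)

    ## ground truth in the registration direction (recurrence -> baseline):
    ## rigid part Minv, residual displacement Y - Minv(W) (zero when the
    ## case has no deformation)
    u <- Y - YR
    trueDef <- new("DeformationField",
                   displacement = array(u, c(d, 3L)), geometry = geom,
                   init = Minv, controlSpacing = NA_real_)

    maskA <- .inSphere(W, cfg@lesionCenterMm, cfg@lesionRadiusMm)
    maskR <- .inSphere(W, cRec, cfg@recurrenceRadiusMm)

    new("PhantomCase",
        petA = asVol(petA, "PET"), ctA = asVol(ctA, "CT"),
        petR = asVol(petR, "PET"), ctR = asVol(ctR, "CT"),
        trueRigid = Minv, trueDeformation = trueDef,
        trueLesionA = voiMask(array(maskA, d), geom, label = "lesion_A",
                              reference = "PET_A"),
        trueLesionR = voiMask(array(maskR, d), geom, label = "lesion_R",
                              reference = "PET_R"),
        positionGroup = cfg@positionGroup, caseId = cfg@caseId, config = cfg)
}

#' Write a phantom case to disk
#'
#' Writes the four volumes and the two ground-truth masks as NIfTI files and
#' a JSON sidecar with the ground-truth rigid parameters and the full
#' configuration into \code{dir}.
#'
#' @param case a \linkS4class{PhantomCase}.
#' @param dir output directory (created if absent).
#' @return The directory, invisibly.
#' @export
writePhantomCase <- function(case, dir) {
    stopifnot(is(case, "PhantomCase"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeVolume(case@petA, file.path(dir, "pet_a.nii.gz"))
    writeVolume(case@ctA, file.path(dir, "ct_a.nii.gz"))
    writeVolume(case@petR, file.path(dir, "pet_r.nii.gz"))
    writeVolume(case@ctR, file.path(dir, "ct_r.nii.gz"))
    writeMask(case@trueLesionA, file.path(dir, "lesion_a.nii.gz"))
    writeMask(case@trueLesionR, file.path(dir, "lesion_r.nii.gz"))
    cfg <- case@config
    slots <- methods::slotNames(class(cfg))
    cfgList <- setNames(lapply(slots, function(s) methods::slot(cfg, s)), slots)
    jsonlite::write_json(
        list(case_id = case@caseId, position_group = case@positionGroup,
             true_rigid = list(rotation_rad = case@trueRigid@rotation,
                               translation_mm = case@trueRigid@translation,
                               center_mm = case@trueRigid@center),
             config = cfgList),
        file.path(dir, "case.json"), digits = NA, auto_unbox = FALSE)
    invisible(dir)
}
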