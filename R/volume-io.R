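## NIfTI-1 I/O via RNifti. Geometry is carried in the sform (code 2) with
## pixdim kept consistent; the modality / VOI provenance is stored in the
## free-text `descrip` header field so masks and volumes round-trip through
## plain NIfTI files.

.geometryToXform <- function(geom) {
    aff <- diag(4)
    aff[1:3, 1:3] <- geom@direction %*% diag(geom@spacing)
    aff[1:3, 4] <- geom@origin
    aff
}

.xformToGeometry <- function(aff, dim) {
    M <- aff[1:3, 1:3]
    spacing <- sqrt(colSums(M^2))
    if (any(spacing <= 0))
        stop("volume has a degenerate affine (zero spacing)")
    direction <- M %*% diag(1 / spacing)
    if (max(abs(crossprod(direction) - diag(3))) > 1e-4)
        stop("volume direction matrix is not orthonormal; refusing to guess geometry")
    ## snap to exact orthonormality (header affines are single precision)
    sv <- svd(direction)
    direction <- sv$u %*% t(sv$v)
    volumeGeometry(dim, spacing, aff[1:3, 4], direction)
}

#' Read and write volumes as NIfTI-1
#'
#' \code{writeVolume} stores the image as float64 NIfTI (\code{.nii} or
#' \code{.nii.gz}) with the grid geometry in the sform; \code{readVolume}
#' reads it back. Round-tripping preserves voxel data bit-exactly and
#' geometry to better than 1e-6 mm (the header stores the affine in single
#' precision; exactly representable spacings/origins round-trip exactly).
#' A file without coded spatial orientation, or with more or fewer than
#' 3 dimensions, is rejected rather than silently defaulted.
#'
#' @param vol a \linkS4class{ScalarVolume}.
#' @param path file path ending in \code{.nii} or \code{.nii.gz}.
#' @param modality override the modality recorded in the file; one of
#'   \code{"PET"}, \code{"CT"}, \code{"OTHER"}.
#' @return \code{readVolume}: a \linkS4class{ScalarVolume};
#'   \code{writeVolume}: the path, invisibly.
#' @export
writeVolume <- function(vol, path) {
    stopifnot(is(vol, "ScalarVolume"))
    img <- RNifti::asNifti(vol@data)
    RNifti::pixdim(img) <- vol@geometry@spacing
    aff <- .geometryToXform(vol@geometry)
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
    img <- RNifti::asNifti(img, reference = list(descrip = paste0("hotspotOverlap;", vol@modality)))
    RNifti::writeNifti(img, path, datatype = "double")
    invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path, modality = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop("expected a 3D volume but '", basename(path), "' has ",
             length(d), " dimensions")
    hdr <- RNifti::niftiHeader(img)
    if (hdr$qform_code == 0 && hdr$sform_code == 0)
        stop("'", basename(path),
             "' carries no coded spatial geometry (qform and sform absent); ",
             "refusing to default spacing")
    geom <- .xformToGeometry(RNifti::xform(img, useQuaternionFirst = FALSE), d)
    if (is.null(modality)) {
        desc <- strsplit(hdr$descrip, ";", fixed = TRUE)[[1]]
        modality <- if (length(desc) >= 2 && desc[1] == "hotspotOverlap" &&
                        desc[2] %in% c("PET", "CT", "OTHER")) desc[2] else "OTHER"
    }
    arr <- as.array(img)
    attributes(arr) <- list(dim = d)
    new("ScalarVolume", data = arr, geometry = geom, modality = modality)
}

#' Read and write VOI masks as NIfTI-1
#'
#' Masks are stored as unsigned 8-bit NIfTI with the label and threshold
#' fraction recorded in the header description.
#'
#' @param mask a \linkS4class{VoiMask}.
#' @param path file path ending in \code{.nii} or \code{.nii.gz}.
#' @param reference reference-scan name to attach on read.
#' @return \code{readMask}: a \linkS4class{VoiMask}; \code{writeMask}: the
#'   path, invisibly.
#' @export
writeMask <- function(mask, path) {
    stopifnot(is(mask, "VoiMask"))
    arr <- array(as.integer(mask@mask), dim = dim(mask@mask))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- mask@geometry@spacing
    aff <- .geometryToXform(mask@geometry)
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
    desc <- paste("hotspotOverlap;MASK", mask@label,
                  format(mask@thresholdFraction), sep = ";")
    img <- RNifti::asNifti(img, reference = list(descrip = desc))
    RNifti::writeNifti(img, path, datatype = "uint8")
    invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path, reference = "") {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop("expected a 3D mask but '", basename(path), "' has ",
             length(d), " dimensions")
    hdr <- RNifti::niftiHeader(img)
    if (hdr$qform_code == 0 && hdr$sform_code == 0)
        stop("'", basename(path), "' carries no coded spatial geometry")
    geom <- .xformToGeometry(RNifti::xform(img, useQuaternionFirst = FALSE), d)
    label <- "mask"; tf <- NA_real_
    desc <- strsplit(hdr$descrip, ";", fixed = TRUE)[[1]]
    if (length(desc) >= 4 && desc[1] == "hotspotOverlap" && desc[2] == "MASK") {
        label <- desc[3]
        tf <- suppressWarnings(as.numeric(desc[4]))
    }
    arr <- as.array(img)
    attributes(arr) <- list(dim = d)
    voiMask(arr != 0, geom, label = label, thresholdFraction = tf,
            reference = reference)
}

.overlapKeyCols <- c("case_id", "method", "a_label", "r_label")
.overlapIndexCols <- c("dice", "jaccard", "of", "common_over_a", "common_over_r")
.overlapTableCols <- c("case_id", "position_group", "method", "a_label",
                       "r_label", .overlapIndexCols,
                       "vol_a_cc", "vol_r_cc", "vol_common_cc")

#' Serialize overlap results to CSV
#'
#' One row per (case, method, baseline threshold, recurrence threshold);
#' columns are the five overlap indices and the three component volumes.
#' Values round-trip losslessly to at least 12 significant digits.
#'
#' @param results data frame of overlap results as returned by
#'   \code{\link{overlapMatrix}} (rows may be concatenated across cases).
#' @param path CSV file path.
#' @return \code{readOverlapTable}: the results data frame;
#'   \code{writeOverlapTable}: the path, invisibly.
#' @export
writeOverlapTable <- function(results, path) {
    if (!is.data.frame(results) || nrow(results) == 0L)
        stop("results must be a non-empty data frame")
    missingCols <- setdiff(.overlapTableCols, names(results))
    if (length(missingCols))
        stop("results lack columns: ", paste(missingCols, collapse = ", "))
    key <- do.call(paste, c(results[.overlapKeyCols], sep = "\r"))
    if (anyDuplicated(key))
        stop("duplicate (case, method, thresholds) rows in results")
    out <- results[.overlapTableCols]
    for (cn in names(out))
        if (is.numeric(out[[cn]]))
            out[[cn]] <- sprintf("%.15g", out[[cn]])
    write.csv(out, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' @rdname writeOverlapTable
#' @export
readOverlapTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.csv(path, stringsAsFactors = FALSE)
    missingCols <- setdiff(.overlapTableCols, names(df))
    if (length(missingCols))
        stop("overlap table lacks columns: ", paste(missingCols, collapse = ", "))
    num <- c(.overlapIndexCols, "vol_a_cc", "vol_r_cc", "vol_common_cc")
    for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
    df
}

#' Serialize transforms
#'
#' Rigid transforms are written as a small JSON document (rotation in
#' radians, translation and center in mm). Deformation fields are written as
#' a 4D NIfTI displacement field (mm) plus a JSON sidecar holding the rigid
#' initialization and the control spacing.
#'
#' @param transform a \linkS4class{RigidTransform} or
#'   \linkS4class{DeformationField}.
#' @param path for rigid transforms a \code{.json} path; for deformation
#'   fields a path prefix (writes \code{<prefix>.nii.gz} and
#'   \code{<prefix>.json}).
#' @return \code{readTransform}: the transform object;
#'   \code{writeTransform}: the path, invisibly.
#' @export
writeTransform <- function(transform, path) {
    if (is(transform, "RigidTransform")) {
        jsonlite::write_json(list(type = "rigid",
                                  rotation_rad = transform@rotation,
                                  translation_mm = transform@translation,
                                  center_mm = transform@center),
                             path, digits = NA, auto_unbox = FALSE)
    } else if (is(transform, "DeformationField")) {
        img <- RNifti::asNifti(transform@displacement)
        RNifti::pixdim(img) <- transform@geometry@spacing
        aff <- .geometryToXform(transform@geometry)
        img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
        img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
        RNifti::writeNifti(img, paste0(path, ".nii.gz"), datatype = "double")
        jsonlite::write_json(list(type = "deformation",
                                  init = list(rotation_rad = transform@init@rotation,
                                              translation_mm = transform@init@translation,
                                              center_mm = transform@init@center),
                                  control_spacing_mm = transform@controlSpacing,
                                  field = basename(paste0(path, ".nii.gz"))),
                             paste0(path, ".json"), digits = NA,
                             auto_unbox = FALSE)
    } else stop("unsupported transform class: ", class(transform)[1])
    invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
    jsonPath <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
    if (!file.exists(jsonPath)) stop("file not found: ", jsonPath)
    meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
    if (identical(meta$type, "rigid")) {
        new("RigidTransform", rotation = meta$rotation_rad,
            translation = meta$translation_mm, center = meta$center_mm)
    } else if (identical(meta$type, "deformation")) {
        fieldPath <- file.path(dirname(jsonPath), meta$field)
        img <- RNifti::readNifti(fieldPath)
        d <- dim(img)
        if (length(d) != 4L || d[4] != 3L)
            stop("deformation field must be a 4D NIfTI with 3 components")
        geom <- .xformToGeometry(RNifti::xform(img, useQuaternionFirst = FALSE),
                                 d[1:3])
        arr <- as.array(img)
        attributes(arr) <- list(dim = d)
        new("DeformationField", displacement = arr, geometry = geom,
            init = new("RigidTransform", rotation = meta$init$rotation_rad,
                       translation = meta$init$translation_mm,
                       center = meta$init$center_mm),
            controlSpacing = meta$control_spacing_mm)
    } else stop("unrecognized transform file: ", jsonPath)
}
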