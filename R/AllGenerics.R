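#' Accessors for image containers
#'
#' \code{geometry} returns the \linkS4class{VolumeGeometry} of a volume,
#' mask or deformation field; \code{voxelData} the raw array;
#' \code{modality} the modality string; \code{voiLabel} a mask's label;
#' \code{volumeCc} the physical volume (cc) of a mask
#' (voxel count x voxel volume / 1000).
#'
#' @param x a \linkS4class{ScalarVolume}, \linkS4class{VoiMask} or
#'   \linkS4class{DeformationField}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setMethod("geometry", "ScalarVolume", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("geometry", "VoiMask", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("geometry", "DeformationField", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("geometry", "VolumeGeometry", function(x) x)

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setMethod("voxelData", "ScalarVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voxelData", "VoiMask", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setMethod("modality", "ScalarVolume", function(x) x@modality)

#' @rdname accessors
#' @export
setGeneric("voiLabel", function(x) standardGeneric("voiLabel"))

#' @rdname accessors
#' @export
setMethod("voiLabel", "VoiMask", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("volumeCc", function(x) standardGeneric("volumeCc"))

#' @rdname accessors
#' @export
setMethod("volumeCc", "VoiMask", function(x)
    sum(x@mask) * .voxelVolumeCc(x@geometry))

#' Construct a scalar volume
#'
#' @param data 3D numeric array.
#' @param geometry a \linkS4class{VolumeGeometry} (defaults to the array's
#'   dimensions at the given spacing, centered on the world origin).
#' @param spacing,origin used only when \code{geometry} is missing.
#' @param modality \code{"PET"}, \code{"CT"} or \code{"OTHER"}.
#' @return A \linkS4class{ScalarVolume}.
#' @export
scalarVolume <- function(data, geometry = NULL, spacing = c(1, 1, 1),
                         origin = NULL, modality = "OTHER") {
    if (is.null(geometry)) {
        d <- dim(data)
        if (is.null(origin)) origin <- -(d - 1) * spacing / 2
        geometry <- volumeGeometry(d, spacing, origin)
    }
    new("ScalarVolume", data = data, geometry = geometry, modality = modality)
}

#' Construct a VOI mask
#'
#' @param mask 3D logical array.
#' @param geometry a \linkS4class{VolumeGeometry}.
#' @param label VOI label (e.g. \code{"A_40"}).
#' @param thresholdFraction relative-SUVmax fraction in (0,1), or \code{NA}.
#' @param reference name of the scan the mask lives on.
#' @return A \linkS4class{VoiMask}.
#' @export
voiMask <- function(mask, geometry, label = "mask",
                    thresholdFraction = NA_real_, reference = "") {
    storage.mode(mask) <- "logical"
    new("VoiMask", mask = mask, geometry = geometry, label = label,
        thresholdFraction = as.numeric(thresholdFraction),
        reference = reference)
}

setMethod("show", "VolumeGeometry", function(object) {
    cat(sprintf("VolumeGeometry: %s voxels, spacing %s mm, origin %s mm\n",
                paste(object@dim, collapse = "x"),
                paste(signif(object@spacing, 4), collapse = "x"),
                paste(signif(object@origin, 4), collapse = ", ")))
})

setMethod("show", "ScalarVolume", function(object) {
    r <- range(object@data)
    cat(sprintf("ScalarVolume (%s): %s voxels, range [%.3g, %.3g]\n",
                object@modality, paste(object@geometry@dim, collapse = "x"),
                r[1], r[2]))
})

setMethod("show", "VoiMask", function(object) {
    cat(sprintf("VoiMask '%s': %d voxels, %.3f cc%s\n", object@label,
                sum(object@mask), volumeCc(object),
                if (is.na(object@thresholdFraction)) "" else
                    sprintf(" (threshold %.0f%% SUVmax)",
                            100 * object@thresholdFraction)))
})

setMethod("show", "RigidTransform", function(object) {
    cat(sprintf(
        "RigidTransform: rot (%s) deg, trans (%s) mm, center (%s) mm\n",
        paste(signif(object@rotation * 180 / pi, 4), collapse = ", "),
        paste(signif(object@translation, 4), collapse = ", "),
        paste(signif(object@center, 4), collapse = ", ")))
})

setMethod("show", "DeformationField", function(object) {
    mag <- sqrt(rowSums(matrix(object@displacement,
                               ncol = 3)^2))
    cat(sprintf(
        "DeformationField on %s grid: |u| max %.2f mm, mean %.2f mm (+ rigid init)\n",
        paste(object@geometry@dim, collapse = "x"), max(mag), mean(mag)))
})

setMethod("show", "UptakeMetrics", function(object) {
    cat(sprintf(
        "UptakeMetrics: SUVmax %.2f, SUVmean %.2f, MTV %.2f cc, TLG %.2f g\n",
        object@suvMax, object@suvMean, object@mtvCc, object@tlgG))
})

setMethod("show", "PhantomCase", function(object) {
    cat(sprintf("PhantomCase '%s' (%s): grid %s, lesion %.2f cc -> recurrence %.2f cc\n",
                object@caseId, object@positionGroup,
                paste(object@petA@geometry@dim, collapse = "x"),
                volumeCc(object@trueLesionA), volumeCc(object@trueLesionR)))
})

setMethod("show", "StudyReport", function(object) {
    cat("StudyReport\n")
    cat(sprintf("  cases: %d  scans: %d  VOIs: %d  index values: %d\n",
                object@counts["nCases"], object@counts["nScans"],
                object@counts["nVois"], object@counts["nIndexValues"]))
    cat(sprintf("  overlap rows: %d  comparisons: %s\n",
                nrow(object@overlaps),
                paste(names(object@comparisons), collapse = ", ")))
})
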