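#' Construct a grid geometry
#'
#' @param dim integer(3) voxel counts.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) world coordinate (mm) of the first voxel center.
#'   The default centers the grid on the world origin.
#' @param direction 3x3 orthonormal direction-cosine matrix.
#' @return A \linkS4class{VolumeGeometry}.
#' @examples
#' volumeGeometry(c(64L, 64L, 48L), c(2, 2, 3))
#' @export
volumeGeometry <- function(dim, spacing, origin = -(dim - 1) * spacing / 2,
                           direction = diag(3)) {
    new("VolumeGeometry", dim = as.integer(dim), spacing = as.numeric(spacing),
        origin = as.numeric(origin), direction = direction)
}

.isIdentityDirection <- function(geom)
    max(abs(geom@direction - diag(3))) < 1e-9

.stopifnotAxisAligned <- function(geom, what) {
    if (!.isIdentityDirection(geom))
        stop(what, " requires an axis-aligned (identity direction) grid")
}

#' @rdname volumeGeometry
#' @param x,y objects with a geometry.
#' @param tol tolerance in mm for origin/spacing comparison.
#' @export
geometriesMatch <- function(x, y, tol = 1e-6) {
    gx <- geometry(x); gy <- geometry(y)
    identical(gx@dim, gy@dim) &&
        max(abs(gx@spacing - gy@spacing)) < tol &&
        max(abs(gx@origin - gy@origin)) < tol &&
        max(abs(gx@direction - gy@direction)) < tol
}

## World coordinates (mm) of every voxel center, as an N x 3 matrix in
## column-major voxel order (x fastest).
.gridWorldCoords <- function(geom) {
    d <- geom@dim
    i <- (seq_len(d[1]) - 1) * geom@spacing[1]
    j <- (seq_len(d[2]) - 1) * geom@spacing[2]
    k <- (seq_len(d[3]) - 1) * geom@spacing[3]
    idx <- cbind(rep(i, times = d[2] * d[3]),
                 rep(rep(j, each = d[1]), times = d[3]),
                 rep(k, each = d[1] * d[2]))
    if (.isIdentityDirection(geom))
        sweep(idx, 2, geom@origin, "+")
    else
        sweep(idx %*% t(geom@direction), 2, geom@origin, "+")
}

## 0-based voxel index -> world (mm); ijk an N x 3 matrix.
.voxelToWorld <- function(geom, ijk) {
    s <- sweep(ijk, 2, geom@spacing, "*")
    if (!.isIdentityDirection(geom)) s <- s %*% t(geom@direction)
    sweep(s, 2, geom@origin, "+")
}

## Physical bounds (voxel-center extent) of the grid: 2 x 3 matrix lo/hi.
.gridBounds <- function(geom) {
    lo <- geom@origin
    hi <- geom@origin + (geom@dim - 1) * geom@spacing
    rbind(lo = pmin(lo, hi), hi = pmax(lo, hi))
}

.voxelVolumeCc <- function(geom) prod(geom@spacing) / 1000

#' Axis-aligned region of interest in world coordinates
#'
#' @param lo,hi numeric(3) opposite corners of the box, mm.
#' @return A 2 x 3 matrix with rows \code{lo} and \code{hi}.
#' @export
regionBox <- function(lo, hi) {
    stopifnot(length(lo) == 3L, length(hi) == 3L, all(is.finite(c(lo, hi))))
    m <- rbind(lo = pmin(lo, hi), hi = pmax(lo, hi))
    colnames(m) <- c("x", "y", "z")
    m
}

## Logical vector over the grid: voxel centers inside the region box.
.regionIndicator <- function(geom, region) {
    .stopifnotAxisAligned(geom, "region selection")
    w <- .gridWorldCoords(geom)
    w[, 1] >= region["lo", 1] & w[, 1] <= region["hi", 1] &
    w[, 2] >= region["lo", 2] & w[, 2] <= region["hi", 2] &
    w[, 3] >= region["lo", 3] & w[, 3] <= region["hi", 3]
}

#' Bounding box of a mask, expanded by a margin
#'
#' @param mask a \linkS4class{VoiMask}.
#' @param marginMm margin added on each side, mm.
#' @return A region box (2 x 3 matrix, mm), clipped to the grid extent.
#' @export
maskBoundingBox <- function(mask, marginMm = 0) {
    stopifnot(is(mask, "VoiMask"))
    if (!any(mask@mask)) stop("mask is empty; no bounding box")
    geom <- mask@geometry
    .stopifnotAxisAligned(geom, "maskBoundingBox")
    idx <- which(mask@mask, arr.ind = TRUE) - 1L
    lo <- .voxelToWorld(geom, rbind(apply(idx, 2, min)))[1, ] - marginMm
    hi <- .voxelToWorld(geom, rbind(apply(idx, 2, max)))[1, ] + marginMm
    b <- .gridBounds(geom)
    regionBox(pmax(lo, b["lo", ]), pmin(hi, b["hi", ]))
}

## Centroid (mm) of a mask.
.maskCentroid <- function(mask) {
    idx <- which(mask@mask, arr.ind = TRUE) - 1L
    colMeans(.voxelToWorld(mask@geometry, idx))
}
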