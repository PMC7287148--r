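#' Construct a rigid transform
#'
#' @param rotation numeric(3) Euler angles about x, y, z. Interpreted in
#'   degrees when \code{degrees = TRUE} (default), else radians. The rotation
#'   matrix is \code{Rz Ry Rx}.
#' @param translation numeric(3), mm.
#' @param center rotation center, mm.
#' @param degrees logical; are the angles given in degrees?
#' @return A \linkS4class{RigidTransform}.
#' @examples
#' rigidTransform(rotation = c(0, 0, 5), translation = c(2, 0, 0))
#' @export
rigidTransform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0), degrees = TRUE) {
    rot <- as.numeric(rotation)
    if (degrees) rot <- rot * pi / 180
    new("RigidTransform", rotation = rot, translation = as.numeric(translation),
        center = as.numeric(center))
}

## ZYX Euler rotation matrix: R = Rz(g) %*% Ry(b) %*% Rx(a).
.eulerToMatrix <- function(angles) {
    a <- angles[1]; b <- angles[2]; g <- angles[3]
    Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
}

## Inverse extraction for the ZYX convention above; safe away from
## gimbal lock (|beta| < 90 deg), which covers every transform this
## package produces (repositioning errors are a few degrees).
.matrixToEuler <- function(R) {
    b <- asin(pmin(1, pmax(-1, -R[3, 1])))
    if (abs(cos(b)) < 1e-9)
        stop("Euler extraction near gimbal lock is not supported")
    a <- atan2(R[3, 2], R[3, 3])
    g <- atan2(R[2, 1], R[1, 1])
    c(a, b, g)
}

## Affine form: p' = A p + b.
.rigidToAffine <- function(t) {
    A <- .eulerToMatrix(t@rotation)
    b <- t@center + t@translation - A %*% t@center
    list(A = A, b = as.numeric(b))
}

#' Apply a rigid transform to world points
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param points N x 3 matrix of world coordinates (mm).
#' @return N x 3 matrix of mapped coordinates.
#' @export
transformPoints <- function(transform, points) {
    stopifnot(is(transform, "RigidTransform"))
    aff <- .rigidToAffine(transform)
    sweep(points %*% t(aff$A), 2, aff$b, "+")
}

#' Invert or compose rigid transforms
#'
#' \code{invertRigid(t)} returns the inverse mapping; \code{composeRigid(s, t)}
#' returns the transform applying \code{t} first, then \code{s}. The result
#' keeps the \code{center} of the first argument.
#'
#' @param transform,s,t \linkS4class{RigidTransform}s.
#' @return A \linkS4class{RigidTransform}.
#' @export
invertRigid <- function(transform) {
    aff <- .rigidToAffine(transform)
    Ai <- t(aff$A)
    bi <- -Ai %*% aff$b
    .affineToRigid(Ai, as.numeric(bi), transform@center)
}

#' @rdname invertRigid
#' @export
composeRigid <- function(s, t) {
    as_ <- .rigidToAffine(s); at_ <- .rigidToAffine(t)
    A <- as_$A %*% at_$A
    b <- as.numeric(as_$A %*% at_$b + as_$b)
    .affineToRigid(A, b, s@center)
}

.affineToRigid <- function(A, b, center) {
    rot <- .matrixToEuler(A)
    tr <- b + as.numeric(A %*% center) - center
    new("RigidTransform", rotation = rot, translation = tr, center = center)
}

## Largest displacement (mm) the transform induces over a grid's corners;
## used to summarize how far from identity a recovered transform is.
.rigidMaxDisplacement <- function(transform, geom) {
    b <- .gridBounds(geom)
    corners <- as.matrix(expand.grid(b[, 1], b[, 2], b[, 3]))
    max(sqrt(rowSums((transformPoints(transform, corners) - corners)^2)))
}
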