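## Intensity-based mono-modal registration of the two CT sessions.
##
## Rigid (RR): 6-parameter transform minimizing the mean squared intensity
## difference over a focus region around the tumor, by Nelder-Mead over a
## 3-level coarse-to-fine sampling pyramid, starting from identity.
##
## Elastic (ER): the rigid result composed with a free-form displacement
## parameterized on a coarse control-point lattice (trilinear, i.e.
## first-order B-spline, interpolation between control points) with a
## first-difference smoothness penalty, minimized by L-BFGS-B with analytic
## gradients, coarse-to-fine over lattice spacings. Both methods are fully
## deterministic.

#' Registration tuning parameters
#'
#' @param strides coarse-to-fine voxel sampling strides of the rigid stage.
#' @param maxit Nelder-Mead iteration caps per stride level.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param ctrlSpacingMm control-point spacing of the free-form lattice, mm.
#' @param lambda smoothness weight of the free-form stage, relative to the
#'   intensity variance of the fixed image over the focus region.
#' @param ffdMaxit L-BFGS-B iteration cap per free-form smoothing stage.
#' @param ffdStride voxel sampling stride of the free-form stage.
#' @param ffdSigmaMm Gaussian image-smoothing continuation schedule of the
#'   free-form stage (mm): the problem is solved at each smoothing scale in
#'   turn, warm-starting the next, which widens the capture range across
#'   sharp edges before the sharp images fix the details.
#' @param ffdClamp intensity window applied to both images in the free-form
#'   metric (default the CT soft-tissue window, HU); bounds the influence
#'   of very-high-contrast air and bone edges so that tissue texture is not
#'   drowned out. \code{NULL} disables windowing.
#' @return A named list of control parameters.
#' @export
registrationControl <- function(strides = c(4L, 2L, 1L),
                                maxit = c(2000L, 1000L, 800L),
                                reltol = 1e-7,
                                ctrlSpacingMm = 16,
                                lambda = 3e-4,
                                ffdMaxit = 200L,
                                ffdStride = 2L,
                                ffdSigmaMm = c(8, 3, 0),
                                ffdClamp = c(-150, 250)) {
    stopifnot(length(strides) == length(maxit), all(strides >= 1L),
              length(ctrlSpacingMm) == 1L)
    list(strides = as.integer(strides), maxit = as.integer(maxit),
         reltol = reltol, ctrlSpacingMm = ctrlSpacingMm, lambda = lambda,
         ffdMaxit = as.integer(ffdMaxit), ffdStride = as.integer(ffdStride),
         ffdSigmaMm = ffdSigmaMm, ffdClamp = ffdClamp)
}

## Region voxels of `geom` at a given stride: list(world = N x 3 coords,
## sel = linear indices into the full grid).
.regionSample <- function(geom, region, stride) {
    inRegion <- .regionIndicator(geom, region)
    sel <- which(inRegion)
    if (!length(sel)) stop("focus region contains no voxel centers")
    d <- geom@dim
    i0 <- (sel - 1L) %% d[1]
    j0 <- ((sel - 1L) %/% d[1]) %% d[2]
    k0 <- (sel - 1L) %/% (d[1] * d[2])
    if (stride > 1L) {
        keep <- i0 %% stride == 0L & j0 %% stride == 0L & k0 %% stride == 0L
        sel <- sel[keep]
        i0 <- i0[keep]; j0 <- j0[keep]; k0 <- k0[keep]
    }
    list(world = .voxelToWorld(geom, cbind(i0, j0, k0)), sel = sel)
}

.gridWorldCenter <- function(geom) colMeans(.gridBounds(geom))

#' Rigid registration of two CT volumes
#'
#' Estimates the 6-parameter rigid transform that maps fixed-grid world
#' coordinates onto the moving volume so that the moving intensities sampled
#' there match the fixed intensities over the focus region (mean squared
#' difference metric, coarse-to-fine Nelder-Mead from identity). When the
#' fixed image is the recurrence CT and the moving image the baseline CT,
#' the result maps recurrence space to baseline space.
#'
#' @param fixed,moving \linkS4class{ScalarVolume}s of the same modality.
#' @param focusRegion 2 x 3 lo/hi matrix (mm) around the tumor over which
#'   the metric is evaluated.
#' @param control see \code{\link{registrationControl}}.
#' @return A \linkS4class{RigidTransform} (rotation center at the fixed-grid
#'   center), with attributes \code{metric} (final mean squared difference)
#'   and \code{counts} (function evaluations per level).
#' @export
registerRigid <- function(fixed, moving, focusRegion,
                          control = registrationControl()) {
    stopifnot(is(fixed, "ScalarVolume"), is(moving, "ScalarVolume"))
    .stopifnotAxisAligned(fixed@geometry, "registerRigid")
    .stopifnotAxisAligned(moving@geometry, "registerRigid")
    center <- .gridWorldCenter(fixed@geometry)
    mg <- moving@geometry
    fill <- min(moving@data)
    par <- rep(0, 6)
    counts <- integer(0)
    value <- NA_real_
    for (lev in seq_along(control$strides)) {
        smp <- .regionSample(fixed@geometry, focusRegion, control$strides[lev])
        fvals <- as.numeric(fixed@data)[smp$sel]
        fn <- function(p) {
            t <- new("RigidTransform", rotation = p[1:3], translation = p[4:6],
                     center = center)
            .cppMseAt(fvals, moving@data, mg@dim, mg@spacing, mg@origin,
                      transformPoints(t, smp$world), fill)
        }
        ## Nelder-Mead with restarts: a degenerate simplex (code 10) is
        ## restarted from the current best point with a fresh simplex
        nEval <- 0L
        for (attempt in 1:4) {
            opt <- optim(par, fn, method = "Nelder-Mead",
                         control = list(maxit = control$maxit[lev],
                                        reltol = control$reltol,
                                        parscale = c(rep(0.01, 3), rep(1, 3))))
            par <- opt$par
            nEval <- nEval + opt$counts[1]
            if (opt$convergence == 0) break
        }
        if (opt$convergence != 0)
            stop(sprintf(paste0("rigid registration failed to converge at ",
                                "level %d (code %d, metric %.6g after %d ",
                                "evaluations)"),
                         lev, opt$convergence, opt$value, nEval))
        counts <- c(counts, nEval)
        value <- opt$value
    }
    out <- new("RigidTransform", rotation = par[1:3], translation = par[4:6],
               center = center)
    attr(out, "metric") <- value
    attr(out, "counts") <- counts
    out
}

## Smoothness penalty on the control lattice: scaled sum of squared first
## differences between neighboring control displacements. Returns the value
## and its gradient w.r.t. the (nc x 3) displacement matrix.
.ffdPenalty <- function(disp, cdim, csp, weight) {
    arr <- array(disp, c(cdim, 3L))
    val <- 0
    grad <- array(0, c(cdim, 3L))
    n <- dim(arr)
    slice <- function(x, axis, idx) {
        ix <- lapply(seq_len(4), function(a)
            if (a == axis) idx else seq_len(n[a]))
        do.call(`[`, c(list(x), ix, drop = FALSE))
    }
    sliceAssign <- function(x, axis, idx, value) {
        ix <- lapply(seq_len(4), function(a)
            if (a == axis) idx else seq_len(n[a]))
        do.call(`[<-`, c(list(x), ix, list(value)))
    }
    for (axis in 1:3) {
        if (cdim[axis] < 2L) next
        hi <- 2:n[axis]
        lo <- 1:(n[axis] - 1L)
        D <- slice(arr, axis, hi) - slice(arr, axis, lo)
        w <- weight / csp[axis]^2
        val <- val + w * sum(D^2)
        grad <- sliceAssign(grad, axis, hi, slice(grad, axis, hi) + 2 * w * D)
        grad <- sliceAssign(grad, axis, lo, slice(grad, axis, lo) - 2 * w * D)
    }
    list(value = val, grad = matrix(grad, ncol = 3L))
}

#' Free-form deformable registration
#'
#' Refines a rigid initialization with a smooth free-form displacement on a
#' cubic B-spline control-point lattice covering the focus region,
#' minimizing the mean squared intensity difference (over an intensity
#' window) plus a smoothness penalty with L-BFGS-B and analytic gradients,
#' warm-started over a Gaussian smoothing continuation schedule. The returned
#' field composes with the initialization: the total mapping of a
#' fixed-grid point x is \code{init(x) + u(x)}. The final intensity metric
#' never exceeds the metric under the initialization alone (the optimizer
#' starts from the zero field and is monotone; if no improvement is found
#' the zero field is returned).
#'
#' @inheritParams registerRigid
#' @param init a \linkS4class{RigidTransform} initialization (typically from
#'   \code{\link{registerRigid}}).
#' @param focusRegion 2 x 3 lo/hi matrix (mm); the control lattice covers
#'   this region plus one control spacing. Defaults to the whole fixed grid.
#' @return A \linkS4class{DeformationField} on the fixed grid, with
#'   attributes \code{metric} (final mean squared difference, penalty
#'   excluded) and \code{initMetric} (metric under \code{init} alone).
#' @export
registerElastic <- function(fixed, moving, init,
                            focusRegion = .gridBounds(fixed@geometry),
                            control = registrationControl()) {
    stopifnot(is(fixed, "ScalarVolume"), is(moving, "ScalarVolume"),
              is(init, "RigidTransform"))
    .stopifnotAxisAligned(fixed@geometry, "registerElastic")
    .stopifnotAxisAligned(moving@geometry, "registerElastic")
    mg <- moving@geometry
    smp <- .regionSample(fixed@geometry, focusRegion, control$ffdStride)
    base <- transformPoints(init, smp$world)

    clampArr <- function(a) {
        if (is.null(control$ffdClamp)) a
        else pmin(pmax(a, control$ffdClamp[1]), control$ffdClamp[2])
    }
    fixC <- array(clampArr(fixed@data), dim(fixed@data))
    movC <- array(clampArr(moving@data), dim(moving@data))
    fill <- min(movC)
    penWeight <- control$lambda *
        max(stats::var(as.numeric(fixC)[smp$sel]), 1e-12)

    smoothArr <- function(a, sigmaMm, g) {
        if (sigmaMm <= 0) a
        else array(.cppSmoothGaussian(a, g@dim, sigmaMm / g@spacing), g@dim)
    }
    mseOf <- function(cdim, csp, corg, disp, fvals, mov)
        .cppFfdMseGrad(fvals, base, smp$world, mov,
                       mg@dim, mg@spacing, mg@origin,
                       cdim, csp, corg, disp, fill)

    ## cubic B-spline support needs two control points beyond the region
    csp <- rep(control$ctrlSpacingMm, 3)
    corg <- focusRegion["lo", ] - 2 * csp
    hi <- focusRegion["hi", ] + 2 * csp
    cdim <- pmax(4L, as.integer(ceiling((hi - corg) / csp)) + 1L)
    nc <- prod(cdim)

    fvalsRaw <- as.numeric(fixC)[smp$sel]
    initMetric <- mseOf(cdim, csp, corg, matrix(0, nc, 3), fvalsRaw,
                        movC)$cost
    par <- rep(0, nc * 3L)
    for (sigma in control$ffdSigmaMm) {
        fvalsS <- as.numeric(smoothArr(fixC, sigma, fixed@geometry))[smp$sel]
        movS <- smoothArr(movC, sigma, moving@geometry)
        cache <- new.env(parent = emptyenv())
        evalAt <- function(p) {
            if (!is.null(cache$par) && identical(cache$par, p))
                return(cache$res)
            disp <- matrix(p, ncol = 3L)
            mseRes <- mseOf(cdim, csp, corg, disp, fvalsS, movS)
            pen <- .ffdPenalty(disp, cdim, csp, penWeight)
            cache$par <- p
            cache$res <- list(value = mseRes$cost + pen$value,
                              grad = as.numeric(mseRes$grad + pen$grad))
            cache$res
        }
        opt <- optim(par, function(p) evalAt(p)$value,
                     function(p) evalAt(p)$grad, method = "L-BFGS-B",
                     control = list(maxit = control$ffdMaxit, factr = 1e5))
        ## an abnormal line-search exit at the end of convergence is a
        ## known benign L-BFGS-B termination; keep the last iterate
        lnsrch <- opt$convergence == 52 && grepl("LNSRCH", opt$message)
        if (opt$convergence != 0 && opt$convergence != 1 && !lnsrch)
            stop(sprintf(paste0("free-form registration failed (code %d, %s; ",
                                "metric %.6g after %d evaluations)"),
                         opt$convergence, opt$message, opt$value,
                         opt$counts[1]))
        par <- opt$par
    }
    disp <- matrix(par, ncol = 3L)
    finalMse <- mseOf(cdim, csp, corg, disp, fvalsRaw, movC)$cost

    W <- .gridWorldCoords(fixed@geometry)
    if (finalMse > initMetric) {      # no improvement over the rigid init
        dense <- matrix(0, nrow(W), 3L)
        finalMse <- initMetric
    } else {
        dense <- .cppCtrlDispAt(W, cdim, csp, corg, disp)
    }
    out <- new("DeformationField",
               displacement = array(dense, c(fixed@geometry@dim, 3L)),
               geometry = fixed@geometry, init = init,
               controlSpacing = control$ctrlSpacingMm)
    attr(out, "metric") <- finalMse
    attr(out, "initMetric") <- initMetric
    out
}

#' Resample a volume or mask through a transform
#'
#' Samples the input at the transformed coordinates of every target-grid
#' voxel: scalar volumes by trilinear interpolation, masks by trilinear
#' interpolation of the binary field followed by thresholding at 0.5.
#' Voxels mapping outside the input grid get 0. An identity transform on a
#' matching grid reproduces the input bit-exactly.
#'
#' @param x a \linkS4class{ScalarVolume} or \linkS4class{VoiMask}.
#' @param transform a \linkS4class{RigidTransform} or
#'   \linkS4class{DeformationField}.
#' @param target the output grid: a \linkS4class{VolumeGeometry} or an
#'   object with one. Defaults to the grid of \code{x} for rigid transforms
#'   and to the transform's own fixed grid for deformation fields (which
#'   must match the requested target).
#' @return The resampled object on the target grid.
#' @export
applyTransform <- function(x, transform, target = NULL) {
    isMask <- is(x, "VoiMask")
    if (!isMask && !is(x, "ScalarVolume"))
        stop("x must be a ScalarVolume or VoiMask")
    xg <- geometry(x)
    .stopifnotAxisAligned(xg, "applyTransform")
    if (is(transform, "RigidTransform")) {
        tg <- if (is.null(target)) xg else geometry(target)
        W <- .gridWorldCoords(tg)
        C <- transformPoints(transform, W)
    } else if (is(transform, "DeformationField")) {
        tg <- if (is.null(target)) transform@geometry else geometry(target)
        if (!identical(tg@dim, transform@geometry@dim) ||
            max(abs(tg@spacing - transform@geometry@spacing)) > 1e-6 ||
            max(abs(tg@origin - transform@geometry@origin)) > 1e-6)
            stop("grid mismatch: deformation field is defined on a different ",
                 "target grid")
        W <- .gridWorldCoords(tg)
        C <- transformPoints(transform@init, W) +
            matrix(transform@displacement, ncol = 3L)
    } else stop("unsupported transform class: ", class(transform)[1])
    src <- if (isMask) array(as.double(x@mask), dim = dim(x@mask)) else x@data
    vals <- .cppInterpTrilinear(src, xg@dim, xg@spacing, xg@origin, C, 0)
    if (isMask)
        voiMask(array(vals >= 0.5, tg@dim), tg, label = x@label,
                thresholdFraction = x@thresholdFraction,
                reference = x@reference)
    else
        new("ScalarVolume", data = array(vals, tg@dim), geometry = tg,
            modality = x@modality)
}
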