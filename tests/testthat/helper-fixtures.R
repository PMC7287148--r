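## Shared fixtures, generated in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, make) {
    if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make()
    .fixtures[[key]]
}

## A clean, noiseless, perfectly aligned case whose recurrence lesion
## equals the baseline lesion.
identityCase <- function() fixture("identity", function()
    generateCase(phantomConfig("TP", noiseSd = 0, ctNoiseSd = 0,
                               rigidErrorDeg = c(0, 0, 0),
                               rigidErrorMm = c(0, 0, 0),
                               recurrenceOffsetMm = c(0, 0, 0),
                               recurrenceRadiusMm = 13,
                               recurrenceCoreRadiusMm = 6)))

## A noiseless case used as a registration target.
cleanCase <- function() fixture("clean", function()
    generateCase(phantomConfig("TP", noiseSd = 0, ctNoiseSd = 0)))

## Build a VoiMask from 1-based voxel indices on a small grid.
maskFromVoxels <- function(idx, dim = c(4L, 4L, 4L), spacing = c(1, 1, 1),
                           label = "mask") {
    geom <- volumeGeometry(dim, spacing)
    m <- array(FALSE, dim)
    m[idx] <- TRUE
    voiMask(m, geom, label = label)
}

## A random non-empty mask on a small grid (for property-style tests).
randomMask <- function(geom, p = 0.3, label = "mask") {
    repeat {
        m <- array(runif(prod(geom@dim)) < p, geom@dim)
        if (any(m)) return(voiMask(m, geom, label = label))
    }
}

## Brute-force overlap indices from voxel index sets (the independent
## oracle for the overlap module).
bruteOverlap <- function(maskA, maskR) {
    a <- which(maskA@mask)
    r <- which(maskR@mask)
    int <- length(intersect(a, r))
    uni <- length(union(a, r))
    list(dice = 2 * int / (length(a) + length(r)),
         jaccard = int / uni,
         of = int / min(length(a), length(r)),
         common_over_a = int / length(a),
         common_over_r = int / length(r))
}

## Analytic two-compartment PET sphere on a 1 mm grid: rim SUV `suvRim`
## of radius rOut around a core SUV `suvCore` of radius rCore.
twoCompartmentPet <- function(rOut = 10, rCore = 4, suvRim = 8, suvCore = 20,
                              n = 28L, spacing = c(1, 1, 1)) {
    geom <- volumeGeometry(rep(n, 3), spacing)
    W <- hotspotOverlap:::.gridWorldCoords(geom)
    r2 <- rowSums(W^2)
    suv <- numeric(nrow(W))
    suv[r2 <= rOut^2] <- suvRim
    suv[r2 <= rCore^2] <- suvCore
    list(pet = scalarVolume(array(suv, geom@dim), geom, modality = "PET"),
         inRim = array(r2 <= rOut^2, geom@dim),
         inCore = array(r2 <= rCore^2, geom@dim),
         region = regionBox(rep(-13, 3), rep(13, 3)))
}
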