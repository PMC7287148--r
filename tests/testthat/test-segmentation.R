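test_that("a homogeneous sphere is delineated whole at any threshold", {
    geom <- volumeGeometry(rep(24L, 3), c(1, 1, 1))
    W <- hotspotOverlap:::.gridWorldCoords(geom)
    inside <- rowSums(W^2) <= 64
    pet <- scalarVolume(array(ifelse(inside, 10, 0), geom@dim), geom,
                        modality = "PET")
    region <- regionBox(rep(-11, 3), rep(11, 3))
    for (x in c(0.3, 0.5, 0.9)) {
        m <- suppressMessages(delineateVoi(pet, region, x))
        expect_identical(m@mask, array(inside, geom@dim))
    }
})

test_that("core/rim thresholds separate compartments as enumerated", {
    tc <- twoCompartmentPet()   # core SUV 20 r 4, rim SUV 8 r 10
    m50 <- suppressMessages(delineateVoi(tc$pet, tc$region, 0.5))
    m30 <- suppressMessages(delineateVoi(tc$pet, tc$region, 0.3))
    expect_identical(m50@mask, tc$inCore)   # threshold 10 > rim 8
    expect_identical(m30@mask, tc$inRim)    # threshold 6 < rim 8
})

test_that("masks are nested and scale-invariant", {
    case <- cleanCase()
    region <- maskBoundingBox(case@trueLesionA, 10)
    xs <- seq(0.3, 0.9, by = 0.1)
    masks <- lapply(xs, function(x)
        suppressMessages(delineateVoi(case@petA, region, x)))
    vols <- vapply(masks, volumeCc, 0)
    expect_true(all(diff(vols) <= 1e-12))
    for (i in seq_along(xs)[-1])
        expect_true(all(masks[[i]]@mask <= masks[[i - 1]]@mask))
    ## multiplying the PET by a positive constant changes nothing
    pet2 <- scalarVolume(case@petA@data * 3.7, case@petA@geometry,
                         modality = "PET")
    m2 <- suppressMessages(delineateVoi(pet2, region, 0.4))
    expect_identical(m2@mask,
                     suppressMessages(delineateVoi(case@petA, region,
                                                   0.4))@mask)
})

test_that("masks match exhaustive threshold enumeration on the phantom", {
    case <- cleanCase()
    region <- maskBoundingBox(case@trueLesionA, 10)
    geom <- case@petA@geometry
    inRegion <- hotspotOverlap:::.regionIndicator(geom, region)
    vals <- as.numeric(case@petA@data)
    suvMax <- max(vals[inRegion])
    for (x in c(0.4, 0.7)) {
        m <- suppressMessages(delineateVoi(case@petA, region, x))
        brute <- inRegion & vals >= x * suvMax
        ## the lesion is one connected blob, so the component restriction
        ## must not remove anything here
        expect_equal(sum(m@mask), sum(brute))
        expect_true(all(which(m@mask) %in% which(brute)))
    }
})

test_that("degenerate regions error; SUVmax ties break deterministically", {
    geom <- volumeGeometry(rep(8L, 3), c(1, 1, 1), origin = c(0, 0, 0))
    zero <- scalarVolume(array(0, geom@dim), geom, modality = "PET")
    expect_error(delineateVoi(zero, regionBox(c(1, 1, 1), c(5, 5, 5)), 0.4),
                 "all-zero region")
    a <- array(0, geom@dim); a[2, 2, 2] <- 10; a[5, 5, 5] <- 10
    pet <- scalarVolume(a, geom, modality = "PET")
    expect_message(m <- delineateVoi(pet, regionBox(c(0, 0, 0), c(7, 7, 7)),
                                     0.5),
                   "tie")
    ## lowest linear index wins; the two maxima are not 26-connected
    expect_true(m@mask[2, 2, 2])
    expect_false(m@mask[5, 5, 5])
})

test_that("delineateAll yields the configured number of masks", {
    case <- identityCase()
    regA <- maskBoundingBox(case@trueLesionA, 10)
    masks <- delineateAll(case@petA, case@petR, regA, regA, studyConfig())
    expect_length(masks$A, 7L)
    expect_length(masks$R, 2L)
    expect_identical(names(masks$A)[1], "A_30")
    custom <- studyConfig(baselineThresholds = c(30, 50, 70))
    masks2 <- delineateAll(case@petA, case@petR, regA, regA, custom)
    expect_equal(length(masks2$A) + length(masks2$R), 5L)
})

test_that("uptake metrics follow their definitions", {
    ## homogeneous lesion of exactly 2 cc at SUV 5: 250 voxels of 8 mm^3
    geom <- volumeGeometry(rep(20L, 3), c(2, 2, 2))
    a <- array(0, geom@dim)
    a[1:250] <- 5
    pet <- scalarVolume(a, geom, modality = "PET")
    um <- computeUptakeMetrics(pet, hotspotOverlap:::.gridBounds(geom))
    expect_equal(um@suvMax, 5)
    expect_equal(um@suvMean, 5)
    expect_equal(um@mtvCc, 2)
    expect_equal(um@tlgG, 10)

    case <- cleanCase()
    region <- maskBoundingBox(case@trueLesionA, 10)
    um2 <- computeUptakeMetrics(case@petA, region)
    ## MTV equals the brute-force count of voxels >= 0.4 SUVmax
    geom2 <- case@petA@geometry
    inRegion <- hotspotOverlap:::.regionIndicator(geom2, region)
    vals <- as.numeric(case@petA@data)
    brute <- sum(inRegion & vals >= 0.4 * max(vals[inRegion])) *
        hotspotOverlap:::.voxelVolumeCc(geom2)
    expect_equal(um2@mtvCc, brute)
    expect_equal(um2@tlgG, um2@suvMean * um2@mtvCc)
    expect_lte(um2@suvMean, um2@suvMax)
})
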