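test_that("voxel/world conversions agree with the grid definition", {
    geom <- volumeGeometry(c(8L, 6L, 4L), c(2, 2, 3), origin = c(-7, -5, -4.5))
    W <- hotspotOverlap:::.gridWorldCoords(geom)
    expect_equal(nrow(W), 8L * 6L * 4L)
    expect_equal(W[1, ], c(-7, -5, -4.5))
    ## column-major: second row advances x by one spacing
    expect_equal(W[2, ], c(-5, -5, -4.5))
    expect_equal(hotspotOverlap:::.voxelToWorld(geom, rbind(c(7, 5, 3)))[1, ],
                 c(7, 5, 4.5))
    expect_equal(hotspotOverlap:::.voxelVolumeCc(geom), 12 / 1000)
})

test_that("geometry validity rejects degenerate inputs", {
    expect_error(volumeGeometry(c(4L, 4L, 4L), c(0, 1, 1)), "positive")
    expect_error(volumeGeometry(c(4L, 4L, 4L), c(1, 1, 1),
                                direction = matrix(1, 3, 3)), "orthonormal")
})

test_that("region boxes select the expected voxels", {
    geom <- volumeGeometry(c(10L, 10L, 10L), c(1, 1, 1), origin = c(0, 0, 0))
    sel <- hotspotOverlap:::.regionIndicator(geom, regionBox(c(2, 2, 2),
                                                            c(4, 4, 4)))
    expect_equal(sum(sel), 27L)
})

test_that("mask bounding box covers the mask and respects the margin", {
    case <- identityCase()
    bb <- maskBoundingBox(case@trueLesionA, marginMm = 10)
    ctr <- hotspotOverlap:::.maskCentroid(case@trueLesionA)
    r <- case@config@lesionRadiusMm
    expect_true(all(bb["lo", ] <= ctr - r))
    expect_true(all(bb["hi", ] >= ctr + r))
    expect_error(maskBoundingBox(voiMask(array(FALSE, c(2, 2, 2)),
                                         volumeGeometry(c(2L, 2L, 2L),
                                                        c(1, 1, 1)))),
                 "empty")
})

test_that("rigid transforms compose and invert consistently", {
    set.seed(42)
    t1 <- rigidTransform(rotation = c(3, -7, 12), translation = c(4, -2, 6),
                         center = c(5, 5, 5))
    t2 <- rigidTransform(rotation = c(-5, 2, 8), translation = c(-1, 3, 2))
    pts <- matrix(rnorm(30, sd = 40), ncol = 3)
    ## inverse undoes the mapping
    expect_equal(transformPoints(invertRigid(t1), transformPoints(t1, pts)),
                 pts, tolerance = 1e-10)
    ## composition applies t2 then t1
    expect_equal(transformPoints(composeRigid(t1, t2), pts),
                 transformPoints(t1, transformPoints(t2, pts)),
                 tolerance = 1e-10)
    ## zero parameters are the identity
    expect_equal(transformPoints(rigidTransform(), pts), pts)
})

test_that("Euler extraction round-trips rotation matrices", {
    for (ang in list(c(0.1, -0.2, 0.3), c(-0.5, 0.4, -0.1), c(0, 0, 0))) {
        R <- hotspotOverlap:::.eulerToMatrix(ang)
        expect_equal(hotspotOverlap:::.matrixToEuler(R), ang,
                     tolerance = 1e-12)
    }
})
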