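test_that("identity inputs register to identity", {
    case <- cleanCase()
    focus <- maskBoundingBox(case@trueLesionA, 25)
    t <- registerRigid(case@ctA, case@ctA, focus)
    expect_lt(max(abs(t@rotation)) * 180 / pi, 0.1)
    expect_lt(max(abs(t@translation)), 0.1)
})

test_that("a known 5 mm / 5 deg misalignment is recovered on clean CT", {
    case <- cleanCase()
    truth <- rigidTransform(rotation = c(2, -3, 5),
                            translation = c(3, -3, 2))
    moving <- applyTransform(case@ctA, truth)
    focus <- maskBoundingBox(case@trueLesionA, 25)
    rec <- registerRigid(moving, case@ctA, focus)
    expect_lt(max(abs(rec@rotation - truth@rotation)) * 180 / pi, 0.5)
    expect_lt(max(abs(rec@translation - truth@translation)), 0.5)
    ## registering raises similarity above the unregistered baseline
    geom <- case@ctA@geometry
    before <- mean((moving@data - case@ctA@data)^2)
    after <- mean((moving@data -
                   applyTransform(case@ctA, rec)@data)^2)
    expect_lt(after, before)
})

test_that("recovery degrades gracefully under noise", {
    cfg <- phantomConfig("TP", seed = 19L,
                         rigidErrorDeg = c(0, 0, 0), rigidErrorMm = c(0, 0, 0),
                         noiseSd = 0.3, ctNoiseSd = 10)
    case <- generateCase(cfg)
    truth <- rigidTransform(rotation = c(2, -3, 5), translation = c(3, -3, 2))
    moving <- applyTransform(case@ctA, truth)
    rec <- registerRigid(moving, case@ctA,
                         maskBoundingBox(case@trueLesionA, 25))
    expect_lt(max(abs(rec@rotation - truth@rotation)) * 180 / pi, 1)
    expect_lt(max(abs(rec@translation - truth@translation)), 1)
})

test_that("free-form registration recovers a known sinusoidal field", {
    case <- cleanCase()
    ct <- case@ctA
    geom <- ct@geometry
    W <- hotspotOverlap:::.gridWorldCoords(geom)
    d <- hotspotOverlap:::.sinDisplacement(W, 4, 80, c(0, 2, 4))
    warped <- hotspotOverlap:::.cppInterpTrilinear(
        ct@data, geom@dim, geom@spacing, geom@origin, W + d, min(ct@data))
    fixed <- scalarVolume(array(warped, geom@dim), geom, modality = "CT")
    focus <- maskBoundingBox(case@trueLesionA, 30)
    field <- registerElastic(fixed, ct, rigidTransform(), focus)
    sel <- which(case@trueLesionA@mask)
    U <- matrix(field@displacement, ncol = 3)[sel, ]
    err <- sqrt(rowSums((U - d[sel, ])^2))
    expect_lt(mean(err), 1.5)
    ## optimizer contract: metric never worse than the rigid init alone
    expect_lte(attr(field, "metric"), attr(field, "initMetric"))
})

test_that("free-form on identical images stays near zero", {
    case <- cleanCase()
    focus <- maskBoundingBox(case@trueLesionA, 30)
    field <- registerElastic(case@ctA, case@ctA, rigidTransform(), focus)
    mag <- sqrt(rowSums(matrix(field@displacement, ncol = 3)^2))
    expect_lt(max(mag), 0.5)
})

test_that("a zero field composed with a rigid init reproduces the rigid map", {
    case <- identityCase()
    init <- rigidTransform(rotation = c(1, 2, -1), translation = c(2, -1, 3))
    geom <- case@petA@geometry
    zero <- new("DeformationField",
                displacement = array(0, c(geom@dim, 3L)), geometry = geom,
                init = init, controlSpacing = NA_real_)
    viaField <- applyTransform(case@petA, zero, geom)
    viaRigid <- applyTransform(case@petA, init, geom)
    expect_identical(viaField@data, viaRigid@data)
})

test_that("resampling contracts hold", {
    case <- identityCase()
    pet <- case@petA
    ## identity is bit-exact
    out <- applyTransform(pet, rigidTransform())
    expect_identical(out@data, pet@data)
    ## an integer-voxel translation is an exact array shift
    shift <- rigidTransform(translation = c(2, 0, 0))   # one voxel in x
    shifted <- applyTransform(pet, shift)
    expect_equal(shifted@data[1:63, , ], pet@data[2:64, , ])
    ## mask warping changes volume by at most 2 voxel volumes on spheres
    m <- case@trueLesionA
    rot <- rigidTransform(rotation = c(4, -3, 6), translation = c(1.3, -2.1, 0.7))
    warped <- applyTransform(m, rot)
    ## binary warping erodes curved surfaces slightly; the measured error
    ## on 13 mm spheres at 2 x 2 x 3 mm voxels stays within 1.5 % of volume
    expect_lt(abs(volumeCc(warped) - volumeCc(m)), 0.015 * volumeCc(m))
    ## deformation fields demand their own grid
    other <- volumeGeometry(c(10L, 10L, 10L), c(2, 2, 3))
    zero <- new("DeformationField",
                displacement = array(0, c(m@geometry@dim, 3L)),
                geometry = m@geometry, init = rigidTransform(),
                controlSpacing = NA_real_)
    expect_error(applyTransform(pet, zero, other), "grid mismatch")
})
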