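test_that("volume write/read round-trips data bit-exactly and geometry", {
    set.seed(7)
    geom <- volumeGeometry(c(10L, 8L, 6L), c(2, 2, 3), origin = c(-9, -7, -7.5))
    vol <- scalarVolume(array(rnorm(480), c(10, 8, 6)), geom, modality = "CT")
    path <- withr::local_tempfile(fileext = ".nii.gz")
    writeVolume(vol, path)
    back <- readVolume(path)
    expect_identical(back@data, vol@data)
    expect_equal(back@geometry@spacing, geom@spacing, tolerance = 1e-7)
    expect_equal(back@geometry@origin, geom@origin, tolerance = 1e-7)
    expect_identical(back@modality, "CT")
})

test_that("4D input and missing files are rejected with clear errors", {
    path <- withr::local_tempfile(fileext = ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), path)
    expect_error(readVolume(path), "4 dimensions")
    expect_error(readVolume(file.path(tempdir(), "does-not-exist.nii.gz")),
                 "not found")
})

test_that("mask round-trip preserves voxels, label and threshold", {
    case <- identityCase()
    m <- delineateVoi(case@petA, maskBoundingBox(case@trueLesionA, 10), 0.4)
    path <- withr::local_tempfile(fileext = ".nii.gz")
    writeMask(m, path)
    back <- readMask(path)
    expect_identical(back@mask, m@mask)
    expect_identical(back@label, m@label)
    expect_equal(back@thresholdFraction, 0.4)
    ## 10 voxels at 2 x 2 x 3 mm = 0.12 cc
    g <- volumeGeometry(c(5L, 5L, 5L), c(2, 2, 3))
    mm <- array(FALSE, c(5, 5, 5)); mm[1:10] <- TRUE
    expect_equal(volumeCc(voiMask(mm, g)), 0.12)
})

test_that("overlap tables enumerate, round-trip and reject duplicates", {
    case <- identityCase()
    study <- studyConfig()
    regA <- maskBoundingBox(case@trueLesionA, 10)
    masks <- delineateAll(case@petA, case@petR, regA, regA, study)
    rows <- rbind(overlapMatrix(masks$A, masks$R, "RR", "c1", "TP"),
                  overlapMatrix(masks$A, masks$R, "ER", "c1", "TP"))
    expect_equal(nrow(rows), 28L)   # 2 methods x 7 x 2 thresholds
    path <- withr::local_tempfile(fileext = ".csv")
    writeOverlapTable(rows, path)
    back <- readOverlapTable(path)
    for (cl in c("dice", "jaccard", "of", "common_over_a", "common_over_r"))
        expect_equal(back[[cl]], rows[[cl]], tolerance = 1e-12)
    expect_error(writeOverlapTable(rows[c(1, 1), ], path), "duplicate")
    expect_error(writeOverlapTable(rows[0, ], path), "non-empty")
})

test_that("transforms serialize losslessly", {
    t1 <- rigidTransform(rotation = c(2, -3, 5), translation = c(1.5, -2, 3),
                         center = c(1, 2, 3))
    path <- withr::local_tempfile(fileext = ".json")
    writeTransform(t1, path)
    back <- readTransform(path)
    expect_equal(back@rotation, t1@rotation)
    expect_equal(back@translation, t1@translation)
    expect_equal(back@center, t1@center)

    geom <- volumeGeometry(c(6L, 6L, 4L), c(2, 2, 3))
    disp <- array(rnorm(6 * 6 * 4 * 3, sd = 2), c(6, 6, 4, 3))
    field <- new("DeformationField", displacement = disp, geometry = geom,
                 init = t1, controlSpacing = 16)
    prefix <- file.path(withr::local_tempdir(), "def")
    writeTransform(field, prefix)
    fback <- readTransform(prefix)
    expect_equal(fback@displacement, disp)
    expect_equal(fback@init@translation, t1@translation)
    expect_equal(fback@controlSpacing, 16)
})
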