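test_that("an unmoved, noiseless case reproduces the baseline voxelwise", {
    case <- identityCase()
    expect_identical(case@petR@data, case@petA@data)
    expect_identical(case@ctR@data, case@ctA@data)
    expect_true(all(case@trueDeformation@displacement == 0))
})

test_that("generation is a pure function of the configuration", {
    cfg <- phantomConfig("NTP", seed = 77L)
    c1 <- generateCase(cfg)
    c2 <- generateCase(cfg)
    expect_identical(c1@petA@data, c2@petA@data)
    expect_identical(c1@petR@data, c2@petR@data)
    expect_identical(c1@ctR@data, c2@ctR@data)
    expect_identical(c1@trueRigid@translation, c2@trueRigid@translation)
    ## a different noise seed changes the voxel noise but not the anatomy
    c3 <- generateCase(phantomConfig("NTP", seed = 78L,
                                     anatomySeed = cfg@anatomySeed))
    expect_false(identical(c1@petA@data, c3@petA@data))
    expect_identical(c1@trueLesionA@mask, c3@trueLesionA@mask)
})

test_that("a pure translation moves the recurrence lesion centroid exactly", {
    cfg <- phantomConfig("TP", noiseSd = 0, ctNoiseSd = 0,
                         rigidErrorDeg = c(0, 0, 0), rigidErrorMm = c(0, 0, 6),
                         recurrenceOffsetMm = c(0, 0, 0))
    case <- generateCase(cfg)
    dc <- hotspotOverlap:::.maskCentroid(case@trueLesionR) -
        hotspotOverlap:::.maskCentroid(case@trueLesionA)
    ## within half a voxel (z spacing 3 mm)
    expect_lt(max(abs(dc - c(0, 0, 6))), 1.5)
})

test_that("thresholding a noiseless recurrence PET recovers the true mask", {
    cfg <- phantomConfig("NTP", noiseSd = 0, ctNoiseSd = 0)
    case <- generateCase(cfg)
    r40 <- delineateVoi(case@petR, maskBoundingBox(case@trueLesionR, 10),
                        0.4, role = "R")
    expect_identical(r40@mask, case@trueLesionR@mask)
})

test_that("true-mask Dice falls monotonically from 1 to 0 with offset", {
    dices <- vapply(seq(0, 26, by = 2), function(off) {
        cfg <- phantomConfig("TP", noiseSd = 0, ctNoiseSd = 0,
                             rigidErrorDeg = c(0, 0, 0),
                             rigidErrorMm = c(0, 0, 0),
                             recurrenceOffsetMm = c(off, 0, 0),
                             recurrenceRadiusMm = 13,
                             recurrenceCoreRadiusMm = 6)
        case <- generateCase(cfg)
        computeOverlap(case@trueLesionA, case@trueLesionR)$dice
    }, 0)
    expect_equal(dices[1], 1)
    expect_equal(dices[length(dices)], 0)
    expect_true(all(diff(dices) <= 1e-12))
})

test_that("lesions outside the grid are rejected with an explicit message", {
    expect_error(generateCase(phantomConfig("TP",
                                            lesionCenterMm = c(60, 0, 0))),
                 "outside the grid")
    expect_error(generateCase(phantomConfig("TP",
                                            recurrenceOffsetMm = c(58, 0, 0))),
                 "recurrence lesion")
})

test_that("config invariants are enforced", {
    expect_error(phantomConfig("TP", suvRim = 13, suvCore = 12), "suvCore")
    expect_error(phantomConfig("TP", noiseSd = -1), "noise")
    expect_error(phantomConfig("TP", deformationAmplitudeMm = 30,
                               deformationWavelengthMm = 60), "invertible")
})

test_that("default cohort mirrors the study composition", {
    configs <- cohortConfigs(studyConfig(), groups = "LR")
    expect_length(configs, 43L)
    groups <- vapply(configs, function(c) c@positionGroup, "")
    expect_equal(sum(groups == "TP"), 15L)
    expect_equal(sum(groups == "NTP"), 28L)
    ## seed mapping is reproducible
    configs2 <- cohortConfigs(studyConfig(), groups = "LR")
    expect_identical(vapply(configs, function(c) c@seed, 1L),
                     vapply(configs2, function(c) c@seed, 1L))
    ## single case
    expect_length(generateCohort(studyConfig(nTP = 1L, nNTP = 0L)), 1L)
})

test_that("phantom cases serialize to NIfTI + JSON sidecar", {
    dir <- withr::local_tempdir()
    case <- identityCase()
    writePhantomCase(case, dir)
    expect_true(all(file.exists(file.path(dir,
        c("pet_a.nii.gz", "ct_a.nii.gz", "pet_r.nii.gz", "ct_r.nii.gz",
          "lesion_a.nii.gz", "lesion_r.nii.gz", "case.json")))))
    pet <- readVolume(file.path(dir, "pet_a.nii.gz"))
    expect_identical(pet@data, case@petA@data)
    expect_identical(pet@modality, "PET")
    side <- jsonlite::read_json(file.path(dir, "case.json"),
                                simplifyVector = TRUE)
    expect_equal(side$position_group, "TP")
})
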