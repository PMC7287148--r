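test_that("identical masks score 1 and disjoint masks 0 on all indices", {
    idx <- c("dice", "jaccard", "of", "common_over_a", "common_over_r")
    a <- maskFromVoxels(1:12, label = "A_40")
    same <- computeOverlap(a, maskFromVoxels(1:12, label = "R_40"))
    expect_equal(unlist(same[idx]), setNames(rep(1, 5), idx))
    disj <- computeOverlap(a, maskFromVoxels(20:40, label = "R_40"))
    expect_equal(unlist(disj[idx]), setNames(rep(0, 5), idx))
})

test_that("hand-enumerated 8/4/2-voxel example matches", {
    a <- maskFromVoxels(1:8, label = "A_40")     # |A| = 8
    r <- maskFromVoxels(7:10, label = "R_40")    # |R| = 4, |A^R| = 2
    ov <- computeOverlap(a, r)
    expect_equal(ov$dice, 1 / 3)
    expect_equal(ov$jaccard, 0.2)
    expect_equal(ov$common_over_a, 0.25)
    expect_equal(ov$common_over_r, 0.5)
    expect_equal(ov$of, 0.5)
})

test_that("indices match brute-force set arithmetic on random masks", {
    set.seed(11)
    geom <- volumeGeometry(c(6L, 5L, 4L), c(2, 2, 3))
    for (i in 1:25) {
        a <- randomMask(geom, p = runif(1, 0.1, 0.6), label = "A_40")
        r <- randomMask(geom, p = runif(1, 0.1, 0.6), label = "R_40")
        ov <- suppressWarnings(computeOverlap(a, r))
        brute <- bruteOverlap(a, r)
        for (nm in names(brute))
            expect_equal(ov[[nm]], brute[[nm]], tolerance = 1e-14)
        ## algebraic identities
        expect_equal(ov$dice, 2 * ov$jaccard / (1 + ov$jaccard),
                     tolerance = 1e-12)
        expect_equal(ov$of, max(ov$common_over_a, ov$common_over_r),
                     tolerance = 1e-12)
        ## symmetry
        ov2 <- suppressWarnings(computeOverlap(r, a))
        expect_equal(ov2$dice, ov$dice)
        expect_equal(ov2$jaccard, ov$jaccard)
        expect_equal(ov2$of, ov$of)
        expect_equal(ov2$common_over_a, ov$common_over_r)
    }
})

test_that("degenerate inputs follow the stated contracts", {
    a <- maskFromVoxels(1:4)
    empty <- maskFromVoxels(integer(0))
    w <- capture_warnings(ov <- computeOverlap(a, empty))
    expect_true(any(grepl("empty denominator", w)))
    expect_equal(ov$common_over_r, 0)
    expect_equal(ov$of, 0)
    expect_error(computeOverlap(empty, maskFromVoxels(integer(0))),
                 "both masks are empty")
    other <- voiMask(array(TRUE, c(3, 3, 3)),
                     volumeGeometry(c(3L, 3L, 3L), c(1, 1, 1)))
    expect_error(computeOverlap(a, other), "same grid")
})

test_that("the overlap matrix enumerates the full threshold grid", {
    case <- identityCase()
    regA <- maskBoundingBox(case@trueLesionA, 10)
    masks <- delineateAll(case@petA, case@petR, regA, regA, studyConfig())
    m <- overlapMatrix(masks$A, masks$R, method = "RR", caseId = "c",
                       positionGroup = "TP")
    expect_equal(nrow(m), 14L)             # 7 x 2 pairs -> 70 index values
    single <- overlapMatrix(masks$A[1], masks$R[1], method = "RR")
    expect_equal(nrow(single), 1L)         # 5 index values
})

test_that("agreement bands partition [0,1] as published", {
    expect_equal(as.character(classifyAgreement(c(0, 0.64, 1))),
                 c("poor", "good", "very good"))
    expect_equal(as.character(classifyAgreement(0.38)), "fair")
    expect_equal(as.character(classifyAgreement(c(0.204, 0.205))),
                 c("poor", "fair"))
    expect_equal(as.character(classifyAgreement(c(0.405, 0.605, 0.805))),
                 c("moderate", "good", "very good"))
    expect_error(classifyAgreement(1.2), "0, 1")
    expect_error(classifyAgreement(-0.1), "0, 1")
})
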