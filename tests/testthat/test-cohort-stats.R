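## Small synthetic overlap tables for the statistics layer.
fakeResults <- function(nTP = 4, nNTP = 5, shiftER = 0.1, seed = 3) {
    set.seed(seed)
    rows <- list()
    for (pg in c("TP", "NTP")) {
        n <- if (pg == "TP") nTP else nNTP
        for (i in seq_len(n)) {
            base <- runif(1, 0.2, 0.6)
            for (m in c("RR", "ER")) {
                v <- min(1, base + if (m == "ER" && pg == "NTP") shiftER else 0)
                rows[[length(rows) + 1L]] <- data.frame(
                    case_id = paste0(pg, i), position_group = pg, method = m,
                    a_label = "A_40", r_label = "R_40",
                    dice = v, jaccard = v, of = v,
                    common_over_a = v, common_over_r = v,
                    vol_a_cc = 1, vol_r_cc = 1, vol_common_cc = v,
                    stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, rows)
}

test_that("subgroup summaries cover the four subgroups with sane stats", {
    res <- fakeResults()
    s <- summarizeSubgroups(res)
    expect_setequal(unique(s$subgroup),
                    c("TP-RR", "TP-ER", "NTP-RR", "NTP-ER"))
    expect_true(all(s$n[s$subgroup == "NTP-RR"] == 5L))
    expect_true(all(s$band %in% c("poor", "fair", "moderate", "good",
                                  "very good")))
    ## all-identical values give sd 0; a single case gives sd NA
    same <- res; same$of <- 0.5; same$dice <- 0.5; same$jaccard <- 0.5
    same$common_over_a <- 0.5; same$common_over_r <- 0.5
    s2 <- summarizeSubgroups(same)
    expect_true(all(s2$mean == 0.5) && all(s2$sd == 0))
    one <- res[res$case_id == "TP1" & res$method == "RR", ]
    s3 <- summarizeSubgroups(one)
    expect_true(is.na(s3$sd[1]) && s3$n[1] == 1L)
    bad <- res; bad$position_group[1] <- "XX"
    expect_error(summarizeSubgroups(bad), "unknown position group")
})

test_that("method comparison is paired and detects the planted shift", {
    res <- fakeResults(nNTP = 10, shiftER = 0.15)
    cmp <- compareMethods(res, "NTP")
    expect_true(all(cmp$test == "Wilcoxon signed-rank"))
    ofRow <- cmp[cmp$index == "of", ]
    expect_gt(ofRow$mean_er, ofRow$mean_rr)
    expect_lt(ofRow$p_value, 0.05)
    ## no difference -> p = 1
    cmp0 <- compareMethods(fakeResults(shiftER = 0), "NTP")
    expect_true(all(cmp0$p_value == 1))
    expect_true(all(cmp0$mean_diff == 0))
    ## unpaired input is rejected with a pointer to comparePositions
    unp <- res[!(res$method == "ER" & res$case_id == "NTP1"), ]
    expect_error(compareMethods(unp, "NTP"), "comparePositions")
})

test_that("position comparison is symmetric under label swap", {
    res <- fakeResults(nTP = 6, nNTP = 6, shiftER = 0)
    res$of[res$position_group == "TP"] <-
        res$of[res$position_group == "TP"] + 0.2
    cmp <- comparePositions(res, "RR")
    ofRow <- cmp[cmp$index == "of", ]
    expect_gt(ofRow$mean_tp, ofRow$mean_ntp)
    swapped <- res
    swapped$position_group <- ifelse(res$position_group == "TP", "NTP", "TP")
    cmp2 <- comparePositions(swapped, "RR")
    expect_equal(cmp2$p_value, cmp$p_value)
    expect_equal(cmp2$mean_diff, -cmp$mean_diff)
    ## identical groups -> p = 1
    same <- res; same$of <- 0.4
    cmpSame <- comparePositions(same, "RR")
    expect_equal(cmpSame$p_value[cmpSame$index == "of"], 1)
    tiny <- res[res$case_id != "TP1", ]
    tiny <- tiny[!(tiny$position_group == "TP" & tiny$case_id != "TP2"), ]
    expect_error(comparePositions(tiny, "RR"), "at least 2")
})

test_that("paired test agrees with exhaustive sign-flip enumeration", {
    set.seed(5)
    d <- round(rnorm(8, 0.05, 0.2), 3)
    d <- d[d != 0]
    while (anyDuplicated(abs(d))) d <- d + rnorm(length(d), 0, 1e-4)
    n <- length(d)
    ranks <- rank(abs(d))
    vObs <- sum(ranks[d > 0])
    ## enumerate all 2^n sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vAll <- signs %*% ranks
    pEnum <- if (vObs > n * (n + 1) / 4) 2 * mean(vAll >= vObs)
             else 2 * mean(vAll <= vObs)
    pEnum <- min(1, pEnum)
    w <- hotspotOverlap:::.wilcoxP(d, rep(0, n), paired = TRUE)
    expect_equal(w$p, pEnum, tolerance = 1e-12)
})

test_that("unpaired test agrees with exhaustive relabeling enumeration", {
    set.seed(6)
    x <- round(runif(5, 0.3, 0.9), 3)
    y <- round(runif(5, 0.1, 0.7), 3)
    while (anyDuplicated(c(x, y))) y <- y + rnorm(5, 0, 1e-4)
    pooled <- c(x, y)
    nx <- 5L
    wObs <- sum(rank(pooled)[1:nx]) - nx * (nx + 1) / 2
    combos <- utils::combn(10, nx)
    wAll <- apply(combos, 2, function(ix)
        sum(rank(pooled)[ix]) - nx * (nx + 1) / 2)
    pEnum <- if (wObs > nx * 5 / 2) 2 * mean(wAll >= wObs)
             else 2 * mean(wAll <= wObs)
    pEnum <- min(1, pEnum)
    w <- hotspotOverlap:::.wilcoxP(x, y, paired = FALSE)
    expect_equal(w$p, pEnum, tolerance = 1e-12)
})

test_that("uptake contrasts detect larger relapse lesions via the generator", {
    ## small-grid cohorts keep the runtime down; the measurement chain
    ## (phantom -> PET -> A_40 -> MTV/TLG) is exercised end to end
    study <- studyConfig(nTP = 8L, nNTP = 0L, nCR = 30L,
                         gridShape = c(48L, 48L, 40L),
                         mtvMeanLrCc = 9.1, mtvMeanCrCc = 6.4, seed = 9L)
    configs <- cohortConfigs(study)
    rows <- lapply(names(configs), function(id) {
        case <- generateCase(configs[[id]])
        um <- computeUptakeMetrics(case@petA,
                                   maskBoundingBox(case@trueLesionA, 10))
        data.frame(case_id = id, group = sub("_.*", "", id),
                   mtv_cc = um@mtvCc, tlg_g = um@tlgG)
    })
    metrics <- do.call(rbind, rows)
    metrics$group[metrics$group == "LR"] <- "LR"
    cmp <- compareUptakeGroups(metrics)
    mtvRow <- cmp[cmp$metric == "mtv_cc" & cmp$contrast == "LR-vs-CR", ]
    expect_gt(mtvRow$mean_relapse, mtvRow$mean_cr)
    ## TLG direction follows MTV under the shared SUV model
    tlgRow <- cmp[cmp$metric == "tlg_g" & cmp$contrast == "LR-vs-CR", ]
    expect_gt(tlgRow$mean_relapse, tlgRow$mean_cr)
    expect_error(compareUptakeGroups(metrics[metrics$group == "CR", ]),
                 "relapse group")
})
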