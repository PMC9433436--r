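test_that("fraction unreacted follows the proportion-ratio identity", {
    # homogeneous depletion: unchanged proportions give F = 1 - f everywhere
    F <- fractionUnreacted(c(100, 100, 100), c(50, 50, 50), f = 0.4,
                           pseudocount = 0)
    expect_equal(unname(F), rep(0.6, 3))
    # two-variant toy: k = (2, 1), F_2 = 0.8 -> proportions
    # p(0) = (1/2, 1/2), p(f) = (0.64, 0.80)/1.44, f = 0.28
    F2 <- fractionUnreacted(c(0.5, 0.5), c(0.64, 0.80) / 1.44, f = 0.28,
                            pseudocount = 0)
    expect_equal(unname(F2), c(0.64, 0.80), tolerance = 1e-12)
    expect_error(fractionUnreacted(1:3, 1:3, f = 1.2), "f must")
    # weighted-mean closure: sum p(0) F = 1 - f, pseudocounts or not
    set.seed(1)
    c0 <- rpois(50, 200); cf <- rpois(50, 150)
    for (pcnt in c(0, 0.5)) {
        F <- fractionUnreacted(c0, cf, f = 0.2, pseudocount = pcnt)
        p0 <- (c0 + pcnt) / sum(c0 + pcnt)
        expect_equal(sum(p0 * F), 0.8, tolerance = 1e-12)
    }
})

test_that("the log-depletion ratio recovers relative rate constants exactly", {
    # ln(0.64)/ln(0.80) = 2 for the two-variant toy
    expect_equal(log(0.64) / log(0.80), 2, tolerance = 1e-12)

    # full-pool version: one variant twice as fast as the reference
    k <- rep(1, 4096); names(k) <- enumerateLeaders()
    k["AAAAAA"] <- 2; k["UUUUUU"] <- 0.25
    tr <- simulationTruth(k)
    pc <- simulatePool(tr, fTargets = 0.2, depth = 1e6, exact = TRUE)
    rrt <- relativeRates(pc, pseudocount = 0)
    expect_equal(unname(krel(rrt)["AAAAAA"]), 2, tolerance = 1e-9)
    expect_equal(unname(krel(rrt)["UUUUUU"]), 0.25, tolerance = 1e-9)
    expect_identical(unname(krel(rrt)["AAAAAG"]), 1)
})

test_that("uniform pools give k_rel = 1 for every variant", {
    m <- matrix(100, nrow = 4096, ncol = 2,
                dimnames = list(enumerateLeaders(), c("t0", "t1")))
    m[, 2] <- 60
    rrt <- relativeRates(poolCounts(m, f = c(0, 0.4)))
    expect_true(all(abs(krel(rrt) - 1) < 1e-12))
})

test_that("the printed pool-sum formula agrees with the ln-ratio route", {
    set.seed(7)
    tr <- assignTrueKrel(ecoliLeaderModel())
    pc <- simulatePool(tr, fTargets = 0.3, depth = 2e6, seed = 7)
    cts <- SummarizedExperiment::assay(pc, "counts")
    f <- SummarizedExperiment::colData(pc)$f[2]
    for (pcnt in c(0.5, 0)) {
        F <- fractionUnreacted(cts[, 1], cts[, 2], f, pseudocount = pcnt)
        direct <- log(F) / log(F[["AAAAAG"]])
        printed <- krelReferenceRatioForm(cts[, 1], cts[, 2], f,
                                          pseudocount = pcnt)
        expect_equal(printed, direct, tolerance = 1e-12)
    }
})

test_that("recovered rates track the truth on deep sampled data", {
    tr <- assignTrueKrel(ecoliLeaderModel())
    pc <- simulatePool(tr, depth = 2e7, seed = 101)
    rrt <- relativeRates(pc)
    k <- krel(rrt); tk <- trueKrel(tr)
    ok <- rrt@table$flag == "ok"
    expect_gt(cor(k[ok], tk[ok], method = "spearman"), 0.99)
    # the largest errors sit in the slow tail, where reads barely change
    lerr <- abs(log(k[ok]) - log(tk[ok]))
    slow <- tk[ok] < quantile(tk[ok], 0.1)
    fast <- tk[ok] > quantile(tk[ok], 0.9)
    expect_gt(median(lerr[slow]), median(lerr[fast]))
})

test_that("early and late timepoints agree within their sampling error", {
    tr <- assignTrueKrel(ecoliLeaderModel())
    pc <- simulatePool(tr, depth = 2e7, seed = 55)
    early <- relativeRates(pc[, c(1, 2)])   # f = 0 and f = 0.05
    late <- relativeRates(pc[, c(1, 4)])    # f = 0 and f = 0.30
    ok <- early@table$flag == "ok" & late@table$flag == "ok"
    z2 <- (log(krel(early)) - log(krel(late)))^2 /
        (krelSE(early)^2 + krelSE(late)^2)
    # squared z-scores should look like chi-square(1)
    expect_lt(mean(z2[ok]), 2)
})

test_that("calibration is idempotent and censoring is flagged, not dropped", {
    tr <- assignTrueKrel(ecoliLeaderModel())
    pc <- simulatePool(tr, fTargets = 0.3, depth = 5e4, seed = 13)
    rrt <- relativeRates(pc)
    rrt2 <- calibrate(rrt)
    expect_equal(krel(rrt2), krel(rrt), tolerance = 1e-12)
    # at shallow depth some slow variants show apparent enrichment
    expect_identical(nrow(rrt@table), 4096L)   # nothing silently dropped
    cens <- rrt@table$flag == "censored_low"
    if (any(cens)) expect_true(all(is.na(rrt@table$krel[cens])))
    # recalibrating to another variant moves the unit
    alt <- rrt@table$variant[which(rrt@table$flag == "ok")[1]]
    rrt3 <- calibrate(rrt, alt)
    expect_equal(unname(krel(rrt3)[alt]), 1)
})

test_that("rate histograms conserve counts, overall and per subset", {
    tr <- assignTrueKrel(ecoliLeaderModel())
    pc <- simulatePool(tr, fTargets = 0.3, depth = 1e6, exact = TRUE)
    rrt <- relativeRates(pc, pseudocount = 0)
    gg <- enumerateLeaders()[substr(enumerateLeaders(), 5, 6) == "GG"]
    au <- enumerateLeaders()[substr(enumerateLeaders(), 5, 6) == "AU"]
    h <- rateDistribution(rrt, bins = 25, subsets = list(GG = gg, AU = au))
    expect_identical(sum(h$count), 4096L)
    expect_identical(sum(h$GG), 256L)
    expect_identical(sum(h$AU), 256L)
    # degenerate distribution occupies a single bin
    h1 <- rateDistribution(setNames(rep(1, 10), letters[1:10]), bins = 5)
    expect_identical(sum(h1$count > 0), 1L)
})

test_that("top-fraction selection sizes and tie-breaks deterministically", {
    tr <- assignTrueKrel(ecoliLeaderModel())
    pc <- simulatePool(tr, fTargets = 0.3, depth = 1e6, exact = TRUE)
    rrt <- relativeRates(pc, pseudocount = 0)
    top <- topFraction(rrt, 0.01)
    expect_length(top, 41L)                      # ceiling(0.01 * 4096)
    expect_identical(top, topFraction(rrt, 0.01))
    expect_length(topFraction(rrt, 0.999), 4092L)
    # selected variants really are the largest k_rel
    k <- krel(rrt)
    expect_gte(min(k[top]), max(k[setdiff(names(k), top)]) - 1e-12)
})
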