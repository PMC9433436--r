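test_that("simulation truth enforces calibration and weight closure", {
    tr <- simulationTruth(rep(2, 4096))        # constant, any scale
    expect_equal(unname(trueKrel(tr)[referenceVariant(tr)]), 1)
    expect_true(all(trueKrel(tr) == 1))        # rescaled by the reference
    expect_equal(sum(poolWeights(tr)), 1, tolerance = 1e-12)
    expect_error(simulationTruth(c(NA, rep(1, 4095))), "finite")
})

test_that("an all-zero model assigns k_rel = 1 everywhere", {
    me <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "U"),
                                          as.character(-6:-1)))
    tr <- assignTrueKrel(makeSpecModel(me))
    expect_true(all(trueKrel(tr) == 1))
})

test_that("a single-position coefficient yields the closed-form k_rel ratio", {
    # u(-1) = ln 2 under sum-to-zero: variants differing only at N(-1)
    # (U vs A) differ by exactly exp(u - a) = 2^(4/3); U vs the reference G
    # likewise by exp(u - g)
    me <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "U"),
                                          as.character(-6:-1)))
    me[, "-1"] <- c(-log(2) / 3, -log(2) / 3, -log(2) / 3, log(2))
    tr <- assignTrueKrel(makeSpecModel(me))
    k <- trueKrel(tr)
    expect_equal(unname(k["AAAAAU"] / k["AAAAAA"]), 2 ^ (4 / 3),
                 tolerance = 1e-12)
    expect_equal(unname(k["AAAAAU"]), 2 ^ (4 / 3), tolerance = 1e-12)
})

test_that("the E. coli-like landscape spans about two orders of magnitude", {
    tr <- assignTrueKrel(ecoliLeaderModel())
    span <- max(trueKrel(tr)) / min(trueKrel(tr))
    expect_gt(span, 30)
    expect_lt(span, 300)
    # G is an anti-determinant at N(-1)..N(-4)
    me <- mainEffects(ecoliLeaderModel())
    expect_true(all(me["G", c("-4", "-3", "-2", "-1")] < 0))
})

test_that("exposure solving hits the requested conversion and conserves mass", {
    trU <- simulationTruth(rep(1, 4096))
    st <- solveExposure(trU, 0.3)
    expect_equal(st@exposure, -log(0.7), tolerance = 1e-9)
    expect_equal(unique(round(st@fractionUnreacted, 9)), 0.7)
    st0 <- solveExposure(trU, 0)
    expect_identical(st0@exposure, 0)
    expect_true(all(st0@fractionUnreacted == 1))
    expect_error(solveExposure(trU, 1), "fTarget")

    tr <- assignTrueKrel(ecoliLeaderModel())
    for (f in c(0.05, 0.15, 0.30, 0.8)) {
        s <- solveExposure(tr, f)
        expect_equal(sum(poolWeights(tr) * s@fractionUnreacted), 1 - f,
                     tolerance = 1e-8)
    }
    # f strictly increasing in exposure, F strictly decreasing
    ss <- lapply(c(0.05, 0.15, 0.30), solveExposure, truth = tr)
    ex <- vapply(ss, function(s) s@exposure, numeric(1))
    expect_true(all(diff(ex) > 0))
    expect_true(all(ss[[1]]@fractionUnreacted > ss[[3]]@fractionUnreacted))
})

test_that("two-variant competitive depletion follows the closed form", {
    # w = (1/2, 1/2), k = (2, 1), exposure chosen so F_2 = 0.8:
    # F_1 = 0.8^2 = 0.64 and f = 1 - (0.64 + 0.80)/2 = 0.28
    c_ <- -log(0.8)
    F <- exp(-c(2, 1) * c_)
    expect_equal(F, c(0.64, 0.80), tolerance = 1e-12)
    expect_equal(1 - sum(0.5 * F), 0.28, tolerance = 1e-12)
})

test_that("read sampling is multinomially closed, seeded, and exact on demand", {
    tr <- assignTrueKrel(ecoliLeaderModel())
    st <- solveExposure(tr, 0.15)
    x1 <- sampleReads(st, tr, depth = 1e5, seed = 42)
    x2 <- sampleReads(st, tr, depth = 1e5, seed = 42)
    expect_identical(x1, x2)
    expect_identical(sum(x1), 1e5)
    # infinite-depth mode returns w_i F_i / (1 - f) times depth
    xe <- sampleReads(st, tr, depth = 1, exact = TRUE)
    p <- poolWeights(tr) * st@fractionUnreacted / (1 - st@totalReacted)
    expect_equal(unname(xe), unname(p), tolerance = 1e-10)
})

test_that("simulated pools carry sample metadata and mass conservation", {
    tr <- assignTrueKrel(ecoliLeaderModel())
    pc <- simulatePool(tr, depth = 1e5, replicates = 2, seed = 1)
    cd <- SummarizedExperiment::colData(pc)
    expect_identical(ncol(pc), 8L)
    expect_identical(sum(cd$f == 0), 2L)
    expect_true(all(colSums(SummarizedExperiment::assay(pc)) == 1e5))
    pcx <- simulatePool(tr, depth = 1e5, seed = 1)
    pcy <- simulatePool(tr, depth = 1e5, seed = 1)
    expect_identical(SummarizedExperiment::assay(pcx),
                     SummarizedExperiment::assay(pcy))
})

test_that("assay curve generators obey their functional forms", {
    d <- simulateInitialRates(kcat = 0.2, Km = 50, E0 = 1, S = 50,
                              replicates = 1)
    expect_equal(d$v, 0.2 * 1 / 2)                     # S = Km half-saturation
    d2 <- simulateInitialRates(kcat = 0.2, Km = 50, E0 = 1,
                               S = c(0.01, 0.02), replicates = 1)
    expect_equal(d2$v / d2$S, rep(0.2 / 50, 2), tolerance = 1e-3)
    expect_error(simulateInitialRates(0.1, 50, E0 = 1, noiseSD = -1),
                 "noiseSD")

    b <- simulateBinding(Kd = 35, Bmax = 0.8, E = c(35, 1e6), replicates = 1)
    expect_equal(b$y[1], 0.4)
    expect_equal(b$y[2], 0.8, tolerance = 1e-4)

    ds <- simulateDissociation(fracFast = 0.5, kFast = 5, kSlow = 0,
                               t = c(0, 100), replicates = 1)
    expect_equal(ds$bound[1], 1)
    expect_equal(ds$bound[2], 0.5, tolerance = 1e-6)   # ES* plateau
    d0 <- simulateDissociation(fracFast = 0, kFast = 1, kSlow = 0.1,
                               t = c(0, 1, 2), replicates = 1)
    expect_equal(d0$bound, exp(-0.1 * c(0, 1, 2)))
})

test_that("truth serialization writes CSV with a YAML sidecar", {
    tr <- assignTrueKrel(ecoliLeaderModel())
    f <- tempfile(fileext = ".csv")
    writeTruth(tr, f, params = list(seed = 1))
    d <- read.csv(f)
    expect_identical(nrow(d), 4096L)
    side <- yaml::read_yaml(paste0(f, ".yml"))
    expect_identical(side$reference, "AAAAAG")
    expect_equal(side$seed, 1)
})
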