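test_that("design matrices code one indicator per position plus interactions", {
    v <- c("AAAAAA", "ACGUAC")
    X <- leaderDesignMatrix(v)
    expect_identical(ncol(X), 24L)
    expect_true(all(rowSums(X) == 6))
    expect_true(all(X[1, grepl("^A", colnames(X))] == 1))
    Xi <- leaderDesignMatrix(v, interactions = "all")
    expect_identical(ncol(Xi), 24L + 240L)          # C(6,2) * 16 candidates
    expect_identical(nrow(allInteractionCandidates()), 240L)
    # an interaction column is the product of its two main-effect columns
    ia <- data.frame(pos1 = -6, pos2 = -1, base1 = "A", base2 = "C")
    Xp <- leaderDesignMatrix(v, interactions = ia)
    expect_equal(Xp[, 25], Xp[, "A(-6)"] * Xp[, "C(-1)"],
                 ignore_attr = TRUE)
})

test_that("a flat landscape fits to all-zero coefficients", {
    v <- enumerateLeaders()
    m <- fitPWM(rep(0, 4096), variants = v)
    expect_equal(max(abs(mainEffects(m))), 0, tolerance = 1e-12)
    expect_equal(m@intercept, 0, tolerance = 1e-12)
    expect_equal(unname(predict(m, c("AAAAAA", "GGGGGG"))), c(0, 0),
                 tolerance = 1e-12)
})

test_that("noiseless main-effect truth is recovered exactly under the same constraint", {
    set.seed(21)
    me <- randomMainEffects()
    v <- enumerateLeaders()
    y <- predict(makeSpecModel(me, intercept = -0.4), v)
    m <- fitPWM(y, variants = v)
    expect_lt(max(abs(mainEffects(m) - me)), 1e-8)
    expect_equal(m@intercept, -0.4, tolerance = 1e-8)
    expect_equal(m@r2, 1, tolerance = 1e-10)
    # predictions reproduce the generating values (same functional form)
    expect_equal(predict(m, v), y, tolerance = 1e-8)
    # and no interaction gets admitted from a pure main-effects truth
    m0 <- selectInteractions(y, variants = v)
    expect_identical(nrow(interactionTerms(m0)), 0L)
})

test_that("a planted strong interaction is admitted in round 1 and recovered", {
    set.seed(31)
    me <- randomMainEffects()
    ia <- data.frame(pos1 = -2, pos2 = -1, base1 = "G", base2 = "U",
                     alpha = -1.4)
    v <- enumerateLeaders()
    y <- predict(makeSpecModel(me, ia), v) + rnorm(4096, 0, 0.1)
    m <- selectInteractions(y, variants = v)
    got <- interactionTerms(m)
    hit <- got$pos1 == -2 & got$pos2 == -1 & got$base1 == "G" &
        got$base2 == "U"
    expect_true(any(hit))
    expect_identical(got$round[hit], 1L)
    expect_gt(abs(got$tAdmission[hit]), 3.5)
    expect_equal(got$alpha[hit], -1.4, tolerance = 0.08)
})

test_that("predictions are invariant to the identifiability constraint", {
    # the linear predictor is a property of the column space, not the
    # coding: a treatment-coded lm on the raw one-hot design must give the
    # same predictions as the sum-to-zero fit
    set.seed(41)
    me <- randomMainEffects()
    v <- enumerateLeaders()
    y <- predict(makeSpecModel(me, intercept = 0.3), v) +
        rnorm(4096, 0, 0.2)
    m <- fitPWM(y, variants = v)
    X <- leaderDesignMatrix(v)
    alt <- lm(y ~ X)                  # rank-deficient; lm drops aliased cols
    expect_equal(unname(predict(m, v)), unname(fitted(alt)),
                 tolerance = 1e-8)
})

test_that("coefficient tables stay identifiable and flag censored input", {
    tr <- assignTrueKrel(ecoliLeaderModel())
    pc <- simulatePool(tr, fTargets = 0.3, depth = 1e6, exact = TRUE)
    rrt <- relativeRates(pc, pseudocount = 0)
    m <- fitPWM(rrt)
    expect_equal(colSums(mainEffects(m)), rep(0, 6), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_identical(m@history$nExcluded, 0L)
})

test_that("sequence logos measure information content in bits", {
    lg <- logoMatrix(rep("ACGUAC", 5))
    expect_equal(lg@bits, rep(2, 6))
    expect_equal(colSums(lg@freq), rep(1, 6), tolerance = 1e-12,
                 ignore_attr = TRUE)
    set.seed(5)
    lg2 <- logoMatrix(sample(enumerateLeaders(), 2000))
    expect_lt(max(lg2@bits), 0.05)
    expect_error(logoMatrix(character(0)), "empty")
    expect_error(logoMatrix("ACG"), "hexamers")
})

test_that("model YAML serialization captures coefficients and terms", {
    m <- ecoliLeaderModel()
    f <- tempfile(fileext = ".yml")
    writeSpecificityModel(m, f)
    obj <- yaml::read_yaml(f)
    expect_length(obj$interactions, 3L)
    expect_equal(obj$mainEffects[["-2"]][1], 0.3)
})
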