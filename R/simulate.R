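#' Construct simulation ground truth for the randomized pool
#'
#' Bundles true relative rate constants (relative kcat/Km) and initial pool
#' weights for all 4096 leader variants. The truth is always rescaled so the
#' reference hexamer has k_rel exactly 1, mirroring the calibration of the
#' measured rate constants to the genomically encoded leader.
#'
#' @param trueKrel positive numeric of length 4096 in enumeration order, or
#'   named by hexamer.
#' @param weights initial pool fractions (default uniform); normalized to
#'   sum to 1.
#' @param reference calibration hexamer, default `"AAAAAG"`.
#' @return a [SimulationTruth-class].
#' @export
simulationTruth <- function(trueKrel,
                            weights = NULL,
                            reference = .DEFAULT_REFERENCE) {
    leaders <- enumerateLeaders()
    if (!is.null(names(trueKrel)))
        trueKrel <- trueKrel[match(leaders, normalizeLeader(names(trueKrel)))]
    trueKrel <- as.numeric(trueKrel)
    if (length(trueKrel) != 4096L || any(!is.finite(trueKrel)))
        stop("trueKrel must supply a finite value for every hexamer")
    reference <- normalizeLeader(reference)
    kref <- trueKrel[match(reference, leaders)]
    if (!is.finite(kref) || kref <= 0)
        stop("reference variant must have a positive rate constant")
    trueKrel <- trueKrel / kref
    if (is.null(weights)) weights <- rep(1 / 4096, 4096L)
    if (length(weights) != 4096L || any(weights < 0))
        stop("weights must be 4096 nonnegative values")
    weights <- weights / sum(weights)
    new("SimulationTruth", variant = leaders, trueKrel = trueKrel,
        weights = weights, reference = reference)
}

#' Assign true rate constants from a specificity model or explicit table
#'
#' When `model` is a [SpecificityModel-class], each variant's true k_rel is
#' `exp()` of the model's linear predictor, rescaled so the reference equals
#' exactly 1; an all-zero model therefore yields k_rel = 1 everywhere. A
#' numeric vector is taken as explicit k_rel values.
#'
#' @param model a `SpecificityModel` or a numeric vector (length 4096 or
#'   named by hexamer).
#' @inheritParams simulationTruth
#' @return a [SimulationTruth-class].
#' @export
assignTrueKrel <- function(model,
                           weights = NULL,
                           reference = .DEFAULT_REFERENCE) {
    if (is(model, "SpecificityModel")) {
        lnk <- predict(model, enumerateLeaders())
        if (any(!is.finite(lnk)))
            stop("model prediction is non-finite for some variants")
        simulationTruth(exp(lnk), weights = weights, reference = reference)
    } else if (is.numeric(model)) {
        simulationTruth(model, weights = weights, reference = reference)
    } else stop("model must be a SpecificityModel or a numeric table")
}

#' Log-normally skewed initial pool weights
#'
#' Emulates transcription bias in the starting pool: weights are drawn
#' log-normally (meanlog 0) and normalized.
#'
#' @param sdlog standard deviation of log weights (default 0.25, a mild
#'   skew).
#' @param seed optional integer seed.
#' @return numeric vector of 4096 weights summing to 1.
#' @export
skewedPoolWeights <- function(sdlog = 0.25, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    w <- stats::rlnorm(4096L, meanlog = 0, sdlog = sdlog)
    w / sum(w)
}

#' Solve for the kinetic exposure reaching a target fraction reacted
#'
#' Under internal competition at sub-saturating substrate every variant
#' depletes first-order in a shared exposure integral c:
#' F_i = exp(-k_i c). The total fraction reacted f(c) = 1 - sum w_i F_i(c)
#' is strictly increasing in c; this solves f(c) = f_target by bisection on
#' c between 0 and 50/min(k_i), to an absolute tolerance of 1e-10 on f.
#'
#' @param truth a [SimulationTruth-class].
#' @param fTarget target total fraction reacted, in [0, 1).
#' @return a [DepletionState-class].
#' @examples
#' tr <- simulationTruth(rep(1, 4096))
#' st <- solveExposure(tr, 0.3)   # exposure = -log(0.7), all F_i = 0.7
#' @export
solveExposure <- function(truth, fTarget) {
    stopifnot(is(truth, "SimulationTruth"))
    if (!is.numeric(fTarget) || length(fTarget) != 1L ||
        fTarget < 0 || fTarget >= 1)
        stop("fTarget must lie in [0, 1)")
    k <- truth@trueKrel
    w <- truth@weights
    if (fTarget == 0)
        return(new("DepletionState", exposure = 0,
                   fractionUnreacted = rep(1, length(k)), totalReacted = 0))
    fOf <- function(c) 1 - sum(w * exp(-k * c))
    lo <- 0
    hi <- 50 / min(k)
    if (fOf(hi) < fTarget)
        stop("fTarget unreachable within the exposure bracket")
    repeat {
        mid <- (lo + hi) / 2
        fm <- fOf(mid)
        if (abs(fm - fTarget) < 1e-10 || (hi - lo) < 1e-14 * max(1, hi))
            break
        if (fm < fTarget) lo <- mid else hi <- mid
    }
    new("DepletionState", exposure = mid,
        fractionUnreacted = exp(-k * mid), totalReacted = fOf(mid))
}

#' Sample sequencing reads of the residual pool
#'
#' Draws `depth` reads as a multinomial over variants with probabilities
#' proportional to w_i F_i (the residual substrate composition); at f = 0
#' the probabilities are the initial weights. With `exact = TRUE` no
#' sampling is done and the exact expected proportions times `depth` are
#' returned (the infinite-depth oracle mode).
#'
#' @param state a [DepletionState-class].
#' @param truth the matching [SimulationTruth-class].
#' @param depth reads for this sample (>= 1).
#' @param seed optional integer seed (same seed, identical counts).
#' @param exact logical; return expected counts instead of a draw.
#' @return numeric vector of 4096 counts named by hexamer.
#' @export
sampleReads <- function(state, truth, depth = 2e7, seed = NULL,
                        exact = FALSE) {
    stopifnot(is(state, "DepletionState"), is(truth, "SimulationTruth"))
    if (depth < 1) stop("depth must be >= 1")
    p <- truth@weights * state@fractionUnreacted
    p <- p / sum(p)
    counts <- if (exact) {
        depth * p
    } else {
        if (!is.null(seed)) set.seed(seed)
        as.numeric(stats::rmultinom(1L, size = as.integer(depth), prob = p))
    }
    names(counts) <- truth@variant
    counts
}

#' Build a PoolCounts container
#'
#' @param counts numeric matrix, 4096 variants x samples (rownames are
#'   hexamers in enumeration order).
#' @param f per-sample total fraction reacted (0 for the start sample).
#' @param replicate per-sample replicate id.
#' @return a [PoolCounts-class].
#' @export
poolCounts <- function(counts, f, replicate = 1L) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts))) rownames(counts) <- enumerateLeaders()
    replicate <- rep(replicate, length.out = ncol(counts))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("rep", replicate, "_f", f)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(replicate = replicate, f = as.numeric(f),
                            row.names = colnames(counts)))
    new("PoolCounts", se)
}

#' Simulate a full HTS-Kin pool-depletion experiment
#'
#' Solves the exposure for each target fraction reacted, then samples read
#' counts for the start sample (f = 0) and every timepoint of every
#' replicate. Default f targets 0.05, 0.15 and 0.30 cover the ~5-30%
#' conversion window at which aliquots are drawn.
#'
#' @inheritParams sampleReads
#' @param fTargets total-fraction-reacted sampling points in (0, 1).
#' @param replicates number of technical replicates (each gets its own
#'   start sample and draws).
#' @param depth reads per sample. The default 2e7 corresponds to a share of
#'   a single Illumina lane per sample and is deep enough that the
#'   reference's small depletion at the shallowest default timepoint
#'   (f = 0.05) stands clear of counting noise; at much lower depth the
#'   reference can show no apparent depletion at that timepoint and the
#'   timepoint is then dropped by [relativeRates()].
#' @return a [PoolCounts-class] with `metadata()` recording the seed, depth
#'   and the exact exposures used.
#' @export
simulatePool <- function(truth, fTargets = c(0.05, 0.15, 0.30),
                         depth = 2e7, replicates = 1L, seed = NULL,
                         exact = FALSE) {
    stopifnot(is(truth, "SimulationTruth"))
    if (any(fTargets <= 0 | fTargets >= 1))
        stop("fTargets must lie in (0, 1)")
    if (!is.null(seed)) set.seed(seed)
    states <- lapply(fTargets, solveExposure, truth = truth)
    state0 <- solveExposure(truth, 0)
    cols <- list()
    f <- numeric()
    rep_id <- integer()
    for (r in seq_len(replicates)) {
        cols[[length(cols) + 1L]] <-
            sampleReads(state0, truth, depth, exact = exact)
        f <- c(f, 0)
        rep_id <- c(rep_id, r)
        for (j in seq_along(fTargets)) {
            cols[[length(cols) + 1L]] <-
                sampleReads(states[[j]], truth, depth, exact = exact)
            f <- c(f, states[[j]]@totalReacted)
            rep_id <- c(rep_id, r)
        }
    }
    m <- do.call(cbind, cols)
    colnames(m) <- paste0("rep", rep_id, "_f", signif(f, 3))
    pc <- poolCounts(m, f = f, replicate = rep_id)
    metadata(pc) <- list(seed = seed, depth = depth, exact = exact,
                         exposures = vapply(states, slot, numeric(1),
                                            "exposure"),
                         fTargets = fTargets)
    pc
}

#' Simulate initial-rate data for a Michaelis-Menten fit
#'
#' v = kcat * E0 * S / (Km + S), with optional homoscedastic Gaussian noise
#' and replicate structure. Either `Km` or `kcatKm` must be given.
#'
#' @param kcat catalytic rate constant (s^-1).
#' @param Km Michaelis constant, same units as `S`.
#' @param kcatKm specificity constant kcat/Km (1 / (conc * s)); used to
#'   derive Km when `Km` is missing.
#' @param E0 enzyme concentration.
#' @param S substrate concentration grid (default 10 nM - 1 uM expressed in
#'   nM).
#' @param noiseSD Gaussian noise SD on v (same units as v; 0 = noiseless).
#' @param replicates replicates per concentration (default 3).
#' @param seed optional integer seed.
#' @return data.frame with columns `S`, `v`, `replicate`.
#' @export
simulateInitialRates <- function(kcat, Km = NULL, kcatKm = NULL, E0 = 1,
                                 S = c(10, 20, 50, 100, 200, 500, 1000),
                                 noiseSD = 0, replicates = 3L, seed = NULL) {
    if (is.null(Km)) {
        if (is.null(kcatKm)) stop("supply Km or kcatKm")
        Km <- kcat / kcatKm
    }
    if (kcat <= 0 || Km <= 0 || E0 <= 0)
        stop("kcat, Km and E0 must be positive")
    if (noiseSD < 0) stop("noiseSD must be nonnegative")
    if (!is.null(seed)) set.seed(seed)
    d <- expand.grid(S = S, replicate = seq_len(replicates))
    d$v <- kcat * E0 * d$S / (Km + d$S)
    if (noiseSD > 0) d$v <- d$v + stats::rnorm(nrow(d), 0, noiseSD)
    d[, c("S", "v", "replicate")]
}

#' Simulate an equilibrium binding isotherm
#'
#' y = Bmax * E / (Kd + E) with optional Gaussian noise.
#'
#' @param Kd dissociation constant, same units as `E`.
#' @param Bmax maximum fraction bound.
#' @param E enzyme concentration grid (default 2.5-200 nM).
#' @inheritParams simulateInitialRates
#' @return data.frame with columns `E`, `y`, `replicate`.
#' @export
simulateBinding <- function(Kd, Bmax = 1,
                            E = c(2.5, 5, 10, 20, 40, 80, 120, 200),
                            noiseSD = 0, replicates = 1L, seed = NULL) {
    if (Kd <= 0 || Bmax <= 0) stop("Kd and Bmax must be positive")
    if (noiseSD < 0) stop("noiseSD must be nonnegative")
    if (!is.null(seed)) set.seed(seed)
    d <- expand.grid(E = E, replicate = seq_len(replicates))
    d$y <- Bmax * d$E / (Kd + d$E)
    if (noiseSD > 0) d$y <- d$y + stats::rnorm(nrow(d), 0, noiseSD)
    d[, c("E", "y", "replicate")]
}

#' Simulate biphasic dissociation of enzyme-substrate complexes
#'
#' bound(t) = (1 - fracFast) exp(-kSlow t) + fracFast exp(-kFast t). The
#' fast phase corresponds to loosely bound encounter complexes (ES), the
#' slow phase to the committed ES* state.
#'
#' @param fracFast fraction of complexes in the fast-dissociating phase,
#'   in \[0, 1\].
#' @param kFast,kSlow phase rate constants; `kFast > kSlow >= 0`.
#' @param t time grid (same time unit as the rate constants).
#' @inheritParams simulateInitialRates
#' @return data.frame with columns `t`, `bound`, `replicate`.
#' @export
simulateDissociation <- function(fracFast, kFast, kSlow = 0,
                                 t = c(0, 0.5, 1, 2, 4, 8, 15, 30, 60),
                                 noiseSD = 0, replicates = 1L, seed = NULL) {
    if (fracFast < 0 || fracFast > 1) stop("fracFast must lie in [0, 1]")
    if (!(kFast > kSlow) || kSlow < 0)
        stop("need kFast > kSlow >= 0")
    if (noiseSD < 0) stop("noiseSD must be nonnegative")
    if (!is.null(seed)) set.seed(seed)
    d <- expand.grid(t = t, replicate = seq_len(replicates))
    d$bound <- (1 - fracFast) * exp(-kSlow * d$t) +
        fracFast * exp(-kFast * d$t)
    if (noiseSD > 0) d$bound <- d$bound + stats::rnorm(nrow(d), 0, noiseSD)
    d[, c("t", "bound", "replicate")]
}

#' A specificity landscape with the hallmarks measured for E. coli RNase P
#'
#' Returns a [SpecificityModel-class] whose main effects favor A at N(-2)
#' and C at N(-4) with U optimal at N(-5)/N(-6), penalize G at N(-1) to
#' N(-4), and whose interaction terms penalize the N(-2)N(-1) dinucleotides
#' GU, GG and UG that can pair with the 3' RCCA tail. The implied k_rel
#' distribution spans roughly two orders of magnitude. Intended as a
#' realistic ground truth for simulation studies.
#'
#' @return a `SpecificityModel`.
#' @export
ecoliLeaderModel <- function() {
    me <- cbind(
        `-6` = c(0,    0.05, -0.15, 0.10),
        `-5` = c(0,    0.05, -0.20, 0.15),
        `-4` = c(-0.10, 0.40, -0.30, 0),
        `-3` = c(0.10, 0,    -0.25, 0.15),
        `-2` = c(0.30, 0,    -0.10, -0.20),
        `-1` = c(0.10, 0,    -0.50, 0.40))
    rownames(me) <- .BASES
    ia <- data.frame(
        pos1 = -2L, pos2 = -1L,
        base1 = c("G", "G", "U"), base2 = c("U", "G", "G"),
        alpha = c(-1.1, -1.3, -1.0),
        se = NA_real_, tvalue = NA_real_, tAdmission = NA_real_,
        round = NA_integer_, stringsAsFactors = FALSE)
    new("SpecificityModel", intercept = 0, mainEffects = me,
        mainSE = me * 0, interactions = ia, r2 = NA_real_,
        sigma = NA_real_, nobs = 0L, df.residual = 0L, history = list())
}

#' Write simulation truth to CSV with a YAML sidecar
#'
#' @param truth a [SimulationTruth-class].
#' @param file CSV path; the sidecar is written to `<file>.yml`.
#' @param params optional named list of simulation parameters (seed, depth,
#'   f targets) to record in the sidecar.
#' @return `file`, invisibly.
#' @export
writeTruth <- function(truth, file, params = list()) {
    utils::write.csv(
        data.frame(variant = truth@variant, true_krel = truth@trueKrel,
                   weight = truth@weights),
        file, row.names = FALSE)
    side <- c(list(reference = truth@reference), params)
    yaml::write_yaml(side, paste0(file, ".yml"))
    invisible(file)
}
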