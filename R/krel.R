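#' Per-variant fraction unreacted from two pool samples
#'
#' Under internal competition the residual-pool read proportions determine
#' each variant's fraction unreacted:
#' `F_i = (1 - f) * p_i(f) / p_i(0)`, where `p_i` is the read proportion of
#' variant i in the sample and `f` the total fraction of substrate reacted
#' when the sample was drawn. When no pseudocounts fire, the
#' initial-proportion-weighted mean of `F` equals `1 - f` exactly.
#'
#' @param counts0 counts at the start of the reaction (f = 0).
#' @param countsF counts at fraction reacted `f` (same replicate).
#' @param f total fraction reacted, in (0, 1).
#' @param pseudocount added to every cell before forming proportions
#'   (default 0.5; use 0 for exact/expected-count input).
#' @return numeric vector of `F_i`, named as the input.
#' @export
fractionUnreacted <- function(counts0, countsF, f, pseudocount = 0.5) {
    if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 1)
        stop("f must lie in (0, 1)")
    if (length(counts0) != length(countsF))
        stop("count vectors must align")
    c0 <- counts0 + pseudocount
    cf <- countsF + pseudocount
    p0 <- c0 / sum(c0)
    pf <- cf / sum(cf)
    (1 - f) * pf / p0
}

#' Relative rate constants by internal competition kinetics
#'
#' For each timepoint sample the per-variant relative specificity constant
#' is `k_rel,i = ln(F_i) / ln(F_ref)` with `F` from [fractionUnreacted()];
#' estimates are combined across timepoints and replicates by an
#' inverse-variance weighted mean on the ln scale (variances from binomial
#' counting error propagated through the log-ratio) and calibrated so the
#' reference variant is exactly 1.
#'
#' Variants whose apparent `F_i >= 1` at a timepoint (apparent enrichment,
#' possible for very slow variants at finite depth) contribute nothing at
#' that timepoint; a variant with no usable timepoint is flagged
#' `"censored_low"` and its k_rel reported `NA`. Variants with zero reads in
#' every start sample are flagged `"unobserved"`. A timepoint at which the
#' reference itself shows no depletion (`F_ref >= 1`, possible at shallow
#' depth and small f) carries no usable internal-competition signal for any
#' variant and is dropped with a warning; if no timepoint is usable this is
#' a hard error.
#'
#' @param pc a [PoolCounts-class].
#' @param reference calibration hexamer (default `"AAAAAG"`).
#' @param pseudocount see [fractionUnreacted()].
#' @return a [RelRateTable-class].
#' @export
relativeRates <- function(pc, reference = .DEFAULT_REFERENCE,
                          pseudocount = 0.5) {
    stopifnot(is(pc, "PoolCounts"))
    reference <- normalizeLeader(reference)
    cts <- assay(pc, "counts")
    cd <- colData(pc)
    leaders <- rownames(cts)
    iref <- match(reference, leaders)
    if (is.na(iref)) stop("reference variant not in the pool")
    tp <- which(cd$f > 0)
    if (!length(tp)) stop("no timepoint samples (f > 0) present")
    if (any(cts[iref, ] + pseudocount <= 0))
        stop("reference variant must have support in every sample")

    lnk <- matrix(NA_real_, nrow = nrow(cts), ncol = length(tp),
                  dimnames = list(leaders, colnames(cts)[tp]))
    wts <- lnk
    dropped <- character()
    for (j in seq_along(tp)) {
        s <- tp[j]
        s0 <- which(cd$replicate == cd$replicate[s] & cd$f == 0)
        if (length(s0) != 1L)
            stop("replicate ", cd$replicate[s], " lacks a unique f = 0 sample")
        f <- cd$f[s]
        Fi <- fractionUnreacted(cts[, s0], cts[, s], f, pseudocount)
        if (Fi[iref] >= 1) {
            warning("reference shows no depletion at sample '",
                    colnames(cts)[s], "' (F_ref >= 1); timepoint dropped")
            dropped <- c(dropped, colnames(cts)[s])
            next
        }
        vlnF <- 1 / (cts[, s] + pseudocount) + 1 / (cts[, s0] + pseudocount)
        usable <- Fi < 1
        lF <- log(Fi)
        k <- lF / lF[iref]
        vlnk <- vlnF / lF^2 + vlnF[iref] / lF[iref]^2
        lnk[usable, j] <- log(k[usable])
        wts[usable, j] <- 1 / vlnk[usable]
    }

    if (length(dropped) == length(tp))
        stop("reference variant shows no depletion at any timepoint ",
             "(F_ref >= 1); the run carries no usable kinetic signal")
    sw <- rowSums(wts, na.rm = TRUE)
    lnkHat <- rowSums(lnk * wts, na.rm = TRUE) / sw
    nT <- rowSums(!is.na(lnk))
    lnkHat[nT == 0L] <- NA_real_
    se <- ifelse(nT > 0L, 1 / sqrt(sw), NA_real_)
    ## calibrate: reference ln k_rel is 0 by construction at every
    ## timepoint, so this subtraction is an exact no-op on clean data and
    ## makes recalibration idempotent in general
    lnkHat <- lnkHat - lnkHat[iref]

    reads0 <- rowSums(cts[, cd$f == 0, drop = FALSE])
    flag <- ifelse(reads0 == 0, "unobserved",
                   ifelse(nT == 0L, "censored_low", "ok"))
    tab <- DataFrame(variant = leaders, krel = exp(lnkHat), se = se,
                     nTimepoints = as.integer(nT), reads0 = reads0,
                     flag = flag)
    tab$perTimepoint <- exp(lnk)
    new("RelRateTable", table = tab, reference = reference)
}

#' Recalibrate a rate table to a (possibly new) reference variant
#'
#' Divides all k_rel by the reference's value; recalibrating to the current
#' reference is an exact no-op.
#'
#' @param rrt a [RelRateTable-class].
#' @param reference hexamer to calibrate to.
#' @return a recalibrated `RelRateTable`.
#' @export
calibrate <- function(rrt, reference = referenceVariant(rrt)) {
    stopifnot(is(rrt, "RelRateTable"))
    reference <- normalizeLeader(reference)
    i <- match(reference, rrt@table$variant)
    if (is.na(i)) stop("reference variant not present")
    kref <- rrt@table$krel[i]
    if (!is.finite(kref) || kref <= 0)
        stop("reference variant has no usable k_rel")
    rrt@table$krel <- rrt@table$krel / kref
    if (!is.null(rrt@table$perTimepoint))
        rrt@table$perTimepoint <- sweep(rrt@table$perTimepoint, 2,
                                        rrt@table$perTimepoint[i, ], "/")
    rrt@reference <- reference
    validObject(rrt)
    rrt
}

#' Relative rate constants via the reference-ratio (pool-sum) formula
#'
#' Algebraically equivalent route to the same k_rel: with `R_i` the
#' variant-to-reference read ratio at the timepoint and `R_i0` the same
#' ratio at the start, and the initial-weighted pool sum
#' `S = sum_j p_j(0) R_j / R_j0` (which normalizes the reference's own
#' depletion, `S = (1 - f) / F_ref`),
#' `k_rel,i = ln((1-f) / ((R_i0/R_i) S)) / ln((1-f) / S)`.
#' Provided as an independently coded cross-check of the
#' `ln F_i / ln F_ref` route used by [relativeRates()]; the two agree to
#' machine precision.
#'
#' @inheritParams fractionUnreacted
#' @param reference calibration hexamer.
#' @return numeric vector of per-variant k_rel for this timepoint.
#' @export
krelReferenceRatioForm <- function(counts0, countsF, f,
                                   reference = .DEFAULT_REFERENCE,
                                   pseudocount = 0.5) {
    if (f <= 0 || f >= 1) stop("f must lie in (0, 1)")
    nm <- names(counts0)
    iref <- match(normalizeLeader(reference), normalizeLeader(nm))
    if (is.na(iref)) stop("reference variant not found")
    c0 <- counts0 + pseudocount
    cf <- countsF + pseudocount
    R0 <- c0 / c0[iref]
    R <- cf / cf[iref]
    p0 <- c0 / sum(c0)
    S <- sum(p0 * R / R0)
    log((1 - f) / ((R0 / R) * S)) / log((1 - f) / S)
}

#' Histogram of the rate constant distribution
#'
#' Bins k_rel on a log scale, optionally tallying named variant subsets
#' (e.g. the AU and GG dinucleotide subsets) in the same bins.
#'
#' @param rrt a [RelRateTable-class] (flagged variants are dropped) or a
#'   positive numeric vector named by variant.
#' @param bins number of log-spaced bins (default 30).
#' @param subsets optional named list of hexamer vectors to overlay.
#' @return data.frame with `lower`, `upper`, `mid` (bin edges/geometric
#'   midpoint), `count`, and one extra count column per subset.
#' @export
rateDistribution <- function(rrt, bins = 30L, subsets = NULL) {
    k <- if (is(rrt, "RelRateTable")) {
        kk <- krel(rrt)
        kk[rrt@table$flag == "ok"]
    } else rrt
    k <- k[is.finite(k) & k > 0]
    lk <- log10(k)
    pad <- if (diff(range(lk)) < 1e-9) 0.5 else 0  # degenerate: widen
    br <- seq(min(lk) - pad, max(lk) + pad, length.out = bins + 1L)
    br[1] <- br[1] - 1e-9
    br[bins + 1L] <- br[bins + 1L] + 1e-9
    cut_all <- cut(lk, br)
    d <- data.frame(lower = 10^br[-(bins + 1L)], upper = 10^br[-1L],
                    mid = 10^((br[-(bins + 1L)] + br[-1L]) / 2),
                    count = as.integer(table(cut_all)))
    for (nm in names(subsets)) {
        ks <- k[names(k) %in% normalizeLeader(subsets[[nm]])]
        d[[nm]] <- as.integer(table(cut(log10(ks), br)))
    }
    d
}

#' Fastest fraction of the pool
#'
#' The `ceiling(q * N)` variants with the largest k_rel; ties broken
#' deterministically by pool (lexicographic) index. Flagged variants are
#' excluded.
#'
#' @param rrt a [RelRateTable-class].
#' @param q fraction in (0, 1) (default 0.01, the "fastest 1%").
#' @return character vector of hexamers, fastest first.
#' @export
topFraction <- function(rrt, q = 0.01) {
    stopifnot(is(rrt, "RelRateTable"))
    if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
    tab <- rrt@table[rrt@table$flag == "ok", ]
    n <- ceiling(q * nrow(rrt@table))
    o <- order(-tab$krel, leaderIndex(tab$variant))
    tab$variant[o][seq_len(min(n, nrow(tab)))]
}

#' Write a rate table as CSV
#'
#' @param rrt a [RelRateTable-class].
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
writeRelRates <- function(rrt, file) {
    utils::write.csv(as.data.frame(rrt), file, row.names = FALSE)
    invisible(file)
}
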