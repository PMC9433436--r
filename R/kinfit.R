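.asXY <- function(data, x, y, xname, yname) {
    if (is.data.frame(data)) {
        if (!all(c(xname, yname) %in% colnames(data)))
            stop("data needs columns '", xname, "' and '", yname, "'")
        list(x = data[[xname]], y = data[[yname]],
             replicate = data$replicate)
    } else list(x = data, y = y, replicate = NULL)
}

## Aggregate replicate measurements: mean, SD and count per x value.
.aggregateReplicates <- function(x, y) {
    sp <- split(y, x)
    xs <- as.numeric(names(sp))
    o <- order(xs)
    data.frame(x = xs[o],
               y = vapply(sp, mean, numeric(1))[o],
               sd = vapply(sp, function(v)
                   if (length(v) > 1) sd(v) else NA_real_, numeric(1))[o],
               n = vapply(sp, length, integer(1))[o])
}

## Replicate-SD weights with a floor at the 10th percentile SD so that a
## chance zero-SD replicate set cannot get infinite weight.
.sdWeights <- function(sd) {
    if (all(is.na(sd))) return(NULL)
    floorSD <- quantile(sd[!is.na(sd) & sd > 0], 0.1, na.rm = TRUE)
    if (!is.finite(floorSD) || floorSD <= 0) return(NULL)
    1 / pmax(sd, floorSD, na.rm = TRUE)^2
}

.nlsMultiStart <- function(formula, data, start, lower, weights = NULL,
                           perturb = "Km") {
    tries <- c(1, 10^seq(-2, 2, length.out = 5))
    for (mult in tries) {
        st <- start
        st[[perturb]] <- start[[perturb]] * mult
        args <- list(formula, data = data, start = st, lower = lower,
                     control = minpack.lm::nls.lm.control(maxiter = 500))
        if (!is.null(weights)) args$weights <- weights
        fit <- tryCatch(do.call(minpack.lm::nlsLM, args),
                        error = function(e) NULL)
        if (!is.null(fit)) return(fit)
    }
    NULL
}

#' Initial rate from a reaction time course
#'
#' The reacted fraction between 0 and 0.1 is fit by linear regression
#' against time; the initial rate is the slope times the initial substrate
#' concentration. Points above 10% conversion are excluded (reported in
#' `info`); fewer than 3 qualifying points is an error. For substrates with
#' several product bands the fractions must already be summed.
#'
#' @param time time points (seconds).
#' @param fraction reacted fraction at each time point.
#' @param S0 initial substrate concentration.
#' @return an [AssayFit-class] with `coef` `slope` (s^-1) and `v`
#'   (concentration per second, units of `S0`).
#' @export
fitInitialRate <- function(time, fraction, S0) {
    keep <- is.finite(fraction) & fraction >= 0 & fraction <= 0.1
    if (sum(keep) < 3L)
        stop("fewer than 3 time points with reacted fraction <= 0.1")
    fit <- lm(fraction[keep] ~ time[keep])
    slope <- unname(coef(fit)[2])
    seSlope <- summary(fit)$coefficients[2, 2]
    new("AssayFit", assay = "initial_rate",
        coef = c(slope = slope, v = slope * S0),
        se = c(slope = seSlope, v = seSlope * S0),
        vcov = matrix(seSlope^2, 1, 1, dimnames = list("slope", "slope")),
        fitted = fitted(fit), residuals = residuals(fit),
        data = data.frame(time = time[keep], fraction = fraction[keep]),
        info = list(nExcluded = sum(!keep), S0 = S0, flags = character()))
}

#' Weighted Michaelis-Menten fit
#'
#' Nonlinear least squares of `v = kcat * E0 * S / (Km + S)`. Replicates at
#' each substrate concentration are averaged and, when replicate SDs are
#' available, the fit is weighted by 1/SD^2 (with a floor at the 10th
#' percentile SD); otherwise unweighted. kcat/Km is reported as the ratio
#' with a delta-method standard error. Starting values come from the
#' half-saturation point, with log-spaced multi-start on non-convergence.
#' If the fitted Km lies far above the sampled S range it is flagged
#' unidentifiable and kcat/Km is reported from the linear (first-order)
#' regime instead.
#'
#' @param data data.frame with columns `S`, `v` (and optionally
#'   `replicate`), or a numeric vector of substrate concentrations.
#' @param v initial rates when `data` is a vector.
#' @param E0 enzyme concentration (same concentration units as `S`; rates
#'   are then in those units per second).
#' @param weighted use replicate-SD weights when available (default TRUE).
#' @return an [AssayFit-class] with `coef` `kcat`, `Km`, `kcatKm`.
#' @examples
#' d <- simulateInitialRates(kcat = 0.12, kcatKm = 7e6 * 1e-9, E0 = 1)
#' fitMichaelisMenten(d, E0 = 1)   # recovers kcat = 0.12 exactly
#' @export
fitMichaelisMenten <- function(data, v = NULL, E0, weighted = TRUE) {
    xy <- .asXY(data, data, v, "S", "v")
    agg <- .aggregateReplicates(xy$x, xy$y)
    if (nrow(agg) < 3L) stop("need at least 3 distinct substrate levels")
    w <- if (weighted) .sdWeights(agg$sd) else NULL
    vmax0 <- max(agg$y)
    Km0 <- approx(agg$y, agg$x, xout = vmax0 / 2, ties = "ordered")$y
    if (!is.finite(Km0) || Km0 <= 0) Km0 <- median(agg$x)
    df <- data.frame(S = agg$x, v = agg$y)
    fit <- .nlsMultiStart(v ~ kcat * E0 * S / (Km + S), df,
                          start = list(kcat = vmax0 / E0, Km = Km0),
                          lower = c(0, 0), weights = w, perturb = "Km")
    if (is.null(fit))
        stop("Michaelis-Menten fit did not converge; S range ",
             min(agg$x), "-", max(agg$x))
    cf <- coef(fit)
    V <- vcov(fit)
    flags <- character()
    kcatKm <- cf[["kcat"]] / cf[["Km"]]
    relVar <- V["kcat", "kcat"] / cf[["kcat"]]^2 +
        V["Km", "Km"] / cf[["Km"]]^2 -
        2 * V["kcat", "Km"] / (cf[["kcat"]] * cf[["Km"]])
    seKcatKm <- abs(kcatKm) * sqrt(max(relVar, 0))
    if (cf[["Km"]] > 10 * max(agg$x)) {
        flags <- c(flags, "Km_unidentifiable")
        lin <- lm(agg$y ~ agg$x - 1)
        kcatKm <- unname(coef(lin)[1]) / E0
        seKcatKm <- summary(lin)$coefficients[1, 2] / E0
    }
    new("AssayFit", assay = "michaelis_menten",
        coef = c(kcat = unname(cf["kcat"]), Km = unname(cf["Km"]),
                 kcatKm = kcatKm),
        se = c(kcat = sqrt(V["kcat", "kcat"]), Km = sqrt(V["Km", "Km"]),
               kcatKm = seKcatKm),
        vcov = V, fitted = fitted(fit), residuals = residuals(fit),
        data = cbind(df, sd = agg$sd, n = agg$n),
        info = list(E0 = E0, weighted = !is.null(w), flags = flags))
}

#' Equilibrium binding isotherm fit
#'
#' Nonlinear least squares of `y = Bmax * E / (Kd + E)` for fraction bound
#' versus enzyme concentration, as used with trace substrate so that total
#' enzyme stands in for free enzyme. A quadratic tight-binding form (which
#' accounts for substrate at concentration `S0` depleting the enzyme) is
#' available but off by default.
#'
#' @param data data.frame with columns `E`, `y` (and optionally
#'   `replicate`), or a numeric vector of enzyme concentrations.
#' @param y fractions bound when `data` is a vector.
#' @param tightBinding use the quadratic form (requires `S0`).
#' @param S0 substrate concentration for the quadratic form.
#' @param weighted use replicate-SD weights when available.
#' @return an [AssayFit-class] with `coef` `Kd`, `Bmax`. The fit is flagged
#'   when Kd falls more than 10x outside the sampled E range.
#' @export
fitBinding <- function(data, y = NULL, tightBinding = FALSE, S0 = NULL,
                       weighted = TRUE) {
    xy <- .asXY(data, data, y, "E", "y")
    agg <- .aggregateReplicates(xy$x, xy$y)
    if (nrow(agg) < 4L) stop("need at least 4 enzyme concentrations")
    w <- if (weighted) .sdWeights(agg$sd) else NULL
    Bmax0 <- max(agg$y)
    Kd0 <- approx(agg$y, agg$x, xout = Bmax0 / 2, ties = "ordered")$y
    if (!is.finite(Kd0) || Kd0 <= 0) Kd0 <- median(agg$x)
    df <- data.frame(E = agg$x, y = agg$y)
    if (tightBinding) {
        if (is.null(S0)) stop("tightBinding requires S0")
        form <- y ~ Bmax * ((E + S0 + Kd) -
            sqrt((E + S0 + Kd)^2 - 4 * E * S0)) / (2 * S0)
        df$S0 <- S0
    } else form <- y ~ Bmax * E / (Kd + E)
    fit <- .nlsMultiStart(form, df, start = list(Bmax = Bmax0, Kd = Kd0),
                          lower = c(0, 0), weights = w, perturb = "Kd")
    if (is.null(fit)) stop("binding fit did not converge")
    cf <- coef(fit)
    V <- vcov(fit)
    flags <- character()
    if (cf[["Kd"]] > 10 * max(agg$x) || cf[["Kd"]] < min(agg$x) / 10)
        flags <- "Kd_outside_E_range"
    new("AssayFit", assay = "binding",
        coef = c(Kd = unname(cf["Kd"]), Bmax = unname(cf["Bmax"])),
        se = c(Kd = sqrt(V["Kd", "Kd"]), Bmax = sqrt(V["Bmax", "Bmax"])),
        vcov = V, fitted = fitted(fit), residuals = residuals(fit),
        data = cbind(df, sd = agg$sd, n = agg$n),
        info = list(tightBinding = tightBinding, weighted = !is.null(w),
                    flags = flags))
}

.aiccRSS <- function(rss, n, k) {
    rss <- max(rss, n * 1e-12)  # floor: don't let machine-epsilon RSS
                                # differences drive model selection
    k <- k + 1  # + residual variance
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Biphasic dissociation fit with model selection
#'
#' Fits `bound(t) = Aslow exp(-kslow t) + Afast exp(-kfast t)` to a
#' dissociation time course normalized to t = 0, and compares it with a
#' single exponential by AICc. The slow amplitude estimates the fraction of
#' complexes in the committed ES* state, the fast amplitude the loosely
#' bound ES fraction. If the two-phase fit does not converge the single
#' exponential is returned with a flag.
#'
#' @param data data.frame with columns `t`, `bound`, or a numeric time
#'   vector.
#' @param bound fractions bound when `data` is a vector.
#' @param normalize divide by the t = 0 value first (default TRUE).
#' @return an [AssayFit-class] with `coef` `Aslow`, `Afast`, `kslow`,
#'   `kfast`; `info$model` is `"one_phase"` or `"two_phase"`.
#' @export
fitDissociation <- function(data, bound = NULL, normalize = TRUE) {
    xy <- .asXY(data, data, bound, "t", "bound")
    t <- xy$x
    b <- xy$y
    if (!any(t == 0)) stop("a t = 0 point is required")
    if (normalize) b <- b / mean(b[t == 0])
    agg <- .aggregateReplicates(t, b)
    df <- data.frame(t = agg$x, bound = agg$y)
    n <- nrow(df)
    tpos <- df$t[df$t > 0]
    plateau <- mean(df$bound[df$t >= max(df$t) * 0.5])
    kf0 <- log(2) / min(tpos)
    ks0 <- max(-log(max(plateau, 0.02)) / max(df$t), 1e-6)

    one <- .nlsMultiStart(bound ~ A1 * exp(-k1 * t), df,
                          start = list(A1 = 1, k1 = ks0 + 1e-3),
                          lower = c(0, 0), perturb = "k1")
    two <- .nlsMultiStart(
        bound ~ Aslow * exp(-kslow * t) + Afast * exp(-kfast * t), df,
        start = list(Aslow = max(plateau, 0.05),
                     Afast = max(1 - plateau, 0.05),
                     kslow = ks0, kfast = kf0),
        lower = c(0, 0, 0, 0), perturb = "kfast")

    flags <- character()
    useTwo <- FALSE
    if (is.null(two) && is.null(one))
        stop("dissociation fit did not converge")
    if (!is.null(two) && !is.null(one)) {
        a1 <- .aiccRSS(sum(residuals(one)^2), n, 2)
        a2 <- .aiccRSS(sum(residuals(two)^2), n, 4)
        useTwo <- a2 < a1
    } else if (!is.null(two)) useTwo <- TRUE
    else flags <- "two_phase_nonconvergent"

    if (useTwo) {
        cf <- coef(two)
        if (cf[["kfast"]] < cf[["kslow"]]) {  # relabel phases if swapped
            cf <- c(Aslow = cf[["Afast"]], Afast = cf[["Aslow"]],
                    kslow = cf[["kfast"]], kfast = cf[["kslow"]])
        }
        V <- vcov(two)
        se <- sqrt(diag(V))[c("Aslow", "Afast", "kslow", "kfast")]
        new("AssayFit", assay = "dissociation",
            coef = c(Aslow = unname(cf["Aslow"]), Afast = unname(cf["Afast"]),
                     kslow = unname(cf["kslow"]), kfast = unname(cf["kfast"])),
            se = se, vcov = V, fitted = fitted(two),
            residuals = residuals(two), data = df,
            info = list(model = "two_phase", flags = flags,
                        esStarFraction = unname(cf["Aslow"]),
                        esFraction = unname(cf["Afast"])))
    } else {
        cf <- coef(one)
        V <- vcov(one)
        new("AssayFit", assay = "dissociation",
            coef = c(Aslow = unname(cf["A1"]), Afast = 0,
                     kslow = unname(cf["k1"]), kfast = NA_real_),
            se = c(Aslow = sqrt(V["A1", "A1"]), Afast = 0,
                   kslow = sqrt(V["k1", "k1"]), kfast = NA_real_),
            vcov = V, fitted = fitted(one), residuals = residuals(one),
            data = df,
            info = list(model = "one_phase", flags = flags,
                        esStarFraction = unname(cf["A1"]),
                        esFraction = 0))
    }
}

#' Fold changes between fitted constructs
#'
#' Ratios of fitted parameters (kcat, kcat/Km, Kd where present) across a
#' named set of assay fits, relative to a reference construct, with
#' standard errors propagated as relative errors in quadrature. Construct
#' names are free-form (e.g. AU, AU_T5, AU_D3, AU_T5D3, GG, GG_D3).
#'
#' @param fits named list of [AssayFit-class] objects (>= 2).
#' @param reference name of the reference construct (default the first).
#' @return data.frame with `construct`, `parameter`, `value`, `fold`
#'   (construct / reference) and `foldSE`.
#' @export
foldChanges <- function(fits, reference = names(fits)[1]) {
    if (length(fits) < 2L) stop("need at least 2 named fits")
    if (is.null(names(fits)) || !reference %in% names(fits))
        stop("fits must be named and include the reference")
    pars <- c("kcat", "kcatKm", "Kd")
    ref <- fits[[reference]]
    out <- list()
    for (nm in names(fits)) {
        ft <- fits[[nm]]
        for (p in intersect(pars, intersect(names(coef(ft)),
                                            names(coef(ref))))) {
            val <- coef(ft)[[p]]
            rv <- coef(ref)[[p]]
            fold <- val / rv
            rel <- sqrt((ft@se[[p]] / val)^2 + (ref@se[[p]] / rv)^2)
            out[[length(out) + 1L]] <- data.frame(
                construct = nm, parameter = p, value = val,
                fold = fold, foldSE = abs(fold) * rel,
                stringsAsFactors = FALSE)
        }
    }
    d <- do.call(rbind, out)
    attr(d, "reference") <- reference
    d
}
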