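#' @describeIn SimulationTruth-class the 4096 leader hexamers.
#' @export
setMethod("variants", "SimulationTruth", function(object) object@variant)

#' @describeIn SimulationTruth-class named vector of true relative rate
#'   constants.
#' @export
setMethod("trueKrel", "SimulationTruth", function(object)
    setNames(object@trueKrel, object@variant))

#' @describeIn SimulationTruth-class named vector of initial pool weights.
#' @export
setMethod("poolWeights", "SimulationTruth", function(object)
    setNames(object@weights, object@variant))

#' @describeIn SimulationTruth-class the calibration hexamer.
#' @export
setMethod("referenceVariant", "SimulationTruth", function(object)
    object@reference)

setMethod("show", "SimulationTruth", function(object) {
    rng <- range(object@trueKrel)
    cat("SimulationTruth: 4096 leader hexamers N(-6)..N(-1)\n",
        "  reference ", object@reference, " (k_rel = 1)\n",
        sprintf("  true k_rel range: %.4g .. %.4g (%.3g-fold)\n",
                rng[1], rng[2], rng[2] / rng[1]),
        sep = "")
})

#' @describeIn RelRateTable-class per-variant k_rel, named by hexamer.
#' @export
setMethod("krel", "RelRateTable", function(object)
    setNames(object@table$krel, object@table$variant))

#' @describeIn RelRateTable-class standard error of ln k_rel per variant.
#' @export
setMethod("krelSE", "RelRateTable", function(object)
    setNames(object@table$se, object@table$variant))

#' @describeIn RelRateTable-class variant hexamers.
#' @export
setMethod("variants", "RelRateTable", function(object) object@table$variant)

#' @describeIn RelRateTable-class the calibration hexamer.
#' @export
setMethod("referenceVariant", "RelRateTable", function(object)
    object@reference)

#' Underlying table of a RelRateTable
#'
#' @param x a [RelRateTable-class] object.
#' @param ... ignored.
#' @return a `DataFrame` with one row per variant.
#' @export
as.data.frame.RelRateTable <- function(x, ...) {
    as.data.frame(x@table[, setdiff(colnames(x@table), "perTimepoint")])
}

setMethod("show", "RelRateTable", function(object) {
    k <- object@table$krel
    ok <- object@table$flag == "ok"
    cat("RelRateTable: ", nrow(object@table), " variants, reference ",
        object@reference, "\n", sep = "")
    cat(sprintf("  k_rel range (unflagged): %.4g .. %.4g\n",
                min(k[ok]), max(k[ok])))
    nf <- table(object@table$flag)
    cat("  flags:", paste(names(nf), nf, sep = "=", collapse = ", "), "\n")
})

#' @describeIn SpecificityModel-class 4 x 6 matrix of position coefficients.
#' @export
setMethod("mainEffects", "SpecificityModel", function(object)
    object@mainEffects)

#' @describeIn SpecificityModel-class data.frame of admitted interaction
#'   terms.
#' @export
setMethod("interactionTerms", "SpecificityModel", function(object)
    object@interactions)

setMethod("show", "SpecificityModel", function(object) {
    cat("SpecificityModel: ln(k_rel) ~ PWM main effects",
        "+ pairwise interactions\n")
    cat(sprintf("  intercept %.4f, R^2 %.4f, n = %d\n",
                object@intercept, object@r2, object@nobs))
    cat("  main effects (sum-to-zero per position):\n")
    print(round(object@mainEffects, 3))
    if (nrow(object@interactions)) {
        cat("  interactions (|T| > 3.5 at admission):\n")
        print(object@interactions[, c("pos1", "pos2", "base1", "base2",
                                      "alpha", "tvalue", "round")],
              row.names = FALSE)
    } else cat("  no interaction terms admitted\n")
})

setMethod("show", "DepletionState", function(object) {
    cat(sprintf(
        "DepletionState: exposure c = %.6g, fraction reacted f = %.4f\n",
        object@exposure, object@totalReacted))
})

setMethod("show", "LogoMatrix", function(object) {
    cat("LogoMatrix over positions -6..-1 (", object@n, " sequences)\n",
        sep = "")
    m <- rbind(round(object@freq, 3), bits = round(object@bits, 3))
    print(m)
})

setMethod("show", "DuplexResult", function(object) {
    cat(sprintf("DuplexResult: leader %s vs tail %s -> %d pair(s)\n",
                object@leader, object@tail, object@nPairs))
    if (nrow(object@trace)) print(object@trace, row.names = FALSE)
})

#' @describeIn AssayFit-class fitted parameter estimates.
#' @param object an `AssayFit`.
#' @param ... ignored.
#' @export
setMethod("coef", "AssayFit", function(object, ...) object@coef)

#' Standard errors of an assay fit
#'
#' @param object an [AssayFit-class].
#' @param ... ignored.
#' @export
fitSE <- function(object, ...) object@se

#' @describeIn AssayFit-class residuals of the fit.
#' @export
setMethod("residuals", "AssayFit", function(object, ...) object@residuals)

setMethod("show", "AssayFit", function(object) {
    cat("AssayFit [", object@assay, "]\n", sep = "")
    tab <- data.frame(estimate = object@coef, se = object@se)
    print(signif(tab, 4))
    if (!is.null(object@info$flags) && length(object@info$flags))
        cat("  flags:", paste(object@info$flags, collapse = "; "), "\n")
})
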