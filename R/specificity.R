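#' All candidate pairwise interaction terms
#'
#' One row per (position pair, base pair) indicator: C(6,2) * 4 * 4 = 240
#' candidates. An interaction column is the product of two single-position
#' base indicators at distinct positions.
#'
#' @return data.frame with columns `pos1`, `pos2` (negative labels,
#'   pos1 < pos2), `base1`, `base2`.
#' @export
allInteractionCandidates <- function() {
    pairs <- utils::combn(.LEADER_POSITIONS, 2)
    out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        expand.grid(pos1 = pairs[1, j], pos2 = pairs[2, j],
                    base1 = .BASES, base2 = .BASES,
                    stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

.posToChar <- function(pos) pos + .LEADER_WIDTH + 1L  # -6 -> 1, -1 -> 6

.baseAt <- function(variants, pos) substr(variants, .posToChar(pos),
                                          .posToChar(pos))

.interactionName <- function(ia) {
    paste0(ia$base1, "(", ia$pos1, "):", ia$base2, "(", ia$pos2, ")")
}

.interactionColumns <- function(variants, ia) {
    if (is.null(ia) || nrow(ia) == 0)
        return(matrix(0, length(variants), 0))
    Z <- vapply(seq_len(nrow(ia)), function(r) {
        as.numeric(.baseAt(variants, ia$pos1[r]) == ia$base1[r] &
                   .baseAt(variants, ia$pos2[r]) == ia$base2[r])
    }, numeric(length(variants)))
    colnames(Z) <- .interactionName(ia)
    Z
}

#' One-hot design matrix for leader hexamers
#'
#' Full indicator coding: 24 main-effect columns (4 bases x 6 positions;
#' every row sums to 6, one indicator per position) plus, optionally,
#' pairwise interaction columns.
#'
#' @param variants character vector of hexamers.
#' @param interactions `NULL`, `"all"` (all 240 candidates), or a data.frame
#'   as returned by [allInteractionCandidates()].
#' @return numeric indicator matrix.
#' @export
leaderDesignMatrix <- function(variants, interactions = NULL) {
    variants <- normalizeLeader(variants)
    main <- do.call(cbind, lapply(.LEADER_POSITIONS, function(p) {
        b <- .baseAt(variants, p)
        m <- vapply(.BASES, function(bb) as.numeric(b == bb),
                    numeric(length(variants)))
        colnames(m) <- paste0(.BASES, "(", p, ")")
        m
    }))
    if (identical(interactions, "all")) interactions <- allInteractionCandidates()
    cbind(main, .interactionColumns(variants, interactions))
}

## Sum-to-zero (identifiable) parameterization: intercept + 3 columns per
## position; the U coefficient is minus the sum of A, C, G.
.sumToZeroDesign <- function(variants) {
    cols <- lapply(.LEADER_POSITIONS, function(p) {
        b <- .baseAt(variants, p)
        m <- vapply(.BASES[1:3], function(bb)
            as.numeric(b == bb) - as.numeric(b == "U"),
            numeric(length(variants)))
        colnames(m) <- paste0(.BASES[1:3], "(", p, ")")
        m
    })
    X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
    X
}

## Core least-squares fit of ln(k_rel) on the constrained main-effect design
## plus a set of interaction indicator columns. Returns a SpecificityModel.
.fitSpecificity <- function(y, variants, ia = NULL, weights = NULL,
                            history = list()) {
    Xm <- .sumToZeroDesign(variants)
    Z <- .interactionColumns(variants, ia)
    X <- cbind(Xm, Z)
    if (!is.null(weights)) {
        sw <- sqrt(weights)
        fit <- stats::lm.fit(X * sw, y * sw)
    } else fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    if (any(is.na(beta[colnames(Xm)])))
        stop("rank-deficient main-effect design after constraints")
    aliased <- names(beta)[is.na(beta)]
    keep <- !is.na(beta)
    Xk <- X[, keep, drop = FALSE]
    p <- ncol(Xk)
    n <- length(y)
    dfres <- n - p
    res <- fit$residuals
    rss <- sum(res^2)
    sigma2 <- rss / dfres
    Xw <- if (is.null(weights)) Xk else Xk * sqrt(weights)
    XtXinv <- solve(crossprod(Xw))
    dimnames(XtXinv) <- list(colnames(Xk), colnames(Xk))
    se <- sqrt(sigma2 * diag(XtXinv))
    tval <- beta[keep] / se

    ## reconstruct the full 4 x 6 coefficient matrix under sum-to-zero
    me <- matrix(0, 4, 6, dimnames = list(.BASES, as.character(.LEADER_POSITIONS)))
    meSE <- me
    for (p_ in .LEADER_POSITIONS) {
        nm <- paste0(.BASES[1:3], "(", p_, ")")
        b3 <- beta[nm]
        me[, as.character(p_)] <- c(b3, -sum(b3))
        V <- XtXinv[nm, nm]
        meSE[, as.character(p_)] <-
            sqrt(sigma2 * c(diag(V), sum(V)))
    }
    iaOut <- if (is.null(ia) || nrow(ia) == 0) {
        data.frame(pos1 = integer(), pos2 = integer(), base1 = character(),
                   base2 = character(), alpha = numeric(), se = numeric(),
                   tvalue = numeric(), tAdmission = numeric(),
                   round = integer(), stringsAsFactors = FALSE)
    } else {
        nm <- .interactionName(ia)
        present <- nm %in% names(beta)[keep]
        data.frame(pos1 = ia$pos1, pos2 = ia$pos2, base1 = ia$base1,
                   base2 = ia$base2,
                   alpha = ifelse(present, beta[nm], NA_real_),
                   se = ifelse(present, se[nm], NA_real_),
                   tvalue = ifelse(present, tval[nm], NA_real_),
                   tAdmission = if (!is.null(ia$tAdmission)) ia$tAdmission
                                else NA_real_,
                   round = if (!is.null(ia$round)) ia$round else NA_integer_,
                   stringsAsFactors = FALSE)
    }
    tss <- sum((y - mean(y))^2)
    new("SpecificityModel",
        intercept = unname(beta["(Intercept)"]),
        mainEffects = me, mainSE = meSE, interactions = iaOut,
        r2 = if (tss > 0) 1 - rss / tss else 1,
        sigma = sqrt(sigma2), nobs = as.integer(n),
        df.residual = as.integer(dfres),
        history = c(history, if (length(aliased))
            list(aliased = aliased) else NULL))
}

.responseFromRates <- function(object, variants) {
    if (is(object, "RelRateTable")) {
        tab <- object@table
        ok <- tab$flag == "ok" & is.finite(tab$krel) & tab$krel > 0
        list(y = log(tab$krel[ok]), variants = tab$variant[ok],
             se = tab$se[ok], nExcluded = sum(!ok))
    } else {
        y <- as.numeric(object)
        if (is.null(variants)) variants <- names(object)
        keep <- is.finite(y)
        list(y = y[keep], variants = normalizeLeader(variants[keep]),
             se = NULL, nExcluded = sum(!keep))
    }
}

#' Fit the position weight matrix (main effects) model
#'
#' Least squares of ln(k_rel) on per-position base indicators under a
#' sum-to-zero constraint within each position, so coefficients read as
#' enrichment relative to the position average. Censored/flagged variants
#' are excluded (count recorded in `history`).
#'
#' @param object a [RelRateTable-class], or a numeric vector of ln(k_rel)
#'   named by (or aligned with) `variants`.
#' @param variants hexamers when `object` is numeric.
#' @param weighted logical; if `TRUE` and SEs are available, weight by
#'   1/se^2 (default unweighted).
#' @return a [SpecificityModel-class] with no interaction terms.
#' @export
fitPWM <- function(object, variants = NULL, weighted = FALSE) {
    d <- .responseFromRates(object, variants)
    w <- if (weighted && !is.null(d$se)) 1 / d$se^2 else NULL
    .fitSpecificity(d$y, d$variants, weights = w,
                    history = list(nExcluded = d$nExcluded))
}

## Exact single-column-addition t statistics for all candidates at once,
## via residual projection: for candidate z with z_perp = z - Q Q'z,
## beta = z_perp'y / |z_perp|^2 and t = beta / sqrt(s^2 / |z_perp|^2) with
## s^2 the residual variance of the augmented model. Identical to the
## t-test of the candidate's coefficient in a full refit.
.screenCandidates <- function(X, y, Z) {
    qrx <- qr(X)
    Q <- qr.Q(qrx)
    r <- y - Q %*% crossprod(Q, y)
    rss <- sum(r^2)
    Zp <- Z - Q %*% crossprod(Q, Z)
    d <- colSums(Zp^2)
    g <- colSums(Zp * as.vector(r))
    n <- length(y)
    p <- qrx$rank
    t <- rep(NA_real_, ncol(Z))
    okc <- d > 1e-8
    beta <- g[okc] / d[okc]
    rssNew <- pmax(rss - g[okc]^2 / d[okc], 0)
    s2 <- rssNew / (n - p - 1)
    t[okc] <- beta / sqrt(s2 / d[okc])
    t
}

#' Iterative selection of pairwise interaction terms
#'
#' Starting from a main-effects fit, each round computes the coefficient
#' t-statistic of every not-yet-included candidate interaction when added
#' singly to the current model (an exact screen via residual projection).
#' Candidates with |T| strictly greater than `tThreshold` are admitted
#' within the round in decreasing |T| order, each re-verified against the
#' model grown so far: the 16 base-pair indicators of a position pair are
#' mutually redundant (they sum to a main-effect column), so admitting all
#' screen-passers simultaneously would bring in whole blocks of aliased
#' terms and destroy the sparse representation. Rounds repeat until a
#' screen admits none; terms whose joint-refit |T| then falls to or below
#' the threshold are pruned (worst first). The final joint refit supplies
#' the reported coefficients and T-values; the admission T is kept
#' alongside.
#'
#' @inheritParams fitPWM
#' @param model optional starting [SpecificityModel-class] (fitted main
#'   effects); fitted from `object` when `NULL`.
#' @param tThreshold admission threshold on |T| (default 3.5, strictly
#'   greater).
#' @param maxRounds error if selection has not converged after this many
#'   rounds (default 20).
#' @param candidates candidate universe (default all 240 pairwise terms).
#' @return a [SpecificityModel-class] with admitted interactions and a
#'   per-round `history`.
#' @export
selectInteractions <- function(object, variants = NULL, model = NULL,
                               tThreshold = 3.5, maxRounds = 20L,
                               weighted = FALSE,
                               candidates = allInteractionCandidates()) {
    d <- .responseFromRates(object, variants)
    y <- d$y
    v <- d$variants
    w <- if (weighted && !is.null(d$se)) 1 / d$se^2 else NULL
    if (!is.null(w)) {
        y <- y * sqrt(w)
        scaleX <- sqrt(w)
    } else scaleX <- 1
    cand <- candidates
    cand$name <- .interactionName(cand)
    cand$tAdmission <- NA_real_
    cand$round <- NA_integer_
    Zall <- .interactionColumns(v, cand)
    Xm <- .sumToZeroDesign(v) * scaleX
    Zall <- Zall * scaleX

    selected <- integer(0)
    history <- list()
    round <- 0L
    repeat {
        round <- round + 1L
        if (round > maxRounds)
            stop("interaction selection did not converge within ",
                 maxRounds, " rounds; admitted so far: ",
                 paste(cand$name[selected], collapse = ", "))
        X <- cbind(Xm, Zall[, selected, drop = FALSE])
        remaining <- setdiff(seq_len(nrow(cand)), selected)
        t <- .screenCandidates(X, y, Zall[, remaining, drop = FALSE])
        pass <- remaining[which(!is.na(t) & abs(t) > tThreshold)]
        pass <- pass[order(-abs(t[match(pass, remaining)]))]
        admitted <- integer(0)
        for (cnd in pass) {
            tv <- .screenCandidates(X, y, Zall[, cnd, drop = FALSE])
            if (is.na(tv) || abs(tv) <= tThreshold) next
            admitted <- c(admitted, cnd)
            cand$tAdmission[cnd] <- tv
            cand$round[cnd] <- round
            X <- cbind(X, Zall[, cnd, drop = FALSE])
        }
        history[[round]] <- data.frame(
            round = rep(round, length(admitted)),
            term = cand$name[admitted],
            tAdmission = cand$tAdmission[admitted],
            stringsAsFactors = FALSE)
        if (!length(admitted)) break
        selected <- c(selected, admitted)
    }
    ## backward pruning: terms that no longer reject the null in the joint
    ## refit are removed, worst first
    repeat {
        ia <- cand[selected, c("pos1", "pos2", "base1", "base2",
                               "tAdmission", "round")]
        fit <- .fitSpecificity(d$y, v, ia = ia, weights = w,
                               history = list(nExcluded = d$nExcluded,
                                              rounds = history))
        tj <- abs(fit@interactions$tvalue)
        weak <- which(is.na(tj) | tj <= tThreshold)
        if (!length(weak) || !length(selected)) break
        drop1 <- weak[which.min(tj[weak])]
        if (is.na(tj[drop1])) drop1 <- weak[1]
        history[[length(history) + 1L]] <- data.frame(
            round = NA_integer_, term = cand$name[selected[drop1]],
            tAdmission = NA_real_, stringsAsFactors = FALSE)
        selected <- selected[-drop1]
    }
    fit
}

#' Predict ln(k_rel) from a specificity model
#'
#' Evaluates the linear predictor (intercept + per-position coefficients +
#' admitted interaction terms) for each supplied hexamer.
#'
#' @param object a [SpecificityModel-class].
#' @param variants character vector of hexamers (default: the whole pool).
#' @param ... ignored.
#' @return numeric vector of ln(k_rel), named by hexamer.
#' @export
setMethod("predict", "SpecificityModel", function(object,
                                                  variants = enumerateLeaders(),
                                                  ...) {
    variants <- normalizeLeader(variants)
    chars <- matrix(match(unlist(strsplit(variants, "")), .BASES),
                    nrow = .LEADER_WIDTH)
    lp <- object@intercept +
        colSums(matrix(object@mainEffects[cbind(as.vector(chars),
                                                rep(1:6, ncol(chars)))],
                       nrow = .LEADER_WIDTH))
    ia <- object@interactions
    for (r in seq_len(nrow(ia))) {
        hit <- .baseAt(variants, ia$pos1[r]) == ia$base1[r] &
               .baseAt(variants, ia$pos2[r]) == ia$base2[r]
        lp <- lp + ia$alpha[r] * hit
    }
    setNames(lp, variants)
})

#' Nucleotide frequency and information content of a sequence subset
#'
#' Per-position base frequencies of a set of hexamers and their information
#' content `IC = 2 + sum p log2 p` bits against a uniform background: 2
#' bits for an invariant position, ~0 for a uniform one.
#'
#' @param seqs non-empty character vector of hexamers.
#' @return a [LogoMatrix-class].
#' @export
logoMatrix <- function(seqs) {
    seqs <- normalizeLeader(seqs)
    if (!length(seqs)) stop("empty sequence subset")
    if (!all(grepl("^[ACGU]{6}$", seqs)))
        stop("sequences must be hexamers over {A,C,G,U}")
    freq <- vapply(1:6, function(p) {
        tab <- table(factor(substr(seqs, p, p), levels = .BASES))
        as.numeric(tab) / length(seqs)
    }, numeric(4))
    dimnames(freq) <- list(.BASES, as.character(.LEADER_POSITIONS))
    plogp <- ifelse(freq > 0, freq * log2(freq), 0)
    bits <- pmin(pmax(2 + colSums(plogp), 0), 2)
    new("LogoMatrix", freq = freq, bits = unname(bits),
        n = length(seqs))
}

#' Serialize a specificity model to YAML
#'
#' @param model a [SpecificityModel-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSpecificityModel <- function(model, file) {
    obj <- list(
        intercept = model@intercept,
        mainEffects = as.list(as.data.frame(model@mainEffects)),
        interactions = if (nrow(model@interactions))
            lapply(seq_len(nrow(model@interactions)), function(i)
                as.list(model@interactions[i, ])) else list(),
        r2 = model@r2, sigma = model@sigma, nobs = model@nobs)
    yaml::write_yaml(obj, file)
    invisible(file)
}
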