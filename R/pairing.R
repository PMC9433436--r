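.canPair <- function(a, b) {
    (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' Maximum base-pairing between a 5' leader window and the 3' RCCA tail
#'
#' Computes the maximum number of antiparallel, non-crossing base pairs
#' between a leader window and the single-stranded 3' tail of the tRNA
#' (default ACCA, i.e. R = A), allowing Watson-Crick (A:U, G:C) and G:U
#' wobble pairs with unpaired bulges permitted on either strand. This is a
#' register-free measure of the pairing potential that extends the acceptor
#' stem and acts as an anti-determinant of cleavage; ties are resolved
#' toward the pairing closest to the cleavage site (the leader 3' end).
#'
#' Implemented as an alignment-style dynamic program on the leader (5'->3')
#' against the reversed tail; equivalent to exhaustive enumeration of all
#' monotone pairings.
#'
#' @param leader leader window, 5'->3' (e.g. `"GG"` for G(-2)G(-1)); may be
#'   empty.
#' @param tail tail sequence 5'->3' (default `"ACCA"`).
#' @return a [DuplexResult-class].
#' @examples
#' maxDuplexPairs("GG")   # 2 pairs with the two C's of ACCA
#' @export
maxDuplexPairs <- function(leader, tail = .DEFAULT_TAIL) {
    leader <- normalizeLeader(leader)
    tail <- normalizeLeader(tail)
    if (!grepl("^[ACGU]*$", leader) || !grepl("^[ACGU]*$", tail))
        stop("sequences must be over {A,C,G,U}")
    L <- strsplit(leader, "")[[1]]
    Trev <- rev(strsplit(tail, "")[[1]])  # antiparallel register
    n <- length(L)
    m <- length(Trev)
    D <- matrix(0L, n + 1L, m + 1L)
    for (i in seq_len(n)) for (j in seq_len(m)) {
        best <- max(D[i, j + 1L], D[i + 1L, j])
        if (.canPair(L[i], Trev[j]))
            best <- max(best, D[i, j] + 1L)
        D[i + 1L, j + 1L] <- best
    }
    ## traceback from the 3' end of the leader, preferring pairs there
    i <- n; j <- m
    lp <- integer(0); tp <- integer(0)
    while (i > 0L && j > 0L) {
        if (.canPair(L[i], Trev[j]) && D[i + 1L, j + 1L] == D[i, j] + 1L) {
            lp <- c(i, lp); tp <- c(j, tp)
            i <- i - 1L; j <- j - 1L
        } else if (D[i + 1L, j + 1L] == D[i, j + 1L]) {
            i <- i - 1L
        } else {
            j <- j - 1L
        }
    }
    tailPos <- length(Trev) - tp + 1L  # back to 5'->3' tail coordinates
    type <- ifelse((L[lp] == "G" & Trev[tp] == "U") |
                   (L[lp] == "U" & Trev[tp] == "G"), "wobble", "WC")
    o <- order(lp)
    new("DuplexResult", leader = leader, tail = tail,
        nPairs = D[n + 1L, m + 1L],
        trace = data.frame(leaderPos = lp[o], tailPos = tailPos[o],
                           type = type[o], stringsAsFactors = FALSE))
}

#' Classify leader variants as 3'-RCCA pairing anti-determinants
#'
#' A variant is an anti-determinant when the leader window closest to the
#' cleavage site (default the N(-2)N(-1) dinucleotide) can form at least
#' `threshold` base pairs with the 3' tail; two pairs is the threshold at
#' which kcat/Km drops.
#'
#' @param variant character vector of hexamers (or shorter windows; the
#'   last `window` nucleotides are used).
#' @param threshold minimum pair count (default 2).
#' @param window leader window width, counted from the cleavage site
#'   (default 2, configurable up to 4).
#' @param tail 3' tail, 5'->3'.
#' @return named logical vector; attribute `"nPairs"` carries the pair
#'   counts.
#' @export
isAntideterminant <- function(variant, threshold = 2L, window = 2L,
                              tail = .DEFAULT_TAIL) {
    variant <- normalizeLeader(variant)
    win <- substr(variant, pmax(nchar(variant) - window + 1L, 1L),
                  nchar(variant))
    np <- vapply(win, function(w) maxDuplexPairs(w, tail)@nPairs,
                 integer(1), USE.NAMES = FALSE)
    structure(setNames(np >= threshold, variant), nPairs = np)
}

#' Paired comparison of k_rel across a single-position substitution
#'
#' For every sequence background compatible with `fixed`, pairs the k_rel
#' of the variant carrying `from` at `position` with the one carrying `to`
#' (e.g. the effect of an A(-2) to G(-2) change in every background with an
#' optimal C(-4)), stratified by the identity of `stratifyBy` (default
#' N(-1)). Backgrounds with a flagged/missing member are kept with `NA`.
#'
#' @param rrt a [RelRateTable-class].
#' @param position leader position that is substituted (negative label).
#' @param from,to bases compared at `position`.
#' @param fixed named character vector of constraints, names are positions
#'   (e.g. `c("-4" = "C")`).
#' @param stratifyBy position whose identity defines the strata.
#' @return data.frame with one row per background: `background` (hexamer
#'   with `position` shown as `.`), `stratum`, `krelFrom`, `krelTo`,
#'   `fold` (= to/from). Attribute `"strata"` summarizes each stratum
#'   (n, median fold, flagged count).
#' @export
compareSubsets <- function(rrt, position = -2L, from = "A", to = "G",
                           fixed = c("-4" = "C"), stratifyBy = -1L) {
    stopifnot(is(rrt, "RelRateTable"))
    k <- krel(rrt)
    k[rrt@table$flag != "ok"] <- NA
    leaders <- names(k)
    keep <- rep(TRUE, length(leaders))
    for (pn in names(fixed))
        keep <- keep & .baseAt(leaders, as.integer(pn)) == fixed[[pn]]
    sel <- leaders[keep & .baseAt(leaders, position) == from]
    toSeq <- sel
    substr(toSeq, .posToChar(position), .posToChar(position)) <- to
    bg <- sel
    substr(bg, .posToChar(position), .posToChar(position)) <- "."
    d <- data.frame(background = bg,
                    stratum = .baseAt(sel, stratifyBy),
                    krelFrom = unname(k[sel]),
                    krelTo = unname(k[toSeq]),
                    stringsAsFactors = FALSE)
    d$fold <- d$krelTo / d$krelFrom
    strat <- do.call(rbind, lapply(split(d, d$stratum), function(s)
        data.frame(stratum = s$stratum[1], n = nrow(s),
                   medianFold = median(s$fold, na.rm = TRUE),
                   flagged = sum(!is.finite(s$fold)))))
    rownames(strat) <- NULL
    attr(d, "strata") <- strat
    d
}

#' Census of cleavage-site dinucleotides in genomic leader sequences
#'
#' Tabulates the N(-2)N(-1) dinucleotide (the last two nucleotides of each
#' supplied 5' leader) across a set of endogenous leader sequences and
#' classifies each class by its 3'-tail pairing potential. Sequences
#' shorter than the window are skipped with a warning.
#'
#' @param seqs character vector of leader sequences, 5'->3' (the cleavage
#'   site is the right end).
#' @param window,threshold,tail see [isAntideterminant()].
#' @return data.frame with `dinucleotide` (5'->3', i.e. N(-2)N(-1)),
#'   `labelN1N2` (the same class labeled cleavage-site-first), `count`,
#'   `nPairs`, `antideterminant`; classes partition the usable input.
#' @export
censusDinucleotides <- function(seqs, window = 2L, threshold = 2L,
                                tail = .DEFAULT_TAIL) {
    seqs <- normalizeLeader(seqs)
    short <- nchar(seqs) < window
    if (any(short)) {
        warning(sum(short), " sequence(s) shorter than the window skipped")
        seqs <- seqs[!short]
    }
    din <- substr(seqs, nchar(seqs) - window + 1L, nchar(seqs))
    lv <- do.call(paste0, expand.grid(.BASES, .BASES)[, c(2, 1)])
    tab <- table(factor(din, levels = lv))
    np <- vapply(lv, function(w) maxDuplexPairs(w, tail)@nPairs, integer(1))
    out <- data.frame(
        dinucleotide = lv,
        labelN1N2 = vapply(strsplit(lv, ""), function(x)
            paste(rev(x), collapse = ""), character(1)),
        count = as.integer(tab),
        nPairs = unname(np),
        antideterminant = unname(np >= threshold),
        stringsAsFactors = FALSE)
    out[order(-out$count), ]
}
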