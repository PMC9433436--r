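# Independent oracles and fixture builders used across the suite.

# Assemble a SpecificityModel directly from known coefficients (ground
# truth for simulation / recovery tests).
makeSpecModel <- function(mainEffects, interactions = NULL, intercept = 0) {
    if (is.null(interactions))
        interactions <- data.frame(pos1 = integer(), pos2 = integer(),
                                   base1 = character(), base2 = character(),
                                   alpha = numeric())
    n <- nrow(interactions)
    ia <- data.frame(pos1 = interactions$pos1, pos2 = interactions$pos2,
                     base1 = interactions$base1, base2 = interactions$base2,
                     alpha = interactions$alpha, se = rep(NA_real_, n),
                     tvalue = rep(NA_real_, n),
                     tAdmission = rep(NA_real_, n),
                     round = rep(NA_integer_, n), stringsAsFactors = FALSE)
    new("SpecificityModel", intercept = intercept,
        mainEffects = mainEffects, mainSE = mainEffects * 0,
        interactions = ia, r2 = NA_real_, sigma = NA_real_, nobs = 0L,
        df.residual = 0L, history = list())
}

randomMainEffects <- function(sd = 0.3) {
    me <- matrix(rnorm(24, 0, sd), 4, 6,
                 dimnames = list(c("A", "C", "G", "U"),
                                 as.character(-6:-1)))
    sweep(me, 2, colMeans(me))  # sum-to-zero per position
}

# Exhaustive enumeration of all monotone (non-crossing, antiparallel)
# pairings between a leader window and a tail; the independent oracle for
# the duplex dynamic program.
bruteMaxPairs <- function(leader, tail) {
    L <- strsplit(leader, "")[[1]]
    Tr <- rev(strsplit(tail, "")[[1]])
    cp <- function(a, b)
        paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
    rec <- function(i, j) {
        if (i > length(L) || j > length(Tr)) return(0L)
        best <- max(rec(i + 1L, j), rec(i, j + 1L))
        if (cp(L[i], Tr[j])) best <- max(best, 1L + rec(i + 1L, j + 1L))
        best
    }
    rec(1L, 1L)
}

allWindows <- function(width) {
    apply(do.call(expand.grid,
                  replicate(width, c("A", "C", "G", "U"),
                            simplify = FALSE)),
          1, paste0, collapse = "")
}
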