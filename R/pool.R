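#' Enumerate the randomized leader pool
#'
#' All 4^6 = 4096 hexamers over {A, C, G, U} covering the randomized leader
#' positions N(-6) to N(-1), in deterministic lexicographic order (AAAAAA
#' first). The string is written 5'->3', so character 1 is N(-6) and
#' character 6 is N(-1), the nucleotide adjacent to the cleavage site.
#'
#' @return character vector of length 4096.
#' @examples
#' leaders <- enumerateLeaders()
#' length(leaders)       # 4096
#' leaders[1]            # "AAAAAA"
#' @export
enumerateLeaders <- function() {
    g <- expand.grid(rev(replicate(.LEADER_WIDTH, .BASES, simplify = FALSE)),
                     stringsAsFactors = FALSE)
    do.call(paste0, rev(g))
}

#' Map leader hexamers to pool indices and back
#'
#' The bijection between a hexamer and its 1-based position in the
#' lexicographic enumeration of [enumerateLeaders()].
#'
#' @param x character vector of hexamers (T is normalized to U,
#'   case-insensitive).
#' @return `leaderIndex`: integer vector in 1..4096; `leaderFromIndex`: the
#'   hexamers at the given indices.
#' @examples
#' leaderIndex("AAAAAA")           # 1
#' leaderFromIndex(4096)           # "UUUUUU"
#' @export
leaderIndex <- function(x) {
    x <- normalizeLeader(x)
    bad <- !grepl("^[ACGU]{6}$", x)
    if (any(bad))
        stop("invalid leader hexamer(s): ",
             paste(unique(x[bad])[seq_len(min(3, sum(bad)))], collapse = ", "))
    m <- matrix(match(unlist(strsplit(x, "")), .BASES) - 1L,
                nrow = .LEADER_WIDTH)
    as.integer(colSums(m * 4L^((.LEADER_WIDTH - 1L):0L))) + 1L
}

#' @rdname leaderIndex
#' @param i integer indices in 1..4096.
#' @export
leaderFromIndex <- function(i) {
    i <- as.integer(i)
    if (any(is.na(i)) || any(i < 1L) || any(i > 4096L))
        stop("indices must lie in 1..4096")
    v <- i - 1L
    out <- matrix("", nrow = .LEADER_WIDTH, ncol = length(i))
    for (p in .LEADER_WIDTH:1) {
        out[p, ] <- .BASES[v %% 4L + 1L]
        v <- v %/% 4L
    }
    apply(out, 2, paste0, collapse = "")
}

#' Normalize leader sequences to the internal RNA alphabet
#'
#' Uppercases and converts T to U. No other editing is performed.
#'
#' @param x character vector.
#' @return character vector over the {A,C,G,U} alphabet (where valid).
#' @export
normalizeLeader <- function(x) {
    chartr("T", "U", toupper(as.character(x)))
}

#' Leader position labels
#'
#' @return integer vector `-6:-1`; element `p` labels string character `p`.
#' @export
leaderPositions <- function() .LEADER_POSITIONS
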