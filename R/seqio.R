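## Constant regions of the randomized ptRNA-Met construct flanking the
## N(-6)..N(-1) window (DNA alphabet, as sequenced). The default extraction
## anchors are the 8 nt immediately flanking the randomized hexamer.
.FLANK5_FULL <- "CATGCACGAAAGTGCGTGCTATGAA"
.FLANK3_FULL <- "GGCTACGTAGCTCAGTTGG"
.ANCHOR5 <- "GCTATGAA"
.ANCHOR3 <- "GGCTACGT"

#' Extract the randomized leader hexamer from reads
#'
#' Locates the 5' and 3' constant flanks in each read and returns the 6-mer
#' between them, normalized to the RNA alphabet (T -> U). Matching is
#' exact-first, then Hamming-tolerant up to `maxMismatch` substitutions per
#' flank (no indels; the reads are amplicon-style). A read is a no-match
#' (`NA`) when either flank is not found within the mismatch budget, the
#' extracted region is not exactly 6 nt, or it contains a non-ACGU
#' character.
#'
#' @param reads character vector or `Biostrings::DNAStringSet` of read
#'   sequences.
#' @param anchor5,anchor3 constant-flank anchors immediately 5' and 3' of
#'   the randomized window (DNA or RNA alphabet; default the 8-mers of the
#'   ptRNA-Met construct).
#' @param maxMismatch substitutions tolerated per flank (default 1).
#' @return character vector of hexamers with `NA` at no-match positions;
#'   attribute `"rejected"` counts the no-matches.
#' @export
extractLeader <- function(reads, anchor5 = .ANCHOR5, anchor3 = .ANCHOR3,
                          maxMismatch = 1L) {
    reads <- toupper(as.character(reads))
    reads <- chartr("U", "T", reads)
    anchor5 <- chartr("U", "T", toupper(anchor5))
    anchor3 <- chartr("U", "T", toupper(anchor3))
    out <- rep(NA_character_, length(reads))

    ## exact pass: flanks adjacent to a 6-nt window
    pat <- paste0(anchor5, "([ACGTN]{6})", anchor3)
    m <- regexpr(pat, reads)
    hit <- m > 0
    if (any(hit)) {
        s <- substr(reads[hit], m[hit] + nchar(anchor5),
                    m[hit] + nchar(anchor5) + 5L)
        out[hit] <- s
    }

    ## mismatch-tolerant pass on the remainder
    todo <- which(!hit & nzchar(reads))
    if (length(todo) && maxMismatch > 0) {
        dss <- Biostrings::DNAStringSet(gsub("[^ACGTN]", "N", reads[todo]))
        m5 <- Biostrings::vmatchPattern(anchor5, dss,
                                        max.mismatch = maxMismatch)
        m3 <- Biostrings::vmatchPattern(anchor3, dss,
                                        max.mismatch = maxMismatch)
        for (j in seq_along(todo)) {
            e5 <- BiocGenerics::end(m5[[j]])
            s3 <- BiocGenerics::start(m3[[j]])
            if (!length(e5) || !length(s3)) next
            e5 <- e5[1L]
            s3 <- s3[s3 > e5]
            if (!length(s3)) next
            if (s3[1L] - e5 - 1L != 6L) next
            out[todo[j]] <- substr(reads[todo[j]], e5 + 1L, e5 + 6L)
        }
    }
    out <- normalizeLeader(out)
    out[!is.na(out) & !grepl("^[ACGU]{6}$", out)] <- NA_character_
    structure(out, rejected = sum(is.na(out)))
}

#' Count extracted leader variants into the dense 4096-row table
#'
#' Tabulates hexamers (or raw reads, which are first passed through
#' [extractLeader()]) per sample into a dense variant-by-sample count
#' matrix; all 4096 rows are always present with zeros kept, so any
#' downstream pseudocount policy is explicit.
#'
#' @param samples named list, one element per sample: either a character
#'   vector of reads/hexamers or a FASTQ file path.
#' @param f per-sample total fraction reacted (0 marks the start sample).
#' @param replicate per-sample replicate id.
#' @param extract logical; `TRUE` (default) runs [extractLeader()] on each
#'   element, `FALSE` treats elements as already-extracted hexamers.
#' @param ... passed to [extractLeader()].
#' @return a [PoolCounts-class]; `metadata(x)$rejected` tallies no-match
#'   reads per sample.
#' @export
countReads <- function(samples, f, replicate = 1L, extract = TRUE, ...) {
    if (is.null(names(samples)))
        names(samples) <- paste0("sample", seq_along(samples))
    leaders <- enumerateLeaders()
    counts <- matrix(0, nrow = 4096L, ncol = length(samples),
                     dimnames = list(leaders, names(samples)))
    rejected <- integer(length(samples))
    for (j in seq_along(samples)) {
        x <- samples[[j]]
        if (is.character(x) && length(x) == 1L && file.exists(x))
            x <- readFastqReads(x)
        hex <- if (extract) extractLeader(x, ...) else normalizeLeader(x)
        ok <- !is.na(hex) & grepl("^[ACGU]{6}$", hex)
        rejected[j] <- sum(!ok)
        if (!any(ok))
            stop("sample '", names(samples)[j], "' has zero accepted reads")
        tab <- table(factor(hex[ok], levels = leaders))
        counts[, j] <- as.integer(tab)
    }
    pc <- poolCounts(counts, f = f, replicate = replicate)
    metadata(pc)$rejected <- setNames(rejected, names(samples))
    pc
}

#' Read sequences from a FASTQ file
#'
#' @param file FASTQ path (gzip-transparent).
#' @return character vector of read sequences.
#' @export
readFastqReads <- function(file) {
    as.character(Biostrings::readDNAStringSet(file, format = "fastq"))
}

#' Write a simulated pool sample as FASTQ
#'
#' Each variant contributes `counts[i]` reads of the form
#' `5' constant + hexamer + 3' constant` (DNA alphabet) with uniform
#' Phred-40 qualities, exercising the extraction path end to end.
#'
#' @param counts named count vector (names are hexamers) or a
#'   [PoolCounts-class] column index together with `pc`.
#' @param file output FASTQ path (`.gz` supported).
#' @param flank5,flank3 constant regions around the randomized window.
#' @return `file`, invisibly.
#' @export
writePoolFastq <- function(counts, file, flank5 = .FLANK5_FULL,
                           flank3 = .FLANK3_FULL) {
    counts <- round(counts)
    counts <- counts[counts > 0]
    hex <- chartr("U", "T", names(counts))
    reads <- rep(paste0(flank5, hex, flank3), counts)
    dss <- Biostrings::DNAStringSet(reads)
    names(dss) <- paste0("read", seq_along(dss))
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(dss)))
    Biostrings::writeXStringSet(dss, file, format = "fastq",
                                compress = grepl("\\.gz$", file),
                                qualities = quals)
    invisible(file)
}

#' Read and write tidy pool count tables
#'
#' CSV layout: one row per (variant, sample) with columns `variant`,
#' `replicate`, `f`, `count`.
#'
#' @param pc a [PoolCounts-class].
#' @param file CSV path.
#' @return `writePoolCounts`: `file` invisibly; `readPoolCounts`: a
#'   `PoolCounts`.
#' @export
writePoolCounts <- function(pc, file) {
    stopifnot(is(pc, "PoolCounts"))
    cts <- assay(pc, "counts")
    cd <- colData(pc)
    d <- data.frame(
        variant = rep(rownames(cts), times = ncol(cts)),
        replicate = rep(cd$replicate, each = nrow(cts)),
        f = rep(cd$f, each = nrow(cts)),
        count = as.vector(cts))
    utils::write.csv(d, file, row.names = FALSE)
    invisible(file)
}

#' @rdname writePoolCounts
#' @export
readPoolCounts <- function(file) {
    d <- utils::read.csv(file, stringsAsFactors = FALSE)
    need <- c("variant", "replicate", "f", "count")
    if (!all(need %in% colnames(d)))
        stop("count CSV needs columns: ", paste(need, collapse = ", "))
    d$variant <- normalizeLeader(d$variant)
    key <- paste(d$replicate, d$f, sep = "|")
    samples <- unique(key)
    leaders <- enumerateLeaders()
    counts <- matrix(0, 4096L, length(samples),
                     dimnames = list(leaders, samples))
    for (j in seq_along(samples)) {
        dj <- d[key == samples[j], ]
        counts[match(dj$variant, leaders), j] <- dj$count
    }
    meta <- d[!duplicated(key), c("replicate", "f")]
    poolCounts(counts, f = meta$f, replicate = meta$replicate)
}

#' Read leader sequences for the genomic census
#'
#' Accepts FASTA (via Biostrings) or a one-column/`sequence`-column
#' TSV/CSV. Sequences are normalized to the RNA alphabet and returned
#' 5'->3'.
#'
#' @param file path to FASTA, TSV or CSV.
#' @return named character vector of leader sequences.
#' @export
readLeaderSequences <- function(file) {
    if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", file, ignore.case = TRUE)) {
        x <- Biostrings::readBStringSet(file)
        setNames(normalizeLeader(as.character(x)), names(x))
    } else {
        d <- utils::read.delim(file, sep = "", stringsAsFactors = FALSE)
        col <- if ("sequence" %in% colnames(d)) "sequence" else colnames(d)[1]
        s <- normalizeLeader(d[[col]])
        names(s) <- if ("name" %in% colnames(d)) d$name else
            paste0("leader", seq_along(s))
        s
    }
}
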