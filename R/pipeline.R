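## Parse "--key value" pairs (with optional YAML config file merged under
## the flags) into a named list.
.parseArgs <- function(args) {
    opts <- list()
    i <- 1L
    while (i <= length(args)) {
        a <- args[i]
        if (!startsWith(a, "--"))
            stop("unexpected argument: ", a)
        key <- sub("^--", "", a)
        if (i == length(args) || startsWith(args[i + 1L], "--")) {
            opts[[key]] <- TRUE
            i <- i + 1L
        } else {
            opts[[key]] <- args[i + 1L]
            i <- i + 2L
        }
    }
    if (!is.null(opts$config)) {
        cfg <- yaml::read_yaml(opts$config)
        for (k in setdiff(names(cfg), names(opts))) opts[[k]] <- cfg[[k]]
    }
    opts
}

.opt <- function(opts, key, default = NULL, as = identity) {
    if (is.null(opts[[key]])) default else as(opts[[key]])
}

.logEvent <- function(logfile, event) {
    if (is.null(logfile)) return(invisible())
    event$time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    cat(jsonlite::toJSON(event, auto_unbox = TRUE), "\n",
        file = logfile, append = TRUE)
}

.cliSimulatePool <- function(opts) {
    seed <- .opt(opts, "seed", 1L, as.integer)
    depth <- .opt(opts, "depth", 5e6, as.numeric)
    reps <- .opt(opts, "replicates", 1L, as.integer)
    fT <- as.numeric(strsplit(.opt(opts, "f", "0.05,0.15,0.30"), ",")[[1]])
    prefix <- .opt(opts, "out-prefix", "pool")
    sdlog <- .opt(opts, "skew-sdlog", 0, as.numeric)
    w <- if (sdlog > 0) skewedPoolWeights(sdlog, seed = seed) else NULL
    truth <- assignTrueKrel(ecoliLeaderModel(), weights = w)
    pc <- simulatePool(truth, fTargets = fT, depth = depth,
                       replicates = reps, seed = seed)
    writePoolCounts(pc, paste0(prefix, "_counts.csv"))
    writeTruth(truth, paste0(prefix, "_truth.csv"),
               params = list(seed = seed, depth = depth, fTargets = fT,
                             replicates = reps, skew_sdlog = sdlog))
    .logEvent(opts$log, list(step = "simulate-pool", seed = seed,
                             depth = depth, f = fT,
                             out = paste0(prefix, "_counts.csv")))
    invisible(0L)
}

.cliKrel <- function(opts) {
    counts <- .opt(opts, "counts")
    if (is.null(counts) || !file.exists(counts))
        stop("--counts <csv> is required")
    pc <- readPoolCounts(counts)
    rrt <- relativeRates(pc,
                         reference = .opt(opts, "reference",
                                          .DEFAULT_REFERENCE),
                         pseudocount = .opt(opts, "pseudocount", 0.5,
                                            as.numeric))
    out <- .opt(opts, "out", "krel.csv")
    writeRelRates(rrt, out)
    .logEvent(opts$log, list(step = "krel", counts = counts, out = out,
                             reference = referenceVariant(rrt)))
    invisible(0L)
}

.readRatesCSV <- function(file) {
    d <- utils::read.csv(file, stringsAsFactors = FALSE)
    if (!all(c("variant", "krel") %in% colnames(d)))
        stop("rates CSV needs columns variant, krel")
    d
}

.cliFitSpecificity <- function(opts) {
    rates <- .opt(opts, "rates")
    if (is.null(rates) || !file.exists(rates))
        stop("--rates <csv> is required")
    d <- .readRatesCSV(rates)
    ok <- is.finite(d$krel) & d$krel > 0
    if (!is.null(d$flag)) ok <- ok & d$flag == "ok"
    model <- selectInteractions(log(d$krel[ok]), variants = d$variant[ok],
                                tThreshold = .opt(opts, "threshold", 3.5,
                                                  as.numeric))
    out <- .opt(opts, "out", "specificity.yml")
    writeSpecificityModel(model, out)
    .logEvent(opts$log, list(step = "fit-specificity", rates = rates,
                             out = out,
                             nInteractions = nrow(interactionTerms(model)),
                             r2 = model@r2))
    invisible(0L)
}

.cliPairing <- function(opts) {
    out <- .opt(opts, "out", "pairing_census.csv")
    leaders <- .opt(opts, "leaders")
    if (is.null(leaders) || !file.exists(leaders))
        stop("--leaders <fasta/tsv> is required")
    seqs <- readLeaderSequences(leaders)
    census <- censusDinucleotides(seqs,
                                  threshold = .opt(opts, "threshold", 2L,
                                                   as.integer),
                                  tail = .opt(opts, "tail", .DEFAULT_TAIL))
    utils::write.csv(census, out, row.names = FALSE)
    .logEvent(opts$log, list(step = "pairing", leaders = leaders,
                             out = out, n = sum(census$count)))
    invisible(0L)
}

.cliFitKinetics <- function(opts) {
    type <- .opt(opts, "type", "mm")
    file <- .opt(opts, "data")
    if (is.null(file) || !file.exists(file))
        stop("--data <csv> is required")
    d <- utils::read.csv(file, stringsAsFactors = FALSE)
    fit <- switch(type,
        mm = fitMichaelisMenten(d, E0 = .opt(opts, "E0", 1, as.numeric)),
        binding = fitBinding(d),
        dissociation = fitDissociation(d),
        stop("--type must be mm, binding or dissociation"))
    out <- .opt(opts, "out", paste0("fit_", type, ".yml"))
    yaml::write_yaml(list(assay = fit@assay,
                          coef = as.list(coef(fit)),
                          se = as.list(fitSE(fit)),
                          info = fit@info[c("flags", "model", "weighted",
                                            "E0")]),
                     out)
    .logEvent(opts$log, list(step = "fit-kinetics", type = type,
                             data = file, out = out,
                             coef = as.list(coef(fit))))
    invisible(0L)
}

.cliReport <- function(opts) {
    rates <- .opt(opts, "rates")
    if (is.null(rates) || !file.exists(rates))
        stop("--rates <csv> is required")
    prefix <- .opt(opts, "out-prefix", "report")
    d <- .readRatesCSV(rates)
    ok <- is.finite(d$krel) & d$krel > 0
    if (!is.null(d$flag)) ok <- ok & d$flag == "ok"
    k <- setNames(d$krel[ok], d$variant[ok])
    hist <- rateDistribution(k, bins = .opt(opts, "bins", 30L, as.integer))
    utils::write.csv(hist, paste0(prefix, "_histogram.csv"),
                     row.names = FALSE)
    q <- .opt(opts, "top", 0.01, as.numeric)
    top <- names(sort(k, decreasing = TRUE))[seq_len(ceiling(q * length(k)))]
    dss <- Biostrings::RNAStringSet(top)
    names(dss) <- top
    Biostrings::writeXStringSet(dss, paste0(prefix, "_top.fasta"))
    logo <- logoMatrix(top)
    utils::write.csv(rbind(logo@freq, bits = logo@bits),
                     paste0(prefix, "_logo.csv"))
    .logEvent(opts$log, list(step = "report", rates = rates,
                             prefix = prefix, nTop = length(top)))
    invisible(0L)
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`simulate-pool`, `count`, `krel`,
#' `fit-specificity`, `pairing`, `fit-kinetics`, `report`) over the
#' package's functions. Options are `--key value` flags, optionally seeded
#' from a YAML file via `--config` (flags take precedence); `--log <file>`
#' appends JSON-lines progress records. A thin wrapper script suitable for
#' `Rscript` ships in `inst/scripts/htskin.R`.
#'
#' @param args character vector, subcommand first (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, invisibly: 0 ok, 1 user error, 2 internal
#'   error.
#' @export
htskinCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
    if (!length(args)) {
        message("usage: htskin <simulate-pool|count|krel|fit-specificity|",
                "pairing|fit-kinetics|report> [--key value ...]")
        return(invisible(1L))
    }
    sub <- args[1]
    status <- tryCatch({
        opts <- .parseArgs(args[-1])
        switch(sub,
            "simulate-pool" = .cliSimulatePool(opts),
            "count" = .cliCount(opts),
            "krel" = .cliKrel(opts),
            "fit-specificity" = .cliFitSpecificity(opts),
            "pairing" = .cliPairing(opts),
            "fit-kinetics" = .cliFitKinetics(opts),
            "report" = .cliReport(opts),
            stop("unknown subcommand: ", sub))
        0L
    }, error = function(e) {
        message("error: ", conditionMessage(e))
        1L
    })
    invisible(status)
}

.cliCount <- function(opts) {
    fastqs <- strsplit(.opt(opts, "fastq", ""), ",")[[1]]
    if (!length(fastqs) || !all(file.exists(fastqs)))
        stop("--fastq <file[,file...]> is required")
    f <- as.numeric(strsplit(.opt(opts, "f", ""), ",")[[1]])
    if (length(f) != length(fastqs))
        stop("--f must give one fraction per FASTQ")
    reps <- as.integer(strsplit(.opt(opts, "replicate",
        paste(rep(1, length(fastqs)), collapse = ",")), ",")[[1]])
    pc <- countReads(as.list(setNames(fastqs, basename(fastqs))),
                     f = f, replicate = reps,
                     maxMismatch = .opt(opts, "max-mismatch", 1L,
                                        as.integer))
    out <- .opt(opts, "out", "counts.csv")
    writePoolCounts(pc, out)
    .logEvent(opts$log, list(step = "count", fastq = fastqs, out = out,
                             rejected = as.list(metadata(pc)$rejected)))
    invisible(0L)
}
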