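Package: htskin
Title: High-Throughput Sequencing Kinetics of RNase P 5' Leader Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of high-throughput sequencing kinetics
    (HTS-Kin) experiments that measure relative kcat/Km for all 4096
    randomized 5' leader hexamer variants of a precursor tRNA substrate by
    internal competition. Provides a multinomial pool-depletion simulator,
    FASTQ variant extraction and counting, relative rate constant estimation
    calibrated to a reference leader, a position weight matrix regression
    with iteratively selected pairwise interaction terms, maximum
    base-pairing scores between the 5' leader and the tRNA 3' RCCA tail
    (Watson-Crick plus G:U wobble, bulges allowed), sequence logos, and
    weighted Michaelis-Menten, equilibrium binding and biphasic dissociation
    fits for single-substrate assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
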