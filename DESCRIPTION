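Package: ampbench
Title: Benchmarking Amplicon Sequence Inference Under Varying Microbial Biomass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates 16S rRNA mock-community dilution series with
    reagent-style contamination, sequencer noise and PCR bimeras; implements
    desk-scale versions of six de novo amplicon sequence inference strategies
    (greedy OTU clustering, UPARSE-style clustering with inline chimera
    checks, UNOISE-style and Deblur-style denoising, a DADA-style iterative
    error-model denoiser, and minimum entropy decomposition); classifies
    inferred features against the known community and a contaminant pool;
    and computes recall, precision, read-fraction and alpha-diversity
    summaries across the dilution axis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
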