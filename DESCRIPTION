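Package: lambscan
Title: Deep Mutational Scanning of a Dual-Function Phage Receptor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of pooled deep-mutational-scanning
    experiments on the Escherichia coli maltoporin LamB, which serves both as
    the maltodextrin transporter and as the receptor for phage lambda.
    Generates error-prone-PCR variant libraries over a LamB-like coding
    sequence, simulates growth competition under phage-lambda and maltodextrin
    selections, emulates Tn5 tagmentation and paired-end short-read sequencing,
    and re-derives per-mutation effects: raw read pairs are collapsed into
    error-corrected unique fragments, per-position base counts are converted to
    log2 enrichments with a pseudocount, enrichments are scaled to functional
    scores anchored at the synonymous (1) and nonsense (0) medians, and scores
    are classified into lambda-resistance and maltodextrin-utilisation
    phenotypes via thresholds, Gaussian-intersection estimates,
    Kolmogorov-Smirnov tests and Mal+/Mal- ratio curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
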