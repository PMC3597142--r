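Package: nucleofinder
Title: Bayesian Detection of Well-Positioned Nucleosomes from MNase-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls well-positioned nucleosomes from MNase-Seq read counts by
    Bayesian model selection over a five-bin sliding window. Signal counts
    are corrected by subtracting a naked-DNA control sample, binned at 30 bp,
    and each 150 bp region is scored by comparing eight Poisson models that
    assign background (gamma prior) or enriched (uniform prior) rates to the
    centre bin and the two flanking segments; a region is called when the
    flank-background / centre-enriched model attains the largest marginal
    likelihood, with the Bayes factor against the all-background model as
    score. Also provides a read-permutation specificity assessment,
    inter-nucleosome spacing estimation downstream of active TSSs, the
    AA/TT vs GC dinucleotide signature with confidence intervals, and a
    synthetic MNase-Seq simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
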