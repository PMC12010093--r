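Package: codonkit
Title: Multi-Criteria Codon Usage Analysis and Synthetic Gene Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds host codon and codon-pair usage references from
    coding-sequence corpora (with highly-expressed-gene subsetting), scores
    candidate genes with a multi-criteria suite (codon adaptation index,
    individual codon usage and codon-context fitness, codon-pair bias,
    overall and positional GC content, mRNA folding stability, restriction
    site screening), generates optimized coding sequences by the
    one-amino-acid-one-codon or usage-matched sampling strategy under motif
    constraints, and compares sequence sets by principal component analysis,
    hierarchical clustering and metric correlation. Includes a synthetic
    corpus generator with controllable codon bias so every analysis is
    reproducible without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
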