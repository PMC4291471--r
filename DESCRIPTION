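Package: mtdr
Title: Typical Codon Decoding Rates and the MTDR Translation Efficiency Index
    from Ribosome Profiling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates each codon's typical decoding time from ribosome
    profiling footprint counts by fitting an exponentially modified Gaussian
    to per-codon normalized footprint-count (NFC) distributions, and scores
    open reading frames by the geometric mean of their codons' typical
    decoding rates (the MTDR index), a condition- and tissue-specific
    translation elongation efficiency index. Includes reference
    implementations of the CAI and tAI codon-usage indexes, validation
    statistics (Spearman and partial Spearman correlation, protein-abundance
    regression with coefficient confidence intervals, held-out ribosomal-load
    prediction, condition comparison tests), and a synthetic ribosome-profile
    generator so the full pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
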