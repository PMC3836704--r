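Package: coft
Title: Compositional Order of Protein Sequences via Frequent Amino-Acid Triplets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of compositional order in protein
    sequences through frequent amino-acid triplets (FTs): overlapping k-mers
    occurring at least n times in a protein, far beyond the expectation of a
    Bernoulli null model. Provides per-protein order measures (relative
    coverage, most frequent interval, relative periodicity, generalized k-mer
    Shannon entropy, motif purity classes), an analytic binomial expectation
    for FT misidentification with Monte-Carlo validation, proteome-level
    FT-vocabulary analysis (DFT counts, Jaccard similarity between
    vocabularies, predominant-FT ranking, power-law fits of FT abundance and
    of the length dependence of order measures), threshold-sweep functional
    enrichment with hypergeometric significance, and seedable generators of
    random and planted-motif synthetic proteomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
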