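Package: sialome
Title: Salivary-Gland EST Analysis: Clustering, Secretome Classification,
    Divergence, Codon Volatility and Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for salivary-gland (sialome) EST studies in
    blood-feeding insects. Clusters expressed sequence tags into contigs and
    singletons by exact-word seeded overlaps, translates reads in three
    frames and selects the reportable open reading frame, flags putative
    secretion, and assigns housekeeping / secreted / unknown functional
    classes from an annotation-evidence table. Downstream analyses cover
    cross-species protein identity with alignment-length and allele-dedup
    filters (Mann-Whitney class comparison), codon volatility under the
    standard genetic code with a Welch t class comparison, cross-library
    transcript-frequency chi-square tests, and neighbor-joining protein
    phylogenies with nonparametric bootstrap support. A synthetic-data
    module generates EST libraries, ortholog pairs, coding genes and
    protein families with known ground truth so every stage is testable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    seqinr,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
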