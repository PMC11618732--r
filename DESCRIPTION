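Package: DigestProfiler
Title: Protease Cleavage-Specificity Profiling and Modification-Aware In
    Silico Digestion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling the cleavage specificity of proteases from
    bottom-up proteomics peptide identifications, developed around prolyl
    endopeptidase (post-Pro/Ala/Cys) digestion. Reads protein FASTA and
    search-engine peptide tables, applies score/length and
    replicate-reproducibility filters, maps peptides to proteins, extracts
    nonredundant cleavage sites, and computes Keil-normalized P1 and P1'
    preference profiles together with digest-quality metrics (sequence
    coverage, unique peptides, peptide length, per-residue redundancy).
    Includes a cysteine-modification-aware in silico digestion engine and a
    stochastic replicate simulator (missed cleavages, nonspecific cleavage,
    acid hydrolysis after Asp, detection dropout) for validation, plus
    monoisotopic peptide mass prediction and immobilized-enzyme column
    residence-time estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
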