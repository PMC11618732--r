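---
title: "Profiling protease cleavage specificity from peptide identifications"
author: "DigestProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling protease cleavage specificity from peptide identifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DigestProfiler)
```

## The problem

Bottom-up proteomics with an unconventional protease — here a prolyl
endopeptidase of the post-Pro/Ala type whose activity extends to reduced
cysteine — needs a way to measure, from ordinary search-engine output, *what
the enzyme actually cut*. The observable is a list of identified peptides
per replicate; the quantity of interest is the enzyme's subsite preference:
how often each amino acid occupies the P1 position (the residue immediately
N-terminal to the cleaved bond) and the P1′ position (immediately
C-terminal), relative to how often that amino acid occurs at all.

DigestProfiler implements that analysis end to end, plus the inverse tool: a
cysteine-modification-aware in silico digestion engine and stochastic
replicate simulator that generate data with a *known* specificity, so the
whole pipeline can be validated by parameter recovery.

## The procedure

1. **Evidence filtering.** Observations are kept when their score is
   strictly above `minScore` (default 25, ion-score-like) and their peptide
   is strictly longer than `minPeptideLength` (default 6). FDR is treated as
   an upstream search-engine property and carried as metadata only —
   re-deriving it would require the decoy database the search engine used.
2. **Reproducibility.** A peptide key is the triple (protein accession,
   peptide sequence, canonical modification string); keys observed in at
   least *k* of *n* replicates survive. *k = n* gives the "fully
   reproducible" (e.g. 3-of-3) peptides on which preference figures should
   be based, since singleton identifications are enriched for search
   artifacts. Modified and unmodified forms are distinct keys: a
   Cys-carbamidomethyl peptide is chemically distinct evidence.
3. **Mapping.** Exact substring search (via Biostrings) locates each key in
   its protein; peptides occurring more than once, or in more than one
   protein, are flagged ambiguous and excluded from site extraction by
   default — an ambiguous location would fabricate sites. They still count
   toward coverage. Leu/Ile are never collapsed.
4. **Nonredundant sites.** Every retained peptide terminus witnesses a
   cleavage: the bond before `start` and the bond after `end`, skipping
   protein termini (those are not cleavages). Sites are deduplicated on
   (protein, bond position): a site counts once however many peptides
   support it.
5. **Keil normalization.** For each residue X,
   `normalized(X) = (sites with P1 = X / total sites) / (background
   fraction of X)`, where the background is the amino-acid composition of
   the identified regions (union of covered residues). A value of 1 means
   no preference. Whole-protein background is available as a sensitivity
   mode (`backgroundMode = "whole_proteins"`).

Digest quality is summarized per protein by sequence coverage, number of
unique peptide keys, average peptide length over keys, and per-residue
redundancy (depth): the number of mapped peptide occurrences spanning each
covered residue, reported as a mean and a histogram. The depth reading of
"redundancy" was chosen over PSM multiplicity because it pairs naturally
with a distribution over residues and contrasts with the unique-peptide
count; users comparing against tools that count PSMs per peptide should be
aware of the difference.

## The digestion model

`SpecificityRule` holds the enzyme model:

* `p1Residues` (default `P, A, C`) — cleavage occurs after these residues.
* `blockingStates` (default carbamidomethyl, oxidized, disulfide) — a Cys
  in any of these states is not cleaved after; unset Cys positions default
  to reduced, matching the usual pre-reduced (TCEP) sample. This reproduces
  the insulin logic: intact (disulfide-bonded) or oxidized chains digest
  only after Pro/Ala, reduced chains also after Cys.
* `nonspecificRate` (default 0.02 per bond) — background nonspecific
  cleavage.
* `acidHydrolysisAspRate` (default 0.05 per bond) — an additional post-Asp
  channel modelling acid hydrolysis at the very low pH these digestions
  run at; chemical, not enzymatic, hence a separate rate.
* `missedCleavageProb` (default 0.1) — probability a true site is skipped
  in a stochastic digest.

`inSilicoDigest()` is the deterministic engine (no noise, full
missed-cleavage enumeration, monoisotopic masses from the standard residue
table, water 18.0105647 Da, proton 1.0072765 Da). Disulfide status is used
only to block cleavage; cross-linked peptide masses are out of scope.

`simulateReplicates()` is the stochastic generator: per replicate it keeps
each true site with probability `1 - missedCleavageProb`, cuts each other
bond with `nonspecificRate` (plus `acidHydrolysisAspRate` after Asp), forms
peptides between consecutive cuts, discards those shorter than
`minDetectLength` (default 7, consistent with the length > 6 filter),
drops each survivor with `detectionDropout` (default 0.3), and attaches
Normal(60, 15) scores — cosmetic values on an ion-score-like scale, present
only so score filters are exercised. All draws flow from one integer seed
and the caller's RNG state is untouched.

## What the simulator does and does not emulate

The generator reproduces the features the analysis depends on: a planted P1
preference, modification-dependent blocking of post-Cys cleavage, missed
cleavages, nonspecific background, a post-Asp acid channel, and
per-replicate detection dropout. Two real-data features are deliberately
absent, and they matter for interpreting passing tests:

* **Correlated missed cleavages.** Real replicate digests miss largely the
  *same* hard-to-cut sites (site susceptibility is chemical), so real data
  combine high coverage with many fully reproducible peptides. The
  generator samples misses independently per replicate; the probability a
  partially missed fragment reproduces 3-of-3 falls as
  `((1-p)^2 p^m (1-dropout))^3`, so reproducible evidence comes almost
  entirely from zero-missed fragments. We therefore simulate a
  near-complete digest (`missedCleavageProb = 0.1`), which preserves the
  analysis-relevant observable — abundant reproducible peptides with
  recoverable specificity — at the cost of lower sequence coverage than a
  real partial digest shows, because for an enzyme with roughly one
  cleavable bond in five, complete digestion leaves most fragments below
  the detectable length. Passing recovery tests demonstrate the pipeline's
  correctness, not that the generator is a complete model of digestion
  kinetics.
* **No retention-time, isotope-envelope or score-distribution realism**,
  and no enzyme kinetics: enzyme/protein-ratio and time effects can only be
  represented through the noise rates.

## Numerical and degenerate-input choices

* Strict inequalities in the filters, exactly as conventionally printed
  (`> 25`, `> 6`).
* Residues absent from the normalization background are reported `NA`
  ("not applicable"), never 0 — a zero would masquerade as biology. A
  residue can have observed sites yet a zero background at sparse coverage,
  because a peptide's flanking P1 (at `start−1`) and P1′ (at `end+1`)
  residues lie just outside the covered region; this produces a warning and
  `NA` rather than an error.
* Zero identified sites give an all-zero profile; an empty peptide set
  gives zero coverage and a warning, with average length reported as 0.
* Residue output order is fixed (`ARNDCQEGHILKMFPSTWYV`) so TSV outputs
  diff cleanly; the pipeline is deterministic, and repeated runs produce
  byte-identical files.
* Nonstandard codes (B, Z, X, U, J) are rejected by default; a permissive
  mode masks them with a sentinel that is excluded from all preference
  statistics, since preferences over ambiguity codes are meaningless.
* "Cys pairs" are counted as adjacent C-C dipeptides with overlap
  (`CCC` contains two), the reading consistent with a sequence-level
  statement about the primary structure; the alternative reading
  (disulfide-bonded partner pairs) is a different quantity, not computed by
  `countMotif()`.
* Residence time rounds to the nearest whole second: a 69 uL bed gives
  41.4 s at 100 uL/min and 20.7 s at 200 uL/min, reported as 41 s and 21 s.

## The validation study

The recovery study digests 24 synthetic proteins of 350 residues with
vertebrate-like amino-acid frequencies (`makeTestProteins()`), in
triplicate with the default noise rates, filters at 3-of-3 reproducibility,
and asks whether the three largest Keil-normalized P1 values are exactly
{P, A, C}. The mixture size was set so that the identified-region
background reliably contains cysteine — under near-complete digestion,
covered cysteines come only from peptides *ending* in Cys, and with too few
proteins that count is Poisson-small and occasionally zero, which would
make the C preference `NA` for want of a denominator rather than for want
of signal. With 24 proteins the study yields a median of roughly 80
nonredundant sites per run. A second arm marks every Cys carbamidomethyl
and checks that the normalized post-Cys value falls below both post-Pro and
post-Ala, mirroring the alkylation experiment. Both arms are run 100 times
with distinct seeds in the test suite and the acceptance script.

```{r recovery, eval = FALSE}
mix <- makeTestProteins(n = 24, lengths = 350, seed = 42)
sim <- simulateReplicates(mix, SpecificityRule(), SimConfig(seed = 1001))
res <- runPipeline(mix, sim$evidence, k = 3, n = 3)
sort(normalizedValues(res$profiles$P1), decreasing = TRUE)[1:5]
```

## Known limitations

* FDR is not recomputed and no decoy machinery exists; the package trusts
  the upstream search.
* No protein inference or grouping: shared peptides are simply flagged
  ambiguous.
* Only P1 and P1′ are profiled; extended subsite matrices (P2, P3, …) are
  out of scope.
* Disulfide "pairing" is a blocking state, not a cross-link mass model.
* The simulator's independence assumptions understate real replicate
  correlation (see above), so absolute coverage and redundancy values from
  simulations should not be compared against real digests.
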