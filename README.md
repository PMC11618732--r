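# DigestProfiler

Cleavage-specificity profiling for bottom-up proteomics with
unconventional proteases, built around prolyl endopeptidase digestion of
the post-Pro/Ala type whose activity extends to *reduced* cysteine.

Given protein sequences (FASTA) and replicate peptide-identification
tables (MASCOT-, PEAKS- or generic-TSV-shaped), the package:

* filters observations (score strictly > 25, peptide length strictly > 6
  by default; FDR is treated as an upstream search-engine property),
* keeps peptide keys — (accession, sequence, modification string) —
  reproduced in at least *k* of *n* replicates (*k = n*: "fully
  reproducible", e.g. 3-of-3),
* maps peptides to proteins and extracts **nonredundant cleavage sites**
  (one count per unique (protein, bond) from either peptide terminus,
  protein termini excluded),
* computes **Keil-normalized P1 and P1′ preference profiles**,

      normalized(X) = ( n_sites(P1 = X) / n_sites ) / ( f_bg(X) )

  where `f_bg(X)` is the fraction of residue X in the identified sequence
  regions, so 1 = no preference,
* reports digest-quality metrics per protein: sequence coverage, unique
  peptides, average peptide length, and per-residue redundancy (mean depth
  and its distribution).

It also ships the inverse tool for validation: a cysteine-modification-
aware in silico digestion engine (`inSilicoDigest`) in which
carbamidomethylated, oxidized or disulfide-bonded Cys block post-Cys
cleavage, a stochastic replicate simulator (`simulateReplicates`) with
missed cleavages, nonspecific cleavage, a post-Asp acid-hydrolysis channel
and detection dropout, monoisotopic peptide masses (`peptideMass`), and the
immobilized-enzyme column residence-time estimate (`residenceTime`).

## Worked example

```r
library(DigestProfiler)

# insulin digestion logic: reduced chains cleave after Cys too
ins <- readProteins(system.file("extdata", "insulin.fasta",
                                package = "DigestProfiler"))
inSilicoDigest(ins["INS_B"], SpecificityRule(), maxMissed = 0)$sequence
#> [1] "FVNQHLC"   "GSHLVEA"   "LYLVC"     "GERGFFYTP" "KT"

insOx <- markAllCys(ins, "oxidized")   # oxidation blocks post-Cys cleavage
inSilicoDigest(insOx["INS_B"], SpecificityRule(), maxMissed = 0)$sequence
#> [1] "FVNQHLCGSHLVEA" "LYLVCGERGFFYTP" "KT"

residenceTime(69, 100)   # 69 uL bed at 100 uL/min
#> [1] 41

# recover a planted {P, A, C} specificity from noisy triplicate digests
mix <- makeTestProteins(n = 24, lengths = 350, seed = 42)
sim <- simulateReplicates(mix, SpecificityRule(), SimConfig(seed = 1001))
res <- runPipeline(mix, sim$evidence, k = 3, n = 3)
res$profiles$P1
#> PreferenceProfile (P1), 69 nonredundant site(s), background: identified_regions
#>   top normalized preferences:  P=10.61  A=10.45  C=6.74
```

The five B-chain fragments end at the two Cys, the single Ala, the single
Pro, and the C terminus; with Cys oxidized only the Pro and Ala bonds
remain. In the recovery run, the three largest Keil-normalized P1 values
are exactly the planted cleavage residues; everything else sits near or
below 1.

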