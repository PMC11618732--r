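#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

# canonical residue order used in every table and profile (diffable output)
AA_ORDER <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
              "P","S","T","W","Y","V")

# sentinel residue for nonstandard codes under the permissive alphabet policy;
# excluded from all preference statistics and backgrounds
AA_SENTINEL <- "X"

CYS_STATES <- c("reduced", "carbamidomethyl", "oxidized", "disulfide")

#' ProteinSet: named protein sequences with optional per-Cys modification states
#'
#' A thin wrapper around a [Biostrings::AAStringSet] holding mature protein
#' chains, plus an optional record of the chemical state of each cysteine
#' (reduced, carbamidomethyl, oxidized or disulfide-bonded). Cys states drive
#' the modification-aware digestion engine: a protease that cleaves after
#' reduced Cys is blocked at modified positions.
#'
#' @slot sequences an \code{AAStringSet}, names are protein accessions.
#' @slot cysStates a named list (by accession); each element is a character
#'   vector of states named by 1-based Cys position. Missing positions default
#'   to \code{"reduced"}.
#' @exportClass ProteinSet
setClass("ProteinSet",
  representation(sequences = "AAStringSet", cysStates = "list"))

setValidity("ProteinSet", function(object) {
  seqs <- object@sequences
  if (length(seqs) > 0 && (is.null(names(seqs)) || anyNA(names(seqs)) ||
                           any(names(seqs) == "")))
    return("all sequences must be named by accession")
  if (anyDuplicated(names(seqs)))
    return("duplicated accessions")
  allowed <- c(AA_ORDER, AA_SENTINEL)
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    if (nchar(s) == 0)
      return(sprintf("empty sequence for record '%s'", names(seqs)[i]))
    bad <- setdiff(unique(strsplit(s, "")[[1]]), allowed)
    if (length(bad))
      return(sprintf("record '%s' contains invalid residue(s): %s",
                     names(seqs)[i], paste(bad, collapse = ", ")))
  }
  cs <- object@cysStates
  if (length(cs)) {
    if (is.null(names(cs)) || !all(names(cs) %in% names(seqs)))
      return("cysStates entries must be named by known accessions")
    for (acc in names(cs)) {
      st <- cs[[acc]]
      if (length(st) == 0) next
      pos <- suppressWarnings(as.integer(names(st)))
      if (anyNA(pos))
        return(sprintf("cysStates positions for '%s' must be integers", acc))
      s <- as.character(seqs[[match(acc, names(seqs))]])
      if (any(pos < 1L | pos > nchar(s)))
        return(sprintf("cysStates position out of range for '%s'", acc))
      if (any(substring(s, pos, pos) != "C"))
        return(sprintf("cysStates for '%s' names a non-Cys residue", acc))
      if (!all(st %in% CYS_STATES))
        return(sprintf("unknown Cys state(s): %s",
                       paste(setdiff(st, CYS_STATES), collapse = ", ")))
    }
  }
  TRUE
})

#' PeptideEvidence: identified peptides across replicates
#'
#' One row per identified peptide per replicate, as exported by search
#' engines: protein accession, peptide sequence, canonical modification
#' string (semicolon-joined \code{position:name} tokens), an ion-score-like
#' confidence score and a replicate label.
#'
#' @slot observations a [S4Vectors::DataFrame] with columns \code{protein},
#'   \code{peptide}, \code{mods}, \code{score}, \code{replicate}.
#' @slot replicateIds ordered character vector of replicate labels present.
#' @exportClass PeptideEvidence
setClass("PeptideEvidence",
  representation(observations = "DataFrame", replicateIds = "character"))

setValidity("PeptideEvidence", function(object) {
  obs <- object@observations
  need <- c("protein", "peptide", "mods", "score", "replicate")
  miss <- setdiff(need, colnames(obs))
  if (length(miss))
    return(sprintf("observations missing column(s): %s",
                   paste(miss, collapse = ", ")))
  if (nrow(obs)) {
    if (any(is.na(obs$peptide)) || any(obs$peptide == ""))
      return("peptide sequences must be non-empty")
    if (!all(obs$replicate %in% object@replicateIds))
      return("observation replicate label not in replicateIds")
    # modification positions must index into the peptide
    mp <- .modPositions(obs$mods)
    bad <- mapply(function(p, pep) length(p) && any(p < 1L | p > nchar(pep)),
                  mp, obs$peptide)
    if (any(bad))
      return("modification position outside 1..peptide length")
  }
  TRUE
})

#' FilterCriteria: upstream-confidence thresholds for peptide evidence
#'
#' Score and length thresholds applied with strict inequality, following the
#' common reporting convention "IonScore > 25, peptide length > 6". The FDR
#' field is carried as metadata only: FDR control is a property of the
#' upstream database search and is not recomputed here.
#'
#' @slot minScore peptides with score strictly greater are kept.
#' @slot minPeptideLength peptides strictly longer are kept.
#' @slot maxFdr nominal upstream FDR fraction (metadata, not enforced).
#' @exportClass FilterCriteria
setClass("FilterCriteria",
  representation(minScore = "numeric", minPeptideLength = "integer",
                 maxFdr = "numeric"),
  prototype(minScore = 25, minPeptideLength = 6L, maxFdr = 0.01))

setValidity("FilterCriteria", function(object) {
  if (length(object@minScore) != 1 || is.na(object@minScore))
    return("minScore must be a single number")
  if (length(object@minPeptideLength) != 1 || object@minPeptideLength < 0L)
    return("minPeptideLength must be a single non-negative integer")
  TRUE
})

#' SpecificityRule: the digestion model of a protease
#'
#' Defines which peptide bonds are cleavable (by the P1 residue, i.e. the
#' residue N-terminal to the scissile bond) and the noise channels of a real
#' digest. Cleavage after Cys happens only when that Cys is in its reduced
#' state; any state listed in \code{blockingStates} blocks it.
#'
#' @slot p1Residues residues cleaved after (default P, A, C for a prolyl
#'   endopeptidase with post-Pro/Ala/Cys specificity).
#' @slot blockingStates Cys states that block post-Cys cleavage.
#' @slot nonspecificRate per-bond probability of a nonspecific cut (stochastic
#'   simulation only).
#' @slot acidHydrolysisAspRate additional per-bond probability of cleavage
#'   after Asp, modelling acid hydrolysis at very low pH.
#' @slot missedCleavageProb probability that a true cleavable site is skipped.
#' @exportClass SpecificityRule
setClass("SpecificityRule",
  representation(p1Residues = "character", blockingStates = "character",
                 nonspecificRate = "numeric", acidHydrolysisAspRate = "numeric",
                 missedCleavageProb = "numeric"),
  prototype(p1Residues = c("P", "A", "C"),
            blockingStates = c("carbamidomethyl", "oxidized", "disulfide"),
            nonspecificRate = 0.02, acidHydrolysisAspRate = 0.05,
            missedCleavageProb = 0.1))

setValidity("SpecificityRule", function(object) {
  if (!all(object@p1Residues %in% AA_ORDER))
    return("p1Residues must be standard one-letter codes")
  if (!all(object@blockingStates %in% CYS_STATES))
    return("unknown blocking state")
  for (nm in c("nonspecificRate", "acidHydrolysisAspRate",
               "missedCleavageProb")) {
    v <- slot(object, nm)
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      return(sprintf("%s must be a single probability in [0, 1]", nm))
  }
  TRUE
})

#' SimConfig: replicate-level parameters of the digest simulator
#'
#' @slot nReplicates number of replicate digests to simulate.
#' @slot detectionDropout probability that a generated peptide goes
#'   undetected in a given replicate.
#' @slot minDetectLength peptides shorter than this are never detected.
#' @slot scoreMean,scoreSd parameters of the Normal score model (cosmetic,
#'   used to exercise score filters).
#' @slot seed integer seed; all randomness flows from it.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nReplicates = "integer", detectionDropout = "numeric",
                 minDetectLength = "integer", scoreMean = "numeric",
                 scoreSd = "numeric", seed = "integer"),
  prototype(nReplicates = 3L, detectionDropout = 0.3, minDetectLength = 7L,
            scoreMean = 60, scoreSd = 15, seed = 1L))

setValidity("SimConfig", function(object) {
  if (object@nReplicates < 1L) return("nReplicates must be >= 1")
  if (object@detectionDropout < 0 || object@detectionDropout > 1)
    return("detectionDropout must be in [0, 1]")
  if (object@minDetectLength < 0L) return("minDetectLength must be >= 0")
  if (object@scoreSd < 0) return("scoreSd must be >= 0")
  TRUE
})

#' PreferenceProfile: raw and Keil-normalized cleavage preferences
#'
#' Per-residue counts of nonredundant cleavage sites at P1 (or P1') plus
#' Keil-normalized values: the observed residue fraction divided by that
#' residue's background fraction in the analyzed sequences, so 1 means no
#' preference. Residues absent from the background carry \code{NA} (not
#' applicable), never a silent zero.
#'
#' @slot position "P1" or "P1prime".
#' @slot rawCounts,rawFractions,normalized named numeric vectors over the 20
#'   standard residues in the fixed order ARNDCQEGHILKMFPSTWYV.
#' @slot nSites number of nonredundant sites tallied.
#' @slot background list with \code{counts} (named) and \code{total}: the
#'   composition used as the normalization denominator.
#' @slot backgroundMode "identified_regions" or "whole_proteins".
#' @exportClass PreferenceProfile
setClass("PreferenceProfile",
  representation(position = "character", rawCounts = "numeric",
                 rawFractions = "numeric", normalized = "numeric",
                 nSites = "integer", background = "list",
                 backgroundMode = "character"))

setValidity("PreferenceProfile", function(object) {
  if (!object@position %in% c("P1", "P1prime"))
    return("position must be 'P1' or 'P1prime'")
  for (nm in c("rawCounts", "rawFractions", "normalized")) {
    v <- slot(object, nm)
    if (!identical(names(v), AA_ORDER))
      return(sprintf("%s must be named by the 20 residues in canonical order",
                     nm))
  }
  if (abs(sum(object@rawCounts) - object@nSites) > 1e-9)
    return("rawCounts must sum to nSites")
  if (object@nSites > 0 && abs(sum(object@rawFractions) - 1) > 1e-9)
    return("rawFractions must sum to 1 when sites exist")
  TRUE
})

#' DigestSummary: digest-quality metrics for one protein
#'
#' The four digest parameters reported for a protein digest: sequence
#' coverage, number of unique peptides, average peptide length, and
#' per-residue redundancy (mean depth plus its distribution).
#'
#' @slot accession protein accession.
#' @slot sequenceCoverage fraction of residues covered (0-1).
#' @slot nUniquePeptides distinct peptide keys mapped to the protein.
#' @slot averagePeptideLength mean length over distinct peptide keys.
#' @slot averageRedundancy mean coverage depth over covered residues.
#' @slot redundancyDistribution named numeric: depth -> number of residues at
#'   that depth (covered residues only).
#' @exportClass DigestSummary
setClass("DigestSummary",
  representation(accession = "character", sequenceCoverage = "numeric",
                 nUniquePeptides = "integer", averagePeptideLength = "numeric",
                 averageRedundancy = "numeric",
                 redundancyDistribution = "numeric"))

setValidity("DigestSummary", function(object) {
  if (object@sequenceCoverage < 0 || object@sequenceCoverage > 1)
    return("sequenceCoverage must be in [0, 1]")
  if (object@sequenceCoverage > 0 && object@averageRedundancy < 1)
    return("averageRedundancy must be >= 1 when coverage > 0")
  TRUE
})
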