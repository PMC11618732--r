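# Standard monoisotopic residue masses (IUPAC/Unimod), Da.
MONO_MASS <- c(
  A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, Q = 128.058578, E = 129.042593, G = 57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
  T = 101.047678, W = 186.079313, Y = 163.063329, V = 99.068414)

WATER_MONO <- 18.0105646837
PROTON_MONO <- 1.00727646677

#' Common modification mass deltas (monoisotopic, Da)
#'
#' Carbamidomethylation of Cys (+57.02146) and single oxidation (+15.99491).
#' @export
MOD_DELTAS <- c(carbamidomethyl = 57.02146, oxidation = 15.99491)

#' Construct a SpecificityRule
#'
#' Defaults describe a post-Pro/Ala/Cys prolyl endopeptidase whose post-Cys
#' activity requires reduced cysteine: carbamidomethylated, oxidized or
#' disulfide-bonded Cys block cleavage.
#'
#' @param p1Residues residues cleaved after.
#' @param blockingStates Cys states that block post-Cys cleavage.
#' @param nonspecificRate per-bond probability of a nonspecific cut.
#' @param acidHydrolysisAspRate extra per-bond cut probability after Asp
#'   (acid hydrolysis at low pH).
#' @param missedCleavageProb probability a true site is skipped.
#' @return a [SpecificityRule-class].
#' @export
SpecificityRule <- function(p1Residues = c("P", "A", "C"),
                            blockingStates = c("carbamidomethyl", "oxidized",
                                               "disulfide"),
                            nonspecificRate = 0.02,
                            acidHydrolysisAspRate = 0.05,
                            missedCleavageProb = 0.1) {
  new("SpecificityRule", p1Residues = p1Residues,
      blockingStates = blockingStates, nonspecificRate = nonspecificRate,
      acidHydrolysisAspRate = acidHydrolysisAspRate,
      missedCleavageProb = missedCleavageProb)
}

#' Construct a SimConfig
#'
#' @param nReplicates replicate digests (default 3, the usual triplicate).
#' @param detectionDropout probability a peptide goes undetected in a
#'   replicate.
#' @param minDetectLength shortest detectable peptide (default 7, consistent
#'   with a length > 6 identification filter).
#' @param scoreMean,scoreSd Normal score model for simulated ion scores.
#' @param seed integer seed for all randomness.
#' @return a [SimConfig-class].
#' @export
SimConfig <- function(nReplicates = 3L, detectionDropout = 0.3,
                      minDetectLength = 7L, scoreMean = 60, scoreSd = 15,
                      seed = 1L) {
  new("SimConfig", nReplicates = as.integer(nReplicates),
      detectionDropout = detectionDropout,
      minDetectLength = as.integer(minDetectLength),
      scoreMean = scoreMean, scoreSd = scoreSd, seed = as.integer(seed))
}

# Deterministically cleavable bond positions (P1 indices) of one protein:
# bonds whose P1 residue is in the rule's P1 set and, for Cys, whose state is
# not blocking (unset states default to reduced).
.cleavablePositions <- function(seq, states, rule) {
  L <- nchar(seq)
  if (L < 2) return(integer(0))
  chars <- strsplit(seq, "")[[1]]
  pos <- which(chars[-L] %in% rule@p1Residues)
  if (!length(pos)) return(integer(0))
  isC <- chars[pos] == "C"
  if (any(isC) && length(states)) {
    st <- states[as.character(pos[isC])]
    st[is.na(st)] <- "reduced"
    blocked <- st %in% rule@blockingStates
    pos <- c(pos[!isC], pos[isC][!blocked])
    pos <- sort(pos)
  }
  pos
}

#' Deterministically cleavable sites of a ProteinSet
#'
#' The bonds a protease with the given rule can cut: P1 residue in the
#' rule's P1 set, and for Cys, the recorded state must not be blocking.
#' Noise rates are ignored — this is the rule's ground truth.
#'
#' @param proteins a [ProteinSet-class].
#' @param rule a [SpecificityRule-class].
#' @return data.frame: protein, p1_position, p1_residue, p1prime_residue.
#' @export
cleavableSites <- function(proteins, rule = SpecificityRule()) {
  stopifnot(is(proteins, "ProteinSet"), is(rule, "SpecificityRule"))
  seqs <- proteinSequences(proteins)
  out <- lapply(names(seqs), function(acc) {
    pos <- .cleavablePositions(seqs[[acc]], cysStates(proteins, acc), rule)
    if (!length(pos)) return(NULL)
    data.frame(protein = acc, p1_position = pos,
               p1_residue = substring(seqs[[acc]], pos, pos),
               p1prime_residue = substring(seqs[[acc]], pos + 1L, pos + 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(protein = character(0), p1_position = integer(0),
                      p1_residue = character(0),
                      p1prime_residue = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# fragments between consecutive cut positions, with up to maxMissed internal
# sites; cuts is sorted, 0 < cuts < L
.fragments <- function(cuts, L, maxMissed) {
  bounds <- c(0L, cuts, L)
  m <- length(bounds) - 1L               # number of minimal segments
  out <- vector("list", 0L)
  for (i in seq_len(m)) {
    jmax <- min(m, i + maxMissed)
    for (j in i:jmax) {
      out[[length(out) + 1L]] <- c(start = bounds[i] + 1L, end = bounds[j + 1L],
                                   missed = j - i)
    }
  }
  do.call(rbind, out)
}

#' In silico digestion of proteins
#'
#' Deterministic full enumeration: cuts at every cleavable bond (see
#' [cleavableSites()]; Cys sites are skipped when their recorded state blocks
#' cleavage) and returns all peptides with up to \code{maxMissed} internal
#' missed cleavages, with monoisotopic masses and singly protonated m/z.
#' Noise rates in the rule are ignored here.
#'
#' @param proteins a [ProteinSet-class].
#' @param rule a [SpecificityRule-class].
#' @param maxMissed maximum internal missed cleavable sites (>= 0).
#' @return data.frame: protein, start, end, sequence, n_missed,
#'   monoisotopic_mass, mz_mh.
#' @examples
#' ins <- ProteinSet(c(insB = "FVNQHLCGSHLVEALYLVCGERGFFYTPKT"))
#' inSilicoDigest(ins, SpecificityRule(), maxMissed = 0)$sequence
#' @export
inSilicoDigest <- function(proteins, rule = SpecificityRule(),
                           maxMissed = 0L) {
  stopifnot(is(proteins, "ProteinSet"), is(rule, "SpecificityRule"))
  if (maxMissed < 0) stop("maxMissed must be >= 0")
  seqs <- proteinSequences(proteins)
  out <- lapply(names(seqs), function(acc) {
    s <- seqs[[acc]]
    cuts <- .cleavablePositions(s, cysStates(proteins, acc), rule)
    fr <- .fragments(cuts, nchar(s), maxMissed)
    data.frame(protein = acc, start = fr[, "start"], end = fr[, "end"],
               sequence = substring(s, fr[, "start"], fr[, "end"]),
               n_missed = fr[, "missed"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$monoisotopic_mass <- .peptideMasses(out$sequence)
  out$mz_mh <- out$monoisotopic_mass + PROTON_MONO
  out
}

# vectorized unmodified monoisotopic masses
.peptideMasses <- function(seqs) {
  vapply(seqs, function(s)
    sum(MONO_MASS[strsplit(s, "")[[1]]]) + WATER_MONO,
    numeric(1), USE.NAMES = FALSE)
}

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water, plus any modification
#' deltas. The proton mass for [M+H]+ is \code{1.00727646677} Da.
#'
#' @param sequence non-empty amino-acid string over the 20 standard codes.
#' @param mods optional data.frame with columns \code{position} (1-based)
#'   and \code{delta} (Da), e.g. carbamidomethyl = +57.02146.
#' @return mass in Da.
#' @examples
#' peptideMass("G")                     # 75.032 Da
#' peptideMass("C", data.frame(position = 1, delta = 57.02146))
#' @export
peptideMass <- function(sequence, mods = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (is.na(sequence) || nchar(sequence) == 0)
    stop("sequence must be non-empty")
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% names(MONO_MASS)))
    stop("nonstandard residue(s): ",
         paste(setdiff(chars, names(MONO_MASS)), collapse = ", "))
  m <- sum(MONO_MASS[chars]) + WATER_MONO
  if (!is.null(mods) && nrow(mods)) {
    if (any(mods$position < 1 | mods$position > nchar(sequence)))
      stop("modification position out of range")
    m <- m + sum(mods$delta)
  }
  unname(m)
}

#' Simulate replicate digests with realistic noise
#'
#' The synthetic-data generator: per replicate, each true cleavable site is
#' realized with probability \code{1 - missedCleavageProb}; every other bond
#' is cut with probability \code{nonspecificRate}; bonds after Asp get an
#' additional \code{acidHydrolysisAspRate} chance (acid hydrolysis). Peptides
#' form between consecutive cuts/termini; those shorter than
#' \code{minDetectLength} are never detected and the rest drop out with
#' probability \code{detectionDropout}. Scores are Normal(scoreMean,
#' scoreSd). Fully deterministic for a fixed \code{seed}; the caller's RNG
#' state is left untouched.
#'
#' @param proteins a [ProteinSet-class].
#' @param rule a [SpecificityRule-class].
#' @param cfg a [SimConfig-class].
#' @return list: \code{evidence} (a [PeptideEvidence-class], replicate
#'   labels \code{r1..rn}) and \code{truth} (the rule-defined cleavable
#'   sites, as from [cleavableSites()]).
#' @export
simulateReplicates <- function(proteins, rule = SpecificityRule(),
                               cfg = SimConfig()) {
  stopifnot(is(proteins, "ProteinSet"), is(rule, "SpecificityRule"),
            is(cfg, "SimConfig"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg@seed)

  seqs <- proteinSequences(proteins)
  truth <- cleavableSites(proteins, rule)
  rows <- list()
  for (r in seq_len(cfg@nReplicates)) {
    rep_id <- paste0("r", r)
    for (acc in names(seqs)) {
      s <- seqs[[acc]]
      L <- nchar(s)
      if (L < 1) next
      true_pos <- truth$p1_position[truth$protein == acc]
      keep_true <- true_pos[stats::runif(length(true_pos)) >
                              rule@missedCleavageProb]
      other <- setdiff(seq_len(max(L - 1L, 0L)), true_pos)
      cut_other <- other[stats::runif(length(other)) < rule@nonspecificRate]
      asp <- setdiff(which(strsplit(s, "")[[1]][-L] == "D"), true_pos)
      cut_asp <- asp[stats::runif(length(asp)) < rule@acidHydrolysisAspRate]
      cuts <- sort(unique(c(keep_true, cut_other, cut_asp)))
      bounds <- c(0L, cuts, L)
      st <- bounds[-length(bounds)] + 1L
      en <- bounds[-1]
      len <- en - st + 1L
      ok <- len >= cfg@minDetectLength
      st <- st[ok]; en <- en[ok]
      if (!length(st)) next
      detected <- stats::runif(length(st)) >= cfg@detectionDropout
      st <- st[detected]; en <- en[detected]
      if (!length(st)) next
      rows[[length(rows) + 1L]] <- data.frame(
        protein = acc, peptide = substring(s, st, en), mods = "",
        score = stats::rnorm(length(st), cfg@scoreMean, cfg@scoreSd),
        replicate = rep_id, stringsAsFactors = FALSE)
    }
  }
  obs <- do.call(rbind, rows)
  ev <- if (is.null(obs))
    PeptideEvidence(replicate = character(0))
  else PeptideEvidence(obs$protein, obs$peptide, obs$mods, obs$score,
                       obs$replicate)
  # all replicate labels present even if a replicate detected nothing
  ev@replicateIds <- paste0("r", seq_len(cfg@nReplicates))
  list(evidence = ev, truth = truth)
}

#' Residence time in an immobilized-enzyme column
#'
#' The estimated sample contact time: bed volume divided by flow rate,
#' reported to the nearest second. A 69 uL bed at 100 uL/min gives 41 s; at
#' 200 uL/min, 21 s.
#'
#' @param bedVolume column bed volume, uL.
#' @param flowRate flow rate, uL/min.
#' @return residence time in whole seconds.
#' @examples
#' residenceTime(69, 100)  # 41
#' residenceTime(69, 200)  # 21
#' @export
residenceTime <- function(bedVolume, flowRate) {
  if (any(!is.finite(bedVolume)) || any(bedVolume <= 0))
    stop("bedVolume must be > 0")
  if (any(!is.finite(flowRate)) || any(flowRate <= 0))
    stop("flowRate must be > 0")
  as.integer(round(bedVolume / flowRate * 60))
}

setMethod("show", "SpecificityRule", function(object) {
  cat(sprintf("SpecificityRule: cleave after {%s}\n",
              paste(object@p1Residues, collapse = ", ")))
  cat(sprintf("  post-Cys blocked by: %s\n",
              paste(object@blockingStates, collapse = ", ")))
  cat(sprintf("  nonspecific %.3g, post-Asp acid %.3g, missed-cleavage %.3g\n",
              object@nonspecificRate, object@acidHydrolysisAspRate,
              object@missedCleavageProb))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d replicate(s), dropout %.2f, min length %d, score N(%g, %g), seed %d\n",
    object@nReplicates, object@detectionDropout, object@minDetectLength,
    object@scoreMean, object@scoreSd, object@seed))
})

# vertebrate-average amino-acid frequencies (percent), used for synthetic
# test proteins
AA_FREQ <- c(A = 7.0, R = 5.5, N = 3.6, D = 4.7, C = 2.3, Q = 4.8, E = 7.1,
             G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.2, F = 3.6,
             P = 6.3, S = 8.3, T = 5.3, W = 1.2, Y = 2.7, V = 6.0)

#' Generate random test proteins
#'
#' Synthetic proteins with vertebrate-like residue frequencies, for sizing
#' simulation studies beyond the shipped fixtures. Deterministic for a fixed
#' seed; the caller's RNG state is left untouched.
#'
#' @param n number of proteins.
#' @param lengths integer vector of lengths (recycled to \code{n}).
#' @param seed integer seed.
#' @return a [ProteinSet-class] with accessions \code{SYNP1..SYNPn}.
#' @export
makeTestProteins <- function(n = 10L, lengths = 350L, seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  lengths <- rep_len(as.integer(lengths), n)
  seqs <- vapply(lengths, function(L)
    paste(sample(names(AA_FREQ), L, replace = TRUE, prob = AA_FREQ),
          collapse = ""), character(1))
  names(seqs) <- paste0("SYNP", seq_len(n))
  ProteinSet(seqs)
}
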