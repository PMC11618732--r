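#' Digest-quality metrics for one protein
#'
#' Computes the standard digest parameters from mapped (nonredundant)
#' peptides: sequence coverage, number of unique peptides, average peptide
#' length, and per-residue redundancy. Redundancy at a residue is its
#' coverage depth — how many mapped peptide occurrences span it; the summary
#' reports the mean depth over covered residues and the full depth histogram.
#' Peptides ambiguous within the protein contribute every occurrence to
#' depth and coverage. Averages are over distinct peptide keys.
#'
#' @param matches the \code{matches} data.frame from [mapPeptides()],
#'   restricted to one protein (rows for any other protein are an error).
#' @param protein a [ProteinSet-class] of length 1, or a larger set plus
#'   \code{accession}.
#' @param accession which protein to summarize (default: the only one).
#' @return a [DigestSummary-class] object.
#' @examples
#' ps <- ProteinSet(c(p = "AAAAAAAA"))
#' m <- data.frame(protein = "p", start = 1L, end = 4L, peptide = "AAAA",
#'                 mods = "", ambiguous = FALSE)
#' computeDigestSummary(m, ps)
#' @export
computeDigestSummary <- function(matches, protein, accession = NULL) {
  stopifnot(is(protein, "ProteinSet"))
  if (is.null(accession)) {
    if (length(protein) != 1)
      stop("give 'accession' when 'protein' holds several sequences")
    accession <- accessions(protein)
  }
  L <- unname(seqLengths(protein)[accession])
  if (nrow(matches) && !all(matches$protein == accession))
    stop("matches reference a protein other than ", accession)

  if (is.null(matches$mods)) matches$mods <- ""
  # one row per (key, occurrence); duplicated input rows collapse
  occ <- unique(matches[, c("peptide", "mods", "start", "end"),
                        drop = FALSE])
  keys <- unique(occ[, c("peptide", "mods"), drop = FALSE])

  depth <- integer(L)
  for (i in seq_len(nrow(occ)))
    depth[occ$start[i]:occ$end[i]] <- depth[occ$start[i]:occ$end[i]] + 1L
  covered <- depth > 0L

  if (nrow(keys) == 0) {
    warning("no peptides for ", accession,
            "; average peptide length reported as 0")
    avg_len <- 0
  } else {
    avg_len <- mean(nchar(keys$peptide))
  }
  dist <- if (any(covered)) {
    tab <- table(depth[covered])
    stats::setNames(as.numeric(tab), names(tab))
  } else stats::setNames(numeric(0), character(0))

  new("DigestSummary",
      accession = accession,
      sequenceCoverage = sum(covered) / L,
      nUniquePeptides = nrow(keys),
      averagePeptideLength = avg_len,
      averageRedundancy = if (any(covered)) mean(depth[covered]) else 0,
      redundancyDistribution = dist)
}

#' Per-protein digest summaries
#'
#' Applies [computeDigestSummary()] to every protein with at least one match.
#' Peptides shared across proteins (cross-protein ambiguous) are excluded
#' from per-protein summaries; peptides ambiguous only within a protein are
#' kept with all their occurrences.
#'
#' @param matches the \code{matches} data.frame from [mapPeptides()].
#' @param proteins a [ProteinSet-class].
#' @return a named list of [DigestSummary-class], one per covered protein.
#' @export
digestSummaries <- function(matches, proteins) {
  stopifnot(is(proteins, "ProteinSet"))
  if (nrow(matches) == 0) return(list())
  # cross-protein shared peptides: same (peptide, mods) on > 1 accession
  key <- paste(matches$peptide, matches$mods, sep = "\r")
  nprot <- tapply(matches$protein, key, function(p) length(unique(p)))
  shared <- names(nprot)[nprot > 1]
  m <- matches[!key %in% shared, , drop = FALSE]
  accs <- intersect(accessions(proteins), unique(m$protein))
  out <- lapply(accs, function(a)
    computeDigestSummary(m[m$protein == a, , drop = FALSE], proteins,
                         accession = a))
  stats::setNames(out, accs)
}

#' One-row data.frame view of a DigestSummary
#' @param x a [DigestSummary-class].
#' @return a data.frame (coverage as a percentage).
#' @export
summaryAsRow <- function(x) {
  stopifnot(is(x, "DigestSummary"))
  data.frame(accession = x@accession,
             sequence_coverage_pct = 100 * x@sequenceCoverage,
             n_unique_peptides = x@nUniquePeptides,
             average_peptide_length = x@averagePeptideLength,
             average_redundancy = x@averageRedundancy,
             stringsAsFactors = FALSE)
}

#' @describeIn computeDigestSummary accessor for the redundancy histogram.
#' @param x a [DigestSummary-class].
#' @export
redundancyDistribution <- function(x) {
  stopifnot(is(x, "DigestSummary"))
  x@redundancyDistribution
}

setMethod("show", "DigestSummary", function(object) {
  cat(sprintf("DigestSummary for %s\n", object@accession))
  cat(sprintf("  coverage: %.1f%%  unique peptides: %d\n",
              100 * object@sequenceCoverage, object@nUniquePeptides))
  cat(sprintf("  avg peptide length: %.2f  avg redundancy: %.3f\n",
              object@averagePeptideLength, object@averageRedundancy))
  if (length(object@redundancyDistribution)) {
    cat("  depth histogram: ")
    cat(paste(sprintf("%sx:%d", names(object@redundancyDistribution),
                      as.integer(object@redundancyDistribution)),
              collapse = "  "), "\n")
  }
})
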