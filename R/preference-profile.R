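#' Build a Keil-normalized cleavage-preference profile
#'
#' Tallies the P1 (or P1') residue of every nonredundant cleavage site and
#' normalizes each residue's observed fraction by its background fraction in
#' the analyzed sequences, after Keil: \deqn{norm(X) =
#' \frac{count(X)/n_{sites}}{bg(X)/bg_{total}}} so a value of 1 means
#' "cleaved exactly as often as chance given how often X occurs at all".
#'
#' The default background is the composition of the identified regions — the
#' union of residues covered by the mapped peptides — because preferences are
#' computed from identified sequences; \code{"whole_proteins"} uses the full
#' sequences instead, for sensitivity analysis. Residues absent from the
#' background get \code{NA}, not zero. Sentinel residues (masked nonstandard
#' codes) are excluded from both counts and background.
#'
#' @param sites data.frame from [extractCleavageSites()].
#' @param matches data.frame from [mapPeptides()]; defines the identified
#'   regions for the default background.
#' @param proteins a [ProteinSet-class].
#' @param position \code{"P1"} (residue before the cut) or \code{"P1prime"}
#'   (residue after it).
#' @param backgroundMode \code{"identified_regions"} (default) or
#'   \code{"whole_proteins"}.
#' @return a [PreferenceProfile-class] object.
#' @export
buildProfile <- function(sites, matches, proteins,
                         position = c("P1", "P1prime"),
                         backgroundMode = c("identified_regions",
                                            "whole_proteins")) {
  position <- match.arg(position)
  backgroundMode <- match.arg(backgroundMode)
  stopifnot(is(proteins, "ProteinSet"))

  res <- if (position == "P1") sites$p1_residue else sites$p1prime_residue
  res <- res[res %in% AA_ORDER]           # sentinel/invalid excluded
  nSites <- length(res)
  rawCounts <- stats::setNames(numeric(length(AA_ORDER)), AA_ORDER)
  if (nSites) {
    tab <- table(factor(res, levels = AA_ORDER))
    rawCounts[] <- as.numeric(tab)
  }

  bg <- .profileBackground(matches, proteins, backgroundMode)
  bgCounts <- stats::setNames(numeric(length(AA_ORDER)), AA_ORDER)
  common <- intersect(names(bg$counts), AA_ORDER)
  bgCounts[common] <- bg$counts[common]
  bgTotal <- sum(bgCounts)

  rawFractions <- if (nSites) rawCounts / nSites else rawCounts
  # a flanking P1/P1' residue can fall just outside the covered regions at
  # sparse coverage; its preference is then not computable (NA), not zero
  if (any(rawCounts > 0 & bgCounts == 0))
    warning("residue(s) with observed sites but zero background: ",
            paste(AA_ORDER[rawCounts > 0 & bgCounts == 0], collapse = ", "),
            "; normalized value reported as NA")
  normalized <- stats::setNames(rep(NA_real_, length(AA_ORDER)), AA_ORDER)
  present <- bgCounts > 0
  if (bgTotal > 0)
    normalized[present] <- rawFractions[present] /
      (bgCounts[present] / bgTotal)

  new("PreferenceProfile", position = position, rawCounts = rawCounts,
      rawFractions = rawFractions, normalized = normalized,
      nSites = as.integer(nSites),
      background = list(counts = bgCounts, total = bgTotal),
      backgroundMode = backgroundMode)
}

.profileBackground <- function(matches, proteins, backgroundMode) {
  seqs <- proteinSequences(proteins)
  if (backgroundMode == "whole_proteins")
    return(composition(paste(seqs, collapse = "")))
  if (nrow(matches) == 0) return(list(counts = integer(0), total = 0L))
  pieces <- character(0)
  for (acc in unique(matches$protein)) {
    m <- matches[matches$protein == acc, , drop = FALSE]
    cov <- logical(nchar(seqs[[acc]]))
    for (i in seq_len(nrow(m))) cov[m$start[i]:m$end[i]] <- TRUE
    pieces <- c(pieces,
                paste(strsplit(seqs[[acc]], "")[[1]][cov], collapse = ""))
  }
  composition(paste(pieces, collapse = ""))
}

#' Accessor: normalized preference values
#' @param x a [PreferenceProfile-class].
#' @return named numeric over the 20 residues (NA where not applicable).
#' @export
normalizedValues <- function(x) {
  stopifnot(is(x, "PreferenceProfile"))
  x@normalized
}

#' Accessor: raw site counts per residue
#' @param x a [PreferenceProfile-class].
#' @return named numeric over the 20 residues.
#' @export
rawCounts <- function(x) {
  stopifnot(is(x, "PreferenceProfile"))
  x@rawCounts
}

#' Profile as a data.frame in canonical residue order
#' @param x a [PreferenceProfile-class].
#' @return data.frame: residue, raw_count, raw_fraction, background_fraction,
#'   normalized.
#' @export
profileTable <- function(x) {
  stopifnot(is(x, "PreferenceProfile"))
  bgf <- if (x@background$total > 0)
    x@background$counts / x@background$total
  else stats::setNames(rep(NA_real_, length(AA_ORDER)), AA_ORDER)
  data.frame(residue = AA_ORDER,
             raw_count = unname(x@rawCounts),
             raw_fraction = unname(x@rawFractions),
             background_fraction = unname(bgf[AA_ORDER]),
             normalized = unname(x@normalized),
             stringsAsFactors = FALSE)
}

#' Write a profile as TSV
#' @param x a [PreferenceProfile-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProfile <- function(x, path) {
  utils::write.table(profileTable(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bar plot of a preference profile
#'
#' @param x a [PreferenceProfile-class].
#' @param what \code{"normalized"} or \code{"raw_fraction"}.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted values.
#' @export
plotProfile <- function(x, what = c("normalized", "raw_fraction"), ...) {
  what <- match.arg(what)
  v <- if (what == "normalized") x@normalized else x@rawFractions
  graphics::barplot(ifelse(is.na(v), 0, v), names.arg = AA_ORDER,
                    ylab = if (what == "normalized")
                      "Keil-normalized preference" else "fraction of sites",
                    xlab = sprintf("%s residue", x@position),
                    las = 2, ...)
  if (what == "normalized") graphics::abline(h = 1, lty = 2)
  invisible(v)
}

setMethod("show", "PreferenceProfile", function(object) {
  cat(sprintf("PreferenceProfile (%s), %d nonredundant site(s), background: %s\n",
              object@position, object@nSites, object@backgroundMode))
  v <- sort(object@normalized[!is.na(object@normalized) &
                              object@normalized > 0], decreasing = TRUE)
  if (length(v)) {
    top <- utils::head(v, 5)
    cat("  top normalized preferences: ",
        paste(sprintf("%s=%.2f", names(top), top), collapse = "  "), "\n")
  }
})

#' Run the full cleavage-preference pipeline
#'
#' FASTA + peptide tables in; filtered, reproducibility-thresholded,
#' mapped, site-extracted, Keil-normalized profiles out. Steps: read inputs,
#' apply score/length filters, keep peptide keys seen in at least \code{k} of
#' \code{n} replicates, locate them in the proteins, extract nonredundant
#' cleavage sites, and compute P1 and P1' profiles plus per-protein digest
#' summaries. Deterministic: identical inputs give byte-identical outputs.
#'
#' @param fasta path to the protein FASTA.
#' @param tables paths to peptide tables (or a ready
#'   [PeptideEvidence-class]).
#' @param dialect table dialect, see [readPeptideTable()].
#' @param k,n reproducibility threshold: keys in at least \code{k} of
#'   \code{n} replicates (use \code{k = n} for fully reproducible peptides).
#' @param criteria a [FilterCriteria-class].
#' @param backgroundMode see [buildProfile()].
#' @param includeAmbiguous see [extractCleavageSites()].
#' @param outDir if non-NULL, writes \code{profile_P1.tsv},
#'   \code{profile_P1prime.tsv}, \code{sites.tsv}, \code{summary.tsv} and a
#'   \code{run_log.json} with all parameters there.
#' @return a list: \code{profiles} (P1, P1prime), \code{summaries},
#'   \code{sites}, \code{matches}, \code{unmapped}, \code{reproducible},
#'   \code{evidence}.
#' @export
runPipeline <- function(fasta, tables, dialect = "generic_tsv", k, n,
                        criteria = new("FilterCriteria"),
                        backgroundMode = "identified_regions",
                        includeAmbiguous = FALSE, outDir = NULL) {
  if (k < 1 || k > n) stop("need 1 <= k <= n")   # fail before any output
  proteins <- if (is(fasta, "ProteinSet")) fasta else readProteins(fasta)
  ev <- if (is(tables, "PeptideEvidence")) tables
        else readPeptideTables(tables, dialect = dialect)
  ev <- applyFilters(ev, criteria)
  keys <- filterReproducible(ev, k = k, n = n)
  mapped <- mapPeptides(keys, proteins)
  sites <- extractCleavageSites(mapped$matches, proteins,
                                includeAmbiguous = includeAmbiguous)
  profs <- list(
    P1 = buildProfile(sites, mapped$matches, proteins, "P1", backgroundMode),
    P1prime = buildProfile(sites, mapped$matches, proteins, "P1prime",
                           backgroundMode))
  sums <- digestSummaries(mapped$matches, proteins)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeProfile(profs$P1, file.path(outDir, "profile_P1.tsv"))
    writeProfile(profs$P1prime, file.path(outDir, "profile_P1prime.tsv"))
    utils::write.table(sites, file.path(outDir, "sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(do.call(rbind, lapply(sums, summaryAsRow)),
                       file.path(outDir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log <- list(k = k, n = n, dialect = dialect,
                min_score = criteria@minScore,
                min_peptide_length = criteria@minPeptideLength,
                background_mode = backgroundMode,
                include_ambiguous = includeAmbiguous,
                n_observations = length(ev),
                n_reproducible_keys = nrow(keys),
                n_sites = nrow(sites))
    jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(profiles = profs, summaries = sums, sites = sites,
       matches = mapped$matches, unmapped = mapped$unmapped,
       reproducible = keys, evidence = ev)
}
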