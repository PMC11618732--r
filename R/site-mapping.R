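#' Locate peptides within proteins
#'
#' Exact substring search of each peptide key in its assigned protein, or in
#' all proteins when the accession is missing or unknown. Every occurrence is
#' returned (overlapping occurrences included). A match is flagged ambiguous
#' when the peptide occurs more than once in its protein or also occurs in
#' another protein — an ambiguous location would fabricate cleavage sites, so
#' downstream site extraction drops ambiguous matches by default.
#' Leu and Ile are never collapsed: search engines report a concrete
#' sequence, and collapsing would create spurious ambiguity.
#'
#' @param peptides a data.frame with columns \code{protein}, \code{peptide}
#'   and optionally \code{mods} (as from [filterReproducible()]), or a
#'   character vector of peptide sequences (searched in all proteins).
#' @param proteins a [ProteinSet-class].
#' @return a list with \code{matches} — data.frame(protein, start, end,
#'   peptide, mods, ambiguous), 1-based inclusive coordinates — and
#'   \code{unmapped} — the keys whose peptide was found nowhere it was looked
#'   for.
#' @export
mapPeptides <- function(peptides, proteins) {
  stopifnot(is(proteins, "ProteinSet"))
  if (is.character(peptides))
    peptides <- data.frame(protein = NA_character_, peptide = peptides,
                           mods = "", stringsAsFactors = FALSE)
  if (!all(c("protein", "peptide") %in% colnames(peptides)))
    stop("peptides must have columns 'protein' and 'peptide'")
  if (is.null(peptides$mods)) peptides$mods <- ""
  peptides <- unique(peptides[, c("protein", "peptide", "mods")])
  seqs <- proteinSequences(proteins)
  accs <- names(seqs)

  out <- vector("list", nrow(peptides))
  unmapped <- logical(nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    pep <- peptides$peptide[i]
    acc <- peptides$protein[i]
    assigned <- !is.na(acc) && acc %in% accs
    search_in <- if (assigned) acc else accs
    hits <- lapply(search_in, function(a) {
      m <- Biostrings::matchPattern(pep, Biostrings::AAString(seqs[[a]]))
      if (length(m) == 0) return(NULL)
      data.frame(protein = a, start = Biostrings::start(m),
                 end = Biostrings::end(m), stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits)
    n_here <- if (is.null(hits)) 0L else nrow(hits)
    if (n_here == 0L) {
      unmapped[i] <- TRUE
      next
    }
    # shared-peptide check: an assigned peptide is also ambiguous if it
    # occurs in any other protein
    elsewhere <- if (assigned) {
      any(vapply(setdiff(accs, acc), function(a)
        Biostrings::countPattern(pep, Biostrings::AAString(seqs[[a]])) > 0,
        logical(1)))
    } else length(unique(hits$protein)) > 1
    amb <- n_here > 1L || elsewhere
    out[[i]] <- data.frame(hits, peptide = pep, mods = peptides$mods[i],
                           ambiguous = amb, stringsAsFactors = FALSE)
  }
  matches <- do.call(rbind, out)
  if (is.null(matches))
    matches <- data.frame(protein = character(0), start = integer(0),
                          end = integer(0), peptide = character(0),
                          mods = character(0), ambiguous = logical(0),
                          stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  list(matches = matches,
       unmapped = peptides[unmapped, , drop = FALSE])
}

#' Extract nonredundant cleavage sites from peptide matches
#'
#' Each retained peptide terminus witnesses one cleavage event: the bond
#' N-terminal to the peptide (P1 position \code{start - 1}) and the bond
#' C-terminal to it (P1 position \code{end}). Protein termini are not
#' cleavage sites, so bonds at position 0 or at the protein length are
#' skipped. Sites are deduplicated on (protein, P1 position) — a site is
#' counted once no matter how many peptides support it.
#'
#' @param matches the \code{matches} data.frame from [mapPeptides()].
#' @param proteins a [ProteinSet-class].
#' @param includeAmbiguous keep sites from ambiguously located peptides
#'   (default \code{FALSE}).
#' @return a data.frame with columns \code{protein}, \code{p1_position}
#'   (1-based index of the residue N-terminal to the cut), \code{p1_residue},
#'   \code{p1prime_residue}, sorted by protein then position.
#' @export
extractCleavageSites <- function(matches, proteins, includeAmbiguous = FALSE) {
  stopifnot(is(proteins, "ProteinSet"))
  empty <- data.frame(protein = character(0), p1_position = integer(0),
                      p1_residue = character(0),
                      p1prime_residue = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(matches) == 0) return(empty)
  if (!all(matches$protein %in% accessions(proteins)))
    stop("matches reference unknown protein(s)")
  if (!includeAmbiguous)
    matches <- matches[!matches$ambiguous, , drop = FALSE]
  if (nrow(matches) == 0) return(empty)
  lens <- seqLengths(proteins)
  seqs <- proteinSequences(proteins)

  prot <- c(matches$protein, matches$protein)
  pos <- c(matches$start - 1L, matches$end)
  keep <- pos >= 1L & pos < lens[prot]
  prot <- prot[keep]; pos <- pos[keep]
  if (!length(pos)) return(empty)
  key <- paste(prot, pos)
  first <- !duplicated(key)
  prot <- prot[first]; pos <- pos[first]
  out <- data.frame(protein = prot, p1_position = as.integer(pos),
                    p1_residue = substring(seqs[prot], pos, pos),
                    p1prime_residue = substring(seqs[prot], pos + 1L,
                                                pos + 1L),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$protein, out$p1_position), , drop = FALSE]
}
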