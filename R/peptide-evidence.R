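# Canonical modification string: semicolon-joined "position:Name" tokens,
# sorted by position; "" when unmodified.

.modPositions <- function(mods) {
  lapply(mods, function(m) {
    if (is.na(m) || m == "") return(integer(0))
    toks <- strsplit(m, ";", fixed = TRUE)[[1]]
    as.integer(sub(":.*$", "", toks))
  })
}

#' Canonicalize modification strings
#'
#' Accepts semicolon- or comma-separated \code{position:name} tokens with
#' arbitrary spacing (e.g. \code{"5: Carbamidomethyl"}) and returns the
#' canonical form: tokens \code{"pos:Name"} sorted by position, joined by
#' \code{";"}. Empty/NA input canonicalizes to \code{""}.
#'
#' @param x character vector of modification strings.
#' @return character vector of canonical strings.
#' @export
canonicalizeMods <- function(x) {
  vapply(x, function(m) {
    if (is.na(m) || !nzchar(trimws(m))) return("")
    toks <- trimws(strsplit(m, "[;,]")[[1]])
    toks <- toks[nzchar(toks)]
    ok <- grepl("^\\d+\\s*:\\s*\\S", toks)
    if (!all(ok))
      stop("unparseable modification token(s): ",
           paste(toks[!ok], collapse = ", "))
    pos <- as.integer(sub("\\s*:.*$", "", toks))
    name <- trimws(sub("^\\d+\\s*:\\s*", "", toks))
    o <- order(pos)
    paste(sprintf("%d:%s", pos[o], name[o]), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct PeptideEvidence from vectors
#'
#' @param protein,peptide,mods,score,replicate parallel vectors, one element
#'   per identified peptide per replicate. \code{mods} are canonicalized.
#' @return a [PeptideEvidence-class] object.
#' @export
PeptideEvidence <- function(protein = character(0), peptide = character(0),
                            mods = character(0), score = numeric(0),
                            replicate = character(0)) {
  n <- length(peptide)
  if (length(mods) == 0 && n > 0) mods <- rep("", n)
  obs <- S4Vectors::DataFrame(protein = as.character(protein),
                              peptide = as.character(peptide),
                              mods = canonicalizeMods(as.character(mods)),
                              score = as.numeric(score),
                              replicate = as.character(replicate))
  new("PeptideEvidence", observations = obs,
      replicateIds = unique(as.character(replicate)))
}

# PEAKS-style inline modifications: "ABC(+57.02)DE" -> seq "ABCDE",
# mods "3:+57.02". Flanking residues "K.PEPTIDE.R" are stripped.
.parseInlinePeptide <- function(pep) {
  pep <- sub("^[A-Z-]\\.", "", pep)
  pep <- sub("\\.[A-Z-]$", "", pep)
  seq <- ""
  mods <- character(0)
  rest <- pep
  while (nzchar(rest)) {
    ch <- substr(rest, 1, 1)
    if (ch == "(") {
      close <- regexpr(")", rest, fixed = TRUE)
      if (close < 0) stop("unbalanced parenthesis in peptide: ", pep)
      mods <- c(mods, sprintf("%d:%s", nchar(seq),
                              substr(rest, 2, close - 1)))
      rest <- substring(rest, close + 1)
    } else {
      seq <- paste0(seq, ch)
      rest <- substring(rest, 2)
    }
  }
  list(sequence = seq, mods = paste(mods, collapse = ";"))
}

.DIALECTS <- list(
  generic_tsv = list(sep = "\t", required = c("protein", "peptide", "mods",
                                              "score")),
  mascot_csv  = list(sep = ",",  required = c("prot_acc", "pep_seq",
                                              "pep_score")),
  peaks_csv   = list(sep = ",",  required = c("Accession", "Peptide",
                                              "-10lgP"))
)

#' Read a peptide-identification table
#'
#' Supports three dialects of search-engine exports:
#' \describe{
#'   \item{generic_tsv}{tab-separated, columns \code{protein}, \code{peptide},
#'     \code{mods}, \code{score} and optionally \code{replicate}.}
#'   \item{mascot_csv}{comma-separated, columns \code{prot_acc},
#'     \code{pep_seq}, \code{pep_score}, and modifications in
#'     \code{pep_var_mod_pos} or \code{pep_var_mod} when present.}
#'   \item{peaks_csv}{comma-separated, columns \code{Accession},
#'     \code{Peptide} (inline mods like \code{C(+57.02)}), \code{-10lgP}.}
#' }
#' Replicate labels come from a \code{replicate} column when present,
#' otherwise one file is one replicate, labelled by \code{replicate} (default:
#' the file name without extension).
#'
#' @param path delimited text file.
#' @param dialect one of \code{"generic_tsv"}, \code{"mascot_csv"},
#'   \code{"peaks_csv"}.
#' @param replicate label used when the table has no replicate column.
#' @return a [PeptideEvidence-class] object.
#' @export
readPeptideTable <- function(path,
                             dialect = c("generic_tsv", "mascot_csv",
                                         "peaks_csv"),
                             replicate = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- .DIALECTS[[dialect]]
  df <- utils::read.table(path, sep = d$sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  miss <- setdiff(d$required, colnames(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (is.null(replicate))
    replicate <- sub("\\.[^.]*$", "", basename(path))
  getcol <- function(nm) if (nm %in% colnames(df)) df[[nm]] else NULL

  if (dialect == "generic_tsv") {
    protein <- df$protein; peptide <- df$peptide
    mods <- as.character(df$mods); score <- df$score
    rep_ <- getcol("replicate")
  } else if (dialect == "mascot_csv") {
    protein <- df$prot_acc; peptide <- df$pep_seq; score <- df$pep_score
    mods <- getcol("pep_var_mod_pos")
    if (is.null(mods)) mods <- getcol("pep_var_mod")
    if (is.null(mods)) mods <- rep("", nrow(df))
    rep_ <- getcol("replicate")
  } else {
    parsed <- lapply(df$Peptide, .parseInlinePeptide)
    protein <- df$Accession
    peptide <- vapply(parsed, `[[`, "", "sequence")
    mods <- vapply(parsed, `[[`, "", "mods")
    score <- df[["-10lgP"]]
    rep_ <- getcol("replicate")
  }
  if (is.null(rep_)) rep_ <- rep(replicate, length(peptide))
  mods[is.na(mods)] <- ""
  score <- suppressWarnings(as.numeric(score))
  bad <- which(is.na(score) | is.na(peptide) | peptide == "")
  if (length(bad))
    stop(sprintf("%s: unparseable row(s) at line(s) %s", path,
                 paste(bad + 1L, collapse = ", ")))
  PeptideEvidence(protein = protein, peptide = toupper(peptide), mods = mods,
                  score = score, replicate = rep_)
}

#' Read and merge several peptide tables
#'
#' @param paths vector of file paths (typically one per replicate).
#' @param replicates labels, one per file; used when tables carry no
#'   replicate column. Default: file names without extension.
#' @inheritParams readPeptideTable
#' @return a merged [PeptideEvidence-class].
#' @export
readPeptideTables <- function(paths,
                              dialect = c("generic_tsv", "mascot_csv",
                                          "peaks_csv"),
                              replicates = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(replicates))
    replicates <- sub("\\.[^.]*$", "", basename(paths))
  stopifnot(length(replicates) == length(paths))
  parts <- mapply(readPeptideTable, paths, replicate = replicates,
                  MoreArgs = list(dialect = dialect), SIMPLIFY = FALSE)
  obs <- do.call(rbind, lapply(parts, function(p) as.data.frame(p@observations)))
  PeptideEvidence(obs$protein, obs$peptide, obs$mods, obs$score,
                  obs$replicate)
}

#' Construct FilterCriteria
#'
#' @param minScore keep peptides with score strictly greater (default 25).
#' @param minPeptideLength keep peptides strictly longer (default 6).
#' @param maxFdr nominal upstream FDR (metadata only; FDR control happens in
#'   the search engine).
#' @return a [FilterCriteria-class].
#' @export
FilterCriteria <- function(minScore = 25, minPeptideLength = 6L,
                           maxFdr = 0.01) {
  new("FilterCriteria", minScore = minScore,
      minPeptideLength = as.integer(minPeptideLength), maxFdr = maxFdr)
}

#' Apply confidence filters to peptide evidence
#'
#' Keeps observations whose score is strictly greater than
#' \code{minScore} and whose peptide is strictly longer than
#' \code{minPeptideLength} — the conventional "IonScore > 25, length > 6"
#' thresholds. Idempotent; replicate labels are recomputed from the survivors.
#'
#' @param x a [PeptideEvidence-class].
#' @param criteria a [FilterCriteria-class] (defaults: score > 25,
#'   length > 6).
#' @return the filtered [PeptideEvidence-class].
#' @export
applyFilters <- function(x, criteria = new("FilterCriteria")) {
  stopifnot(is(x, "PeptideEvidence"), is(criteria, "FilterCriteria"))
  obs <- x@observations
  keep <- obs$score > criteria@minScore &
    nchar(obs$peptide) > criteria@minPeptideLength
  obs <- obs[keep, , drop = FALSE]
  new("PeptideEvidence", observations = obs,
      replicateIds = unique(obs$replicate))
}

.peptideKey <- function(protein, peptide, mods) {
  paste(protein, peptide, mods, sep = "\r")
}

#' Reproducibility filtering of peptide evidence
#'
#' Returns the peptide keys — (protein accession, peptide sequence, canonical
#' modification string) — observed in at least \code{k} of the \code{n}
#' replicates. "Fully reproducible" peptides are \code{k == n} (e.g. 3 of 3).
#' Modified and unmodified forms of the same sequence are distinct keys.
#'
#' @param x a [PeptideEvidence-class] containing exactly \code{n} distinct
#'   replicate labels.
#' @param k minimum number of distinct replicates a key must appear in.
#' @param n expected number of replicates (checked against the data).
#' @return a data.frame with columns \code{protein}, \code{peptide},
#'   \code{mods}, \code{n_replicates}.
#' @export
filterReproducible <- function(x, k, n) {
  stopifnot(is(x, "PeptideEvidence"))
  if (k < 1 || k > n) stop("need 1 <= k <= n")
  nrep <- length(x@replicateIds)
  if (nrep != n)
    stop(sprintf("evidence has %d replicate label(s), expected n = %d",
                 nrep, n))
  obs <- as.data.frame(x@observations)
  if (nrow(obs) == 0)
    return(data.frame(protein = character(0), peptide = character(0),
                      mods = character(0), n_replicates = integer(0),
                      stringsAsFactors = FALSE))
  key <- .peptideKey(obs$protein, obs$peptide, obs$mods)
  # distinct replicates per key
  u <- unique(data.frame(key = key, replicate = obs$replicate,
                         stringsAsFactors = FALSE))
  cnt <- table(u$key)
  keep <- names(cnt)[cnt >= k]
  first <- obs[match(keep, key), c("protein", "peptide", "mods")]
  out <- data.frame(first,
                    n_replicates = as.integer(cnt[keep]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$protein, out$peptide, out$mods), , drop = FALSE]
}

## --- accessors ------------------------------------------------------------

#' @describeIn PeptideEvidence number of observations (rows).
#' @param x a PeptideEvidence.
#' @export
setMethod("length", "PeptideEvidence", function(x) nrow(x@observations))

#' Observations table of a PeptideEvidence object
#' @param x a [PeptideEvidence-class].
#' @return a data.frame with one row per observation.
#' @export
observations <- function(x) {
  stopifnot(is(x, "PeptideEvidence"))
  as.data.frame(x@observations)
}

#' Replicate labels present in a PeptideEvidence object
#' @param x a [PeptideEvidence-class].
#' @return character vector.
#' @export
replicateIds <- function(x) {
  stopifnot(is(x, "PeptideEvidence"))
  x@replicateIds
}

setMethod("show", "PeptideEvidence", function(object) {
  obs <- object@observations
  cat(sprintf("PeptideEvidence: %d observation(s), %d replicate(s) [%s]\n",
              nrow(obs), length(object@replicateIds),
              paste(object@replicateIds, collapse = ", ")))
  if (nrow(obs)) {
    cat(sprintf("  %d distinct peptide key(s)\n",
                length(unique(.peptideKey(obs$protein, obs$peptide,
                                          obs$mods)))))
  }
})
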