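#' Construct a ProteinSet
#'
#' @param sequences a named character vector of amino-acid sequences, or an
#'   \code{AAStringSet} named by accession.
#' @param cysStates optional named list (by accession) of character vectors of
#'   Cys states (\code{"reduced"}, \code{"carbamidomethyl"},
#'   \code{"oxidized"}, \code{"disulfide"}) named by 1-based Cys position.
#'   Positions not listed default to reduced.
#' @param permissive if \code{TRUE}, nonstandard codes (B, Z, X, U, J) are
#'   mapped to the sentinel residue \code{X}, which is excluded from all
#'   preference statistics; if \code{FALSE} (default) they are an error.
#' @return a [ProteinSet-class] object.
#' @examples
#' ps <- ProteinSet(c(insB = "FVNQHLCGSHLVEALYLVCGERGFFYTPKT"))
#' seqLengths(ps)
#' @export
ProteinSet <- function(sequences, cysStates = list(), permissive = FALSE) {
  if (is(sequences, "AAStringSet")) {
    seqs <- toupper(as.character(sequences))
    names(seqs) <- names(sequences)
  } else {
    seqs <- toupper(as.character(sequences))
    names(seqs) <- names(sequences)
  }
  seqs <- gsub("[[:space:]*]", "", seqs)
  if (permissive) {
    seqs <- chartr("BZUJ", paste(rep(AA_SENTINEL, 4), collapse = ""), seqs)
  } else {
    for (i in seq_along(seqs)) {
      bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), AA_ORDER)
      if (length(bad))
        stop(sprintf(
          "record '%s' contains nonstandard residue(s) %s (use permissive = TRUE to mask them)",
          if (is.null(names(seqs))) as.character(i) else names(seqs)[i],
          paste(bad, collapse = ", ")))
    }
  }
  new("ProteinSet", sequences = Biostrings::AAStringSet(seqs),
      cysStates = cysStates)
}

#' Read protein sequences from FASTA
#'
#' One record per header; sequences are uppercased with whitespace stripped
#' and record order is preserved. The accession is the first whitespace-
#' delimited token of the header.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @inheritParams ProteinSet
#' @return a [ProteinSet-class] object.
#' @export
readProteins <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path)
  accs <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- accs
  ps <- ProteinSet(seqs, permissive = permissive)
  ps
}

#' Write a ProteinSet to FASTA
#'
#' Round-trips accessions and sequences exactly through [readProteins()].
#' Cys states are not serialized (FASTA has no standard representation).
#'
#' @param x a [ProteinSet-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeProteins <- function(x, path) {
  stopifnot(is(x, "ProteinSet"))
  Biostrings::writeXStringSet(x@sequences, path)
  invisible(path)
}

#' Amino-acid composition of a sequence
#'
#' Counts each residue letter; the composition of the identified sequence
#' regions is the denominator of Keil normalization (observed cleavage
#' frequencies are divided by how often each residue occurs at all).
#'
#' @param sequence an amino-acid string (may be empty).
#' @return a list with \code{counts} (named integer vector of residues
#'   present) and \code{total} (sequence length).
#' @examples
#' composition("FVNQHLCGSHLVEALYLVCGERGFFYTPKT")$counts[c("A", "P", "C")]
#' @export
composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (is.na(sequence) || nchar(sequence) == 0)
    return(list(counts = integer(0), total = 0L))
  letters <- strsplit(sequence, "")[[1]]
  tab <- table(letters)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  list(counts = counts, total = nchar(sequence))
}

#' Count overlapping occurrences of a motif
#'
#' Occurrences are counted with overlap: \code{countMotif("CCC", "CC")} is 2.
#' Overlap matters for runs of identical residues, e.g. counting adjacent
#' Cys-Cys pairs in serum albumin.
#'
#' @param sequence amino-acid string to scan.
#' @param motif non-empty amino-acid string.
#' @return non-negative integer count.
#' @examples
#' countMotif("ACCA", "CC")  # 1
#' countMotif("CCC", "CC")   # 2
#' @export
countMotif <- function(sequence, motif) {
  stopifnot(is.character(sequence), length(sequence) == 1,
            is.character(motif), length(motif) == 1)
  if (is.na(motif) || nchar(motif) == 0) stop("motif must be non-empty")
  if (nchar(sequence) < nchar(motif)) return(0L)
  Biostrings::countPattern(motif, Biostrings::AAString(sequence))
}

## --- ProteinSet accessors -------------------------------------------------

#' @describeIn ProteinSet number of protein records.
#' @param x a ProteinSet.
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' Accessions of a ProteinSet
#' @param x a [ProteinSet-class].
#' @return character vector of accessions.
#' @export
accessions <- function(x) {
  stopifnot(is(x, "ProteinSet"))
  names(x@sequences)
}

#' Protein sequences as a character vector
#' @param x a [ProteinSet-class].
#' @return named character vector.
#' @export
proteinSequences <- function(x) {
  stopifnot(is(x, "ProteinSet"))
  s <- as.character(x@sequences)
  names(s) <- names(x@sequences)
  s
}

#' Sequence lengths of a ProteinSet
#' @param x a [ProteinSet-class].
#' @return named integer vector.
#' @export
seqLengths <- function(x) {
  stopifnot(is(x, "ProteinSet"))
  w <- Biostrings::width(x@sequences)
  names(w) <- names(x@sequences)
  w
}

#' Get or set per-Cys modification states
#'
#' States are character vectors named by 1-based Cys position; positions not
#' listed are treated as reduced.
#'
#' @param x a [ProteinSet-class].
#' @param accession a single accession, or \code{NULL} for the whole list.
#' @return named character vector of states (or list over accessions).
#' @export
cysStates <- function(x, accession = NULL) {
  stopifnot(is(x, "ProteinSet"))
  if (is.null(accession)) return(x@cysStates)
  if (!accession %in% accessions(x)) stop("unknown accession: ", accession)
  st <- x@cysStates[[accession]]
  if (is.null(st)) character(0) else st
}

#' @rdname cysStates
#' @param value named character vector of states (names = Cys positions).
#' @export
`cysStates<-` <- function(x, accession, value) {
  stopifnot(is(x, "ProteinSet"))
  cs <- x@cysStates
  cs[[accession]] <- value
  out <- new("ProteinSet", sequences = x@sequences, cysStates = cs)
  validObject(out)
  out
}

#' Mark every cysteine of every protein with one state
#'
#' Convenience for whole-sample chemistry: e.g. iodoacetamide alkylation sets
#' every Cys to carbamidomethyl, which blocks post-Cys cleavage.
#'
#' @param x a [ProteinSet-class].
#' @param state one of \code{"reduced"}, \code{"carbamidomethyl"},
#'   \code{"oxidized"}, \code{"disulfide"}.
#' @return the modified [ProteinSet-class].
#' @export
markAllCys <- function(x, state) {
  stopifnot(is(x, "ProteinSet"), state %in% CYS_STATES)
  seqs <- proteinSequences(x)
  cs <- lapply(seqs, function(s) {
    pos <- which(strsplit(s, "")[[1]] == "C")
    if (!length(pos)) return(character(0))
    stats::setNames(rep(state, length(pos)), as.character(pos))
  })
  cs <- cs[vapply(cs, length, 1L) > 0]
  out <- new("ProteinSet", sequences = x@sequences, cysStates = cs)
  validObject(out)
  out
}

#' @describeIn ProteinSet subset by index or accession.
#' @param i index or accession.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = TRUE) {
  seqs <- x@sequences[i]
  new("ProteinSet", sequences = seqs,
      cysStates = x@cysStates[intersect(names(x@cysStates), names(seqs))])
})

setMethod("show", "ProteinSet", function(object) {
  cat(sprintf("ProteinSet with %d sequence(s)\n", length(object)))
  n <- min(length(object), 6L)
  w <- seqLengths(object)
  for (i in seq_len(n)) {
    s <- proteinSequences(object)[i]
    disp <- if (nchar(s) > 40) paste0(substr(s, 1, 37), "...") else s
    st <- if (!is.null(object@cysStates[[names(w)[i]]])) " [Cys states set]" else ""
    cat(sprintf("  %s (%d aa)%s  %s\n", names(w)[i], w[i], st, disp))
  }
  if (length(object) > n) cat(sprintf("  ... and %d more\n", length(object) - n))
})
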