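# fixture paths (installed package) and small in-code builders

insulinFasta <- function()
  system.file("extdata", "insulin.fasta", package = "DigestProfiler")
bsaFasta <- function()
  system.file("extdata", "bsa_mature.fasta", package = "DigestProfiler")
mixtureFasta <- function()
  system.file("extdata", "toy_mixture.fasta", package = "DigestProfiler")

writeTempFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

writeTempTsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# evidence built directly from vectors, one replicate label per row
makeEvidence <- function(protein, peptide, score = 60,
                         replicate = "r1", mods = "") {
  n <- length(peptide)
  PeptideEvidence(protein = rep_len(protein, n), peptide = peptide,
                  mods = rep_len(mods, n), score = rep_len(score, n),
                  replicate = rep_len(replicate, n))
}

# independent sliding-window motif count (oracle)
slidingCount <- function(s, m) {
  n <- nchar(s); k <- nchar(m)
  if (n < k) return(0L)
  sum(vapply(seq_len(n - k + 1L),
             function(i) substring(s, i, i + k - 1L) == m, logical(1)))
}

# brute-force site oracle: every (protein, position) adjacent to a retained
# peptide terminus, protein termini excluded, unique
oracleSites <- function(matches, lens, includeAmbiguous = FALSE) {
  if (!includeAmbiguous) matches <- matches[!matches$ambiguous, , drop = FALSE]
  seen <- character(0)
  out <- list()
  for (i in seq_len(nrow(matches))) {
    for (p in c(matches$start[i] - 1L, matches$end[i])) {
      if (p < 1L || p >= lens[[matches$protein[i]]]) next
      k <- paste(matches$protein[i], p)
      if (k %in% seen) next
      seen <- c(seen, k)
      out[[length(out) + 1L]] <- data.frame(protein = matches$protein[i],
                                            p1_position = p,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(protein = character(0), p1_position = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$protein, df$p1_position), , drop = FALSE]
}

# brute-force per-residue depth oracle over occurrence intervals
oracleDepth <- function(occ, L) {
  d <- integer(L)
  for (i in seq_len(nrow(occ)))
    for (p in seq(occ$start[i], occ$end[i])) d[p] <- d[p] + 1L
  d
}
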