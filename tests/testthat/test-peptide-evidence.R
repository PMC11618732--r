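test_that("generic_tsv tables are read row-per-observation", {
  f <- writeTempTsv(data.frame(protein = "P1",
                               peptide = c("MKPAGHE", "GIVEQCC", "LLQAW"),
                               mods = "", score = c(40, 55, 31),
                               replicate = "r1"))
  ev <- readPeptideTable(f, "generic_tsv")
  expect_s4_class(ev, "PeptideEvidence")
  expect_equal(length(ev), 3L)
  expect_equal(replicateIds(ev), "r1")

  f2 <- writeTempTsv(data.frame(protein = "P1", mods = "", score = 1))
  expect_error(readPeptideTable(f2, "generic_tsv"), "peptide")
})

test_that("files without a replicate column get one label per file", {
  mk <- function() writeTempTsv(data.frame(protein = "P1", peptide = "MKPAGHE",
                                           mods = "", score = 40))
  ev <- readPeptideTables(c(mk(), mk(), mk()), "generic_tsv",
                          replicates = c("a", "b", "c"))
  expect_equal(replicateIds(ev), c("a", "b", "c"))
})

test_that("mascot modification tokens canonicalize to position:name", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(prot_acc = "P1", pep_seq = "MKPACDE",
                       pep_score = 44, pep_var_mod = "5: Carbamidomethyl"),
            f, row.names = FALSE)
  ev <- readPeptideTable(f, "mascot_csv")
  expect_equal(observations(ev)$mods, "5:Carbamidomethyl")
  # canonical form is a fixed point
  expect_equal(canonicalizeMods("5:Carbamidomethyl"), "5:Carbamidomethyl")
  # unsorted multi-token input sorts by position
  expect_equal(canonicalizeMods("7: Oxidation; 2:Carbamidomethyl"),
               "2:Carbamidomethyl;7:Oxidation")
  expect_error(canonicalizeMods("Carbamidomethyl"), "token")
})

test_that("PEAKS inline modifications are lifted out of the sequence", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(Accession = "P1", Peptide = "MKPAC(+57.02)DE",
                   lgp = 35, check.names = FALSE)
  colnames(df)[3] <- "-10lgP"
  write.csv(df, f, row.names = FALSE)
  ev <- readPeptideTable(f, "peaks_csv")
  expect_equal(observations(ev)$peptide, "MKPACDE")
  expect_equal(observations(ev)$mods, "5:+57.02")
})

test_that("score/length filters are strict and idempotent", {
  ev <- PeptideEvidence(protein = "P1",
                        peptide = c("AAAAAAA", "CCCCCCC", "DDDDDD", "EEEEEEE"),
                        mods = rep("", 4), score = c(25, 25.01, 80, 26),
                        replicate = rep("r1", 4))
  kept <- applyFilters(ev)           # defaults: score > 25, length > 6
  obs <- observations(kept)
  expect_equal(obs$peptide, c("CCCCCCC", "EEEEEEE"))  # score 25 and 6-mer gone
  expect_identical(observations(applyFilters(kept)), obs)  # idempotent

  empty <- applyFilters(PeptideEvidence())
  expect_equal(length(empty), 0L)
})

test_that("reproducibility filter keeps keys seen in >= k of n replicates", {
  ev <- PeptideEvidence(
    protein = "P1",
    peptide = c("AAAAAAA", "AAAAAAA", "AAAAAAA", "CCCCCCC", "CCCCCCC",
                "GGGGGGG"),
    mods = c("", "", "", "", "", "1:Oxidation"),
    score = 60, replicate = c("r1", "r2", "r3", "r1", "r2", "r1"))
  keys <- filterReproducible(ev, k = 3, n = 3)
  expect_equal(keys$peptide, "AAAAAAA")     # 3 of 3 kept, 2 of 3 dropped
  expect_equal(keys$n_replicates, 3L)

  # k = 1 returns every distinct key; modified forms are distinct keys
  k1 <- filterReproducible(ev, k = 1, n = 3)
  expect_equal(nrow(k1), 3L)
  expect_true("1:Oxidation" %in% k1$mods)

  expect_error(filterReproducible(ev, k = 4, n = 3))
  expect_error(filterReproducible(ev, k = 2, n = 4), "replicate")
})

test_that("reproducible key count is monotone non-increasing in k", {
  set.seed(3)
  peps <- paste0(replicate(30, paste(sample(LETTERS[c(1, 3, 4, 5, 7)], 8,
                                            replace = TRUE), collapse = "")))
  rows <- do.call(rbind, lapply(1:4, function(r)
    data.frame(peptide = sample(peps, 18), replicate = paste0("r", r))))
  ev <- PeptideEvidence(protein = "P1", peptide = rows$peptide,
                        mods = rep("", nrow(rows)), score = 60,
                        replicate = rows$replicate)
  counts <- vapply(1:4, function(k) nrow(filterReproducible(ev, k, 4)), 1L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], length(unique(rows$peptide)))
})
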