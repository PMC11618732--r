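test_that("Keil normalization follows the stated ratio on a hand example", {
  # covered region PPPA; all sites after P -> raw fraction 1.0, background
  # fraction 0.75, normalized 4/3
  ps <- ProteinSet(c(p = "PPPAG"))
  m <- data.frame(protein = "p", start = 1L, end = 4L, peptide = "PPPA",
                  mods = "", ambiguous = FALSE)
  sites <- data.frame(protein = "p", p1_position = c(1L, 2L, 3L),
                      p1_residue = "P", p1prime_residue = c("P", "P", "A"))
  prof <- buildProfile(sites, m, ps, "P1", "identified_regions")
  expect_equal(prof@nSites, 3L)
  expect_equal(unname(rawCounts(prof)["P"]), 3)
  expect_equal(unname(normalizedValues(prof)["P"]), 4 / 3)
  # residues absent from the covered region are NA, not zero
  expect_true(is.na(normalizedValues(prof)["W"]))
})

test_that("sites distributed like the background normalize to exactly 1", {
  # covered region has equal counts of A, C, D, G; one site after each
  ps <- ProteinSet(c(p = "ACDGACDGW"))
  m <- data.frame(protein = "p", start = c(1L, 5L), end = c(4L, 8L),
                  peptide = "ACDG", mods = c("a", "b"), ambiguous = FALSE)
  sites <- data.frame(protein = "p", p1_position = c(1L, 2L, 3L, 4L),
                      p1_residue = c("A", "C", "D", "G"),
                      p1prime_residue = c("C", "D", "G", "A"))
  prof <- buildProfile(sites, m, ps, "P1")
  nv <- normalizedValues(prof)
  expect_true(all(abs(nv[c("A", "C", "D", "G")] - 1) < 1e-12))
})

test_that("zero sites give an all-zero profile", {
  ps <- ProteinSet(c(p = "ACDG"))
  m <- data.frame(protein = "p", start = 1L, end = 4L, peptide = "ACDG",
                  mods = "", ambiguous = FALSE)
  sites <- extractCleavageSites(m[0, ], ps)
  prof <- buildProfile(sites, m, ps, "P1")
  expect_equal(prof@nSites, 0L)
  expect_true(all(rawCounts(prof) == 0))
  nv <- normalizedValues(prof)
  expect_true(all(nv[!is.na(nv)] == 0))
})

test_that("profiles are invariant under permutation of input rows", {
  set.seed(13)
  mix <- readProteins(mixtureFasta())
  sim <- simulateReplicates(mix, SpecificityRule(), SimConfig(seed = 31L))
  res <- suppressWarnings(runPipeline(mix, sim$evidence, k = 2, n = 3))
  perm <- sample(nrow(res$sites))
  prof1 <- suppressWarnings(
    buildProfile(res$sites, res$matches, mix, "P1"))
  prof2 <- suppressWarnings(
    buildProfile(res$sites[perm, ], res$matches[sample(nrow(res$matches)), ],
                 mix, "P1"))
  expect_equal(normalizedValues(prof1), normalizedValues(prof2))
  expect_equal(rawCounts(prof1), rawCounts(prof2))
})

test_that("P1prime profiles tally the residue after the cut", {
  ps <- ProteinSet(c(p = "APCGAPCG"))
  m <- data.frame(protein = "p", start = c(1L, 5L), end = c(4L, 8L),
                  peptide = "APCG", mods = c("a", "b"), ambiguous = FALSE)
  sites <- extractCleavageSites(m, ps)
  prime <- buildProfile(sites, m, ps, "P1prime")
  expect_equal(unname(rawCounts(prime)["A"]), 1)  # bond G|A at position 4
})

test_that("the pipeline is deterministic and validates k before any work", {
  mix <- readProteins(mixtureFasta())
  sim <- simulateReplicates(mix, SpecificityRule(), SimConfig(seed = 8L))
  d1 <- file.path(tempdir(), "runA"); d2 <- file.path(tempdir(), "runB")
  r1 <- suppressWarnings(runPipeline(mix, sim$evidence, k = 3, n = 3,
                                     outDir = d1))
  r2 <- suppressWarnings(runPipeline(mix, sim$evidence, k = 3, n = 3,
                                     outDir = d2))
  for (f in c("profile_P1.tsv", "profile_P1prime.tsv", "sites.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_true(file.exists(file.path(d1, "run_log.json")))
  # profile internal consistency
  expect_equal(sum(rawCounts(r1$profiles$P1)), r1$profiles$P1@nSites)

  expect_error(runPipeline(mix, sim$evidence, k = 4, n = 3))
})

test_that("simulated post-P/A/C digests recover the planted specificity", {
  mix <- makeTestProteins(n = 24, lengths = 350, seed = 42)
  sim <- simulateReplicates(mix, SpecificityRule(), SimConfig(seed = 1001L))
  res <- suppressWarnings(runPipeline(mix, sim$evidence, k = 3, n = 3))
  nv <- normalizedValues(res$profiles$P1)
  top3 <- names(sort(nv[!is.na(nv)], decreasing = TRUE))[1:3]
  expect_setequal(top3, c("P", "A", "C"))

  # alkylating every Cys abolishes the post-Cys preference
  alk <- markAllCys(mix, "carbamidomethyl")
  sim2 <- simulateReplicates(alk, SpecificityRule(), SimConfig(seed = 1001L))
  res2 <- suppressWarnings(runPipeline(alk, sim2$evidence, k = 3, n = 3))
  nv2 <- normalizedValues(res2$profiles$P1)
  expect_lt(nv2[["C"]], nv2[["P"]])
  expect_lt(nv2[["C"]], nv2[["A"]])
})
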