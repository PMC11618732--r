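test_that("insulin B chain digests per the post-P/A/C rule, Cys-state aware", {
  ins <- readProteins(insulinFasta())
  red <- inSilicoDigest(ins["INS_B"], SpecificityRule(), maxMissed = 0)
  expect_equal(red$sequence,
               c("FVNQHLC", "GSHLVEA", "LYLVC", "GERGFFYTP", "KT"))

  ox <- markAllCys(ins, "oxidized")
  oxd <- inSilicoDigest(ox["INS_B"], SpecificityRule(), maxMissed = 0)
  expect_equal(oxd$sequence,
               c("FVNQHLCGSHLVEA", "LYLVCGERGFFYTP", "KT"))

  noPAC <- ProteinSet(c(q = "GGKRHE"))
  expect_equal(inSilicoDigest(noPAC, SpecificityRule(), 0)$sequence, "GGKRHE")
  expect_error(inSilicoDigest(ins, SpecificityRule(), -1))
})

test_that("blocking every Cys is equivalent to a post-P/A rule", {
  mix <- readProteins(mixtureFasta())
  blocked <- markAllCys(mix, "disulfide")
  a <- inSilicoDigest(blocked, SpecificityRule(), maxMissed = 1)
  b <- inSilicoDigest(mix, SpecificityRule(p1Residues = c("P", "A")),
                      maxMissed = 1)
  expect_equal(a$sequence, b$sequence)
  expect_equal(a$start, b$start)
})

test_that("zero-missed fragments partition each protein and conserve mass", {
  mix <- readProteins(mixtureFasta())
  d <- inSilicoDigest(mix, SpecificityRule(), maxMissed = 0)
  for (acc in accessions(mix)) {
    frag <- d[d$protein == acc, ]
    expect_equal(paste(frag$sequence, collapse = ""),
                 unname(proteinSequences(mix)[acc]))
    whole <- peptideMass(proteinSequences(mix)[[acc]])
    expect_equal(sum(frag$monoisotopic_mass),
                 whole + (nrow(frag) - 1) * 18.0105646837, tolerance = 1e-9)
  }
})

test_that("missed-cleavage enumeration yields all contiguous joins", {
  ps <- ProteinSet(c(p = "GGAGGAGG"))  # sites after A at 3 and 6
  d0 <- inSilicoDigest(ps, SpecificityRule(), 0)
  d1 <- inSilicoDigest(ps, SpecificityRule(), 1)
  d2 <- inSilicoDigest(ps, SpecificityRule(), 2)
  expect_equal(nrow(d0), 3L)
  expect_equal(nrow(d1), 5L)
  expect_equal(nrow(d2), 6L)
  expect_equal(sort(unique(d1$n_missed)), c(0L, 1L))
  expect_true("GGAGGAGG" %in% d2$sequence)
})

test_that("monoisotopic masses match residue-table arithmetic", {
  expect_equal(peptideMass("G"), 75.03203, tolerance = 1e-5)
  expect_equal(peptideMass("GG"), 132.05349, tolerance = 1e-5)
  cam <- data.frame(position = 1, delta = 57.02146)
  expect_equal(peptideMass("C", cam), peptideMass("C") + 57.02146)
  expect_error(peptideMass(""), "non-empty")
  expect_error(peptideMass("G", data.frame(position = 2, delta = 1)),
               "out of range")
  expect_error(peptideMass("GJG"), "nonstandard")
})

test_that("peptide mass is additive up to one water (property)", {
  set.seed(17)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:30) {
    a <- paste(sample(aa, sample(1:15, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(1:15, 1), replace = TRUE), collapse = "")
    expect_equal(peptideMass(paste0(a, b)),
                 peptideMass(a) + peptideMass(b) - 18.0105646837,
                 tolerance = 1e-9)
  }
})

test_that("the noise-free simulator reduces to the deterministic digest", {
  mix <- readProteins(mixtureFasta())
  rule <- SpecificityRule(nonspecificRate = 0, acidHydrolysisAspRate = 0,
                          missedCleavageProb = 0)
  cfg <- SimConfig(nReplicates = 2L, detectionDropout = 0,
                   minDetectLength = 1L, seed = 99L)
  sim <- simulateReplicates(mix, rule, cfg)
  want <- inSilicoDigest(mix, rule, maxMissed = 0)
  obs <- observations(sim$evidence)
  for (r in c("r1", "r2")) {
    got <- obs[obs$replicate == r, ]
    expect_equal(sort(got$peptide), sort(want$sequence))
  }
  # ground truth is the rule's cleavable-site list
  expect_equal(sim$truth, cleavableSites(mix, rule))
})

test_that("simulation is seed-deterministic and respects boundary dropout", {
  mix <- readProteins(mixtureFasta())
  s1 <- simulateReplicates(mix, SpecificityRule(), SimConfig(seed = 5L))
  s2 <- simulateReplicates(mix, SpecificityRule(), SimConfig(seed = 5L))
  expect_identical(observations(s1$evidence), observations(s2$evidence))
  s3 <- simulateReplicates(mix, SpecificityRule(), SimConfig(seed = 6L))
  expect_false(identical(observations(s1$evidence),
                         observations(s3$evidence)))

  gone <- simulateReplicates(mix, SpecificityRule(),
                             SimConfig(detectionDropout = 1, seed = 5L))
  expect_equal(length(gone$evidence), 0L)
  # caller RNG state untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulateReplicates(mix, SpecificityRule(),
                                              SimConfig(seed = 5L)))
  expect_equal(runif(1), before)
})

test_that("rule-truth sites alone already show the planted P1 preference", {
  mix <- readProteins(mixtureFasta())
  rule <- SpecificityRule(nonspecificRate = 0, acidHydrolysisAspRate = 0,
                          missedCleavageProb = 0)
  truth <- cleavableSites(mix, rule)
  m <- data.frame(protein = truth$protein, start = 1L,
                  end = seqLengths(mix)[truth$protein],
                  peptide = proteinSequences(mix)[truth$protein],
                  mods = "", ambiguous = FALSE)
  m <- unique(m)
  prof <- buildProfile(truth, m, mix, "P1", "whole_proteins")
  nv <- normalizedValues(prof)
  top3 <- names(sort(nv[!is.na(nv)], decreasing = TRUE))[1:3]
  expect_setequal(top3, c("P", "A", "C"))
})

test_that("column residence time is bed volume over flow, in seconds", {
  expect_equal(residenceTime(69, 100), 41L)
  expect_equal(residenceTime(69, 200), 21L)
  expect_equal(residenceTime(100, 100), 60L)
  expect_error(residenceTime(0, 100))
  expect_error(residenceTime(69, -1))
})

test_that("synthetic test proteins are reproducible and standard-alphabet", {
  a <- makeTestProteins(n = 3, lengths = c(50, 60, 70), seed = 7)
  b <- makeTestProteins(n = 3, lengths = c(50, 60, 70), seed = 7)
  expect_identical(proteinSequences(a), proteinSequences(b))
  expect_equal(unname(seqLengths(a)), c(50L, 60L, 70L))
  expect_true(all(strsplit(paste(proteinSequences(a), collapse = ""),
                           "")[[1]] %in%
                  strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]))
})
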