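idsDf <- function(ids, proteins) {
  data.frame(id = ids, proteins = proteins, stringsAsFactors = FALSE)
}

SETS <- AccessionSets(c("TRUEP001", "TRUEP002"), c("ENTRAPP001", "ENTRAPP002"))
LAB <- TruthLabeler(SETS, "spectrum")

test_that("identifications are labelled by the shared-peptide rule", {
  ids <- idsDf(c("a", "b", "c", "d"),
               c("TRUEP001;ENTRAPP001",  # shared -> true
                 "ENTRAPP001;ENTRAPP002",  # all entrapment -> false
                 "UNKNOWN1",               # neither set -> unlabelable
                 "ENTRAPP001;UNKNOWN1"))   # mixed unknown -> unlabelable
  lab <- labelIdentifications(ids, LAB)
  expect_equal(lab$true, "a")
  expect_equal(lab$false, "b")
  expect_setequal(lab$unlabelable, c("c", "d"))
})

test_that("entrapment FDP is the false fraction among labelled hits", {
  all_true <- idsDf(sprintf("s%d", 1:10), rep("TRUEP001", 10))
  expect_equal(entrapmentFdp(all_true, LAB), 0)

  one_bad <- idsDf(sprintf("s%d", 1:100),
                   c(rep("TRUEP001", 99), "ENTRAPP001"))
  expect_equal(entrapmentFdp(one_bad, LAB), 0.01)

  # unlabelable excluded from the denominator
  with_unknown <- idsDf(sprintf("s%d", 1:4),
                        c("TRUEP001", "ENTRAPP001", "UNKNOWN1", "UNKNOWN2"))
  expect_equal(entrapmentFdp(with_unknown, LAB), 0.5)

  empty <- idsDf(character(0), character(0))
  expect_warning(fdp <- entrapmentFdp(empty, LAB), "empty")
  expect_equal(fdp, 0)
})

mkOutcome <- function(ids, proteins, alpha = 0.01, mode = "separate") {
  n <- length(ids)
  psm <- data.frame(spectrum_id = ids, peptide = strrep("A", 7),
                    charge = 2L, mass = 1000, score = seq(100, by = -1, length.out = n),
                    is_decoy = FALSE, proteins = proteins,
                    q_value = 0, accepted = TRUE, stringsAsFactors = FALSE)
  new("FdrOutcome", alpha = alpha, mode = mode, scoreColumn = "score",
      threshold = min(psm$score), psm = psm, acceptedSpectra = ids,
      acceptedPeptides = unique(normalizePeptide(psm$peptide)),
      decoysRemoved = 0L)
}

test_that("method comparison partitions unique identifications", {
  base_ids <- sprintf("s%02d", 1:6)
  base_prot <- rep("TRUEP001", 6)
  same <- compareMethods(mkOutcome(base_ids, base_prot),
                         mkOutcome(base_ids, base_prot), LAB)
  expect_equal(c(same@tp, same@fp, same@tn, same@fn), rep(0L, 4))
  expect_equal(same@common, 6L)

  plus_one <- compareMethods(mkOutcome(c(base_ids, "s99"),
                                       c(base_prot, "TRUEP002")),
                             mkOutcome(base_ids, base_prot), LAB)
  expect_equal(plus_one@tp, 1L)
  expect_equal(c(plus_one@fp, plus_one@tn, plus_one@fn), rep(0L, 3))

  expect_error(compareMethods(mkOutcome(base_ids, base_prot, alpha = 0.01),
                              mkOutcome(base_ids, base_prot, alpha = 0.05),
                              LAB),
               class = "flexifdr_config_error")
  expect_error(compareMethods(mkOutcome(base_ids, base_prot, mode = "separate"),
                              mkOutcome(base_ids, base_prot,
                                        mode = "concatenated"),
                              LAB),
               class = "flexifdr_config_error")
})

test_that("net positive gain follows its defining arithmetic", {
  rep0 <- new("EvaluationReport", tp = 10L, fp = 2L, tn = 1L, fn = 3L,
              common = 0L, unlabelable = 0L, level = "spectrum",
              alpha = 0.01, simpleTotal = 100L, flexiTotal = 100L,
              npgPercent = NA_real_, fdpSimple = 0, fdpFlexi = 0)
  expect_equal(netPositiveGain(rep0), 6)  # 100*((10-2)-(3-1))/100

  zero <- initialize(rep0, tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  expect_equal(netPositiveGain(zero), 0)

  sym <- initialize(rep0, tp = 5L, fn = 5L, fp = 2L, tn = 2L)
  expect_equal(netPositiveGain(sym), 0)

  expect_error(netPositiveGain(rep0, simpleTotal = 0),
               class = "flexifdr_config_error")
})

test_that("comparison on the fixture is complete and level-consistent", {
  gen <- defaultFixture()
  simple <- runSimpleFdr(gen$result, 0.01)
  flexi <- runFlexiFdr(gen$result, 0.01)$outcome
  for (level in c("spectrum", "peptide")) {
    lab <- truthToLabeler(gen$truth, gen$sets, level)
    rep <- compareMethods(flexi, simple, lab)
    total <- rep@tp + rep@fp + rep@tn + rep@fn + 2L * rep@common +
      rep@unlabelable
    expect_equal(total, rep@flexiTotal + rep@simpleTotal)
  }
  # every accepted peptide backs onto >= 1 accepted spectrum
  for (out in list(simple, flexi)) {
    expect_lte(length(acceptedPeptides(out)), length(acceptedSpectra(out)))
    pep_ids <- nrow(acceptedIdentifications(out, "peptide"))
    spec_ids <- nrow(acceptedIdentifications(out, "spectrum"))
    expect_lte(pep_ids, spec_ids)
  }
})

test_that("swapping the two methods swaps the unique sets exactly", {
  gen <- generatePsmData(generatorConfig(nSpectra = 400L), seed = 9L)
  simple <- runSimpleFdr(gen$result, 0.01)
  flexi <- runFlexiFdr(gen$result, 0.01)$outcome
  lab <- truthToLabeler(gen$truth, gen$sets, "spectrum")
  ab <- compareMethods(flexi, simple, lab)
  ba <- compareMethods(simple, flexi, lab)
  expect_equal(ab@tp, ba@fn)
  expect_equal(ab@fp, ba@tn)
  expect_equal(ab@tn, ba@fp)
  expect_equal(ab@fn, ba@tp)
  expect_equal(ab@common, ba@common)
})

test_that("generator truth maps onto accession labels, blind spot included", {
  gen <- generatePsmData(generatorConfig(nSpectra = 300L), seed = 3L)
  lab <- truthToLabeler(gen$truth, gen$sets, "spectrum")
  tab <- psmTable(gen$result)
  targets <- tab[!tab$is_decoy, ]
  ids <- idsDf(targets$spectrum_id, targets$proteins)
  lres <- labelIdentifications(ids, lab)
  truth <- gen$truth
  correct <- truth$spectrum_id[truth$truth == "correct_true_protein"]
  entrap <- truth$spectrum_id[truth$truth == "incorrect_entrapment"]
  blind <- truth$spectrum_id[truth$truth == "incorrect_true_protein_random"]
  expect_true(all(correct %in% lres$true))
  expect_true(all(entrap %in% lres$false))
  # incorrect hits on true proteins are invisible to the accession labeler
  expect_true(all(blind %in% lres$true))
})
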