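test_that("net charge follows the Henderson-Hasselbalch expansion", {
  pka <- defaultPkaTable()
  # hand-expanded four-term sum for DDK at pH 7
  byHand <- 1 / (1 + 10^(7 - 8.6)) +            # N-terminus
    1 / (1 + 10^(7 - 10.8)) -                   # K side chain
    1 / (1 + 10^(3.6 - 7)) -                    # C-terminus
    2 / (1 + 10^(3.9 - 7))                      # two D side chains
  expect_equal(netCharge("DDK", 7, pka), byHand, tolerance = 1e-12)
  # strictly decreasing in pH, for any sequence
  set.seed(33)
  for (aa in replicate(20, randomPeptide(sample(5:20, 1)))) {
    q <- netCharge(aa, seq(0, 14, by = 0.5), pka)
    expect_true(all(diff(q) < 0))
  }
  # far below every pKa a side-chain-free peptide approaches +1
  expect_equal(netCharge("GG", -3), 1, tolerance = 1e-3)
  expect_error(netCharge("GXG", 7), "X")
  expect_error(isoelectricPoint("GBG"), "B")
})

test_that("bisection pI recovers the two-group closed form and the grid root", {
  pka <- defaultPkaTable()
  expect_equal(isoelectricPoint("GG", tol = 1e-8)$pI,
               (pka[["N_terminus"]] + pka[["C_terminus"]]) / 2,
               tolerance = 1e-3)
  set.seed(44)
  for (aa in replicate(25, randomPeptide(sample(6:18, 1)))) {
    expect_equal(isoelectricPoint(aa, tol = 1e-8)$pI, oracleGridPI(aa),
                 tolerance = 1e-3)
  }
})

test_that("acid and base perturbations move pI the expected way", {
  set.seed(55)
  for (aa in replicate(15, randomPeptide(sample(6:15, 1)))) {
    base <- isoelectricPoint(aa, tol = 1e-8)$pI
    expect_lte(isoelectricPoint(paste0(aa, "D"), tol = 1e-8)$pI, base + 1e-6)
    expect_gte(isoelectricPoint(paste0(aa, "K"), tol = 1e-8)$pI, base - 1e-6)
  }
})

test_that("residue composition counts property-group occurrences", {
  comp <- residueComposition("CASSF")
  get <- function(g) comp[comp$group == g, ]
  expect_equal(get("Sulphur")$times_found, 1)
  expect_equal(get("Sulphur")$percentage, 20)
  expect_equal(attr(comp, "total_residues"), 5)
  # the synthetase classes partition every residue: percentages sum to 100
  set.seed(66)
  peps <- replicate(10, randomPeptide(sample(5:20, 1)))
  comp2 <- residueComposition(peps)
  expect_equal(sum(comp2$percentage[grepl("class", comp2$group)]), 100)
  # the six physicochemical groups cover everything except proline
  pP <- 100 * sum(vapply(strsplit(peps, ""), function(r) sum(r == "P"),
                         numeric(1))) / attr(comp2, "total_residues")
  expect_equal(sum(comp2$percentage[!grepl("class", comp2$group)]), 100 - pP)
  # counts are additive across disjoint peptide sets
  c1 <- residueComposition(peps[1:4])
  c2 <- residueComposition(peps[5:10])
  expect_equal(comp2$times_found, c1$times_found + c2$times_found)
  expect_error(residueComposition("CAX"), "X")
})

test_that("cohort-level pI and composition tables cover samples and groups", {
  sim <- simulateCohort(simulationConfig(
    nSamples = c(ARDS = 2L, non_ARDS = 1L),
    cloneRange = list(ARDS = c(30L, 40L), non_ARDS = c(25L, 30L)),
    seed = 9))
  coh <- translateRepertoire(sim$cohort, verbose = FALSE)
  pi <- cohortIsoelectricPoints(coh)
  expect_true(all(pi$pI > 0 & pi$pI < 14))
  expect_setequal(unique(pi$sample_id), sampleIds(coh))
  comp <- cohortComposition(coh)
  expect_setequal(comp$id[comp$level == "group"], c("ARDS", "non_ARDS"))
  expect_setequal(comp$id[comp$level == "sample"], sampleIds(coh))
})
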