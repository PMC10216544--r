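smallConfig <- function(seed, ...) {
  simulationConfig(
    nSamples = c(ARDS = 4L, non_ARDS = 3L),
    cloneRange = list(ARDS = c(40L, 80L), non_ARDS = c(25L, 40L),
                      unlabeled = c(25L, 80L)),
    seed = seed, ...)
}

test_that("the generator is fully reproducible from its seed", {
  a <- simulateCohort(smallConfig(31))
  b <- simulateCohort(smallConfig(31))
  for (s in sampleIds(a$cohort)) {
    expect_equal(as.data.frame(rearrangements(a$cohort[[s]])),
                 as.data.frame(rearrangements(b$cohort[[s]])))
  }
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- exportCohort(a$cohort, d1)
  f2 <- exportCohort(b$cohort, d2)
  expect_identical(readLines(f1[["rearrangements"]]),
                   readLines(f2[["rearrangements"]]))
  expect_error(simulationConfig(), "seed")
})

test_that("productive junctions have in-frame lengths and C...F anchors", {
  sim <- simulateCohort(smallConfig(32))
  for (s in sampleIds(sim$cohort)) {
    df <- rearrangements(translateRepertoire(sim$cohort[[s]],
                                             verbose = FALSE))
    prod <- df[df$productive, ]
    expect_true(all(nchar(prod$cdr3_nt) %% 3L == 0L))
    expect_true(all(nchar(prod$cdr3_nt) >= 21L &
                      nchar(prod$cdr3_nt) <= 69L))
    expect_true(all(substr(prod$cdr3_aa, 1, 1) == "C"))
    expect_true(all(substr(prod$cdr3_aa, nchar(prod$cdr3_aa),
                           nchar(prod$cdr3_aa)) == "F"))
  }
})

test_that("the nonproductive fraction is realized and recoverable", {
  cfg <- simulationConfig(seed = 33, nonproductiveFraction = 0.1)
  rep <- simulateRepertoire(cfg, "s", "ARDS", nClones = 1000)
  truth <- attr(rep, "truth")
  expect_equal(mean(!truth$productive_truth), 0.1, tolerance = 0.001)
  # classifier recovers the generated labels
  called <- classifyProductive(
    CDR3Repertoire("s", truth$cdr3_nt, templates = 1L))
  expect_equal(called, truth$productive_truth)
})

test_that("the default preset emits 4+3 samples with the planted sharing", {
  sim <- simulateCohort(smallConfig(34))
  expect_equal(length(sim$cohort), 7L)
  expect_equal(as.vector(table(groupLabels(sim$cohort))[c("ARDS", "non_ARDS")]),
               c(4L, 3L))
  rep <- sharedClones(sim$cohort)
  expect_equal(sort(rep$sequence), sort(sim$truth$shared$cdr3_aa))
  expect_equal(attr(rep, "n_within_group"), 4L)
  expect_equal(attr(rep, "n_between_group"), 1L)
  within <- rep[rep$sharing == "within_group", ]
  expect_true(all(within$samples == "A2,A3,A4"))
  expect_equal(rep$samples[rep$sharing == "between_group"], "A3,N3")
})

test_that("clonality regimes follow the concentration parameter", {
  cfg <- simulationConfig(seed = 35, alpha = 1e6)
  even <- simulateRepertoire(cfg, "s", "unlabeled", nClones = 10000)
  expect_lt(cohortClonality(CDR3Cohort(list(even)))$clonality, 0.05)
  cfgSkew <- simulationConfig(seed = 36, alpha = 0.02)
  skew <- simulateRepertoire(cfgSkew, "s", "unlabeled", nClones = 200)
  cl <- cohortClonality(CDR3Cohort(list(skew)))$clonality
  expect_gt(cl, 0.2)
  expect_lte(cl, 1)
})

test_that("infeasible configurations are rejected", {
  cfg <- smallConfig(37, sharedPlan = list(list(n = 50L, samples = c("N1"))))
  expect_error(simulateCohort(cfg), "budget")
  badPlan <- smallConfig(38, sharedPlan = list(list(n = 1L, samples = "Z9")))
  expect_error(simulateCohort(badPlan), "unknown sample")
  expect_error(simulationConfig(seed = 1, nonproductiveFraction = 1), ">=|<")
  expect_error(simulationConfig(seed = 1, lengthRange = list(
    ARDS = c(20L, 60L), non_ARDS = c(30L, 66L), unlabeled = c(21L, 69L))),
    "multiples")
})

test_that("power-law mode produces valid skewed repertoires", {
  cfg <- simulationConfig(seed = 39, model = "powerlaw",
                          powerlawExponent = 1.5)
  rep <- simulateRepertoire(cfg, "s", "unlabeled", nClones = 300)
  f <- cloneFrequencies(rep, productiveOnly = FALSE)
  expect_equal(sum(f$frequency), 1, tolerance = 1e-12)
  expect_gt(cohortClonality(CDR3Cohort(list(rep)),
                            productiveOnly = FALSE)$clonality,
            1 / sqrt(300))
})
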