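test_that("the packaged model is complete and anchor-masked", {
  m <- defaultImmunogenicityModel()
  expect_setequal(names(m@enrichment),
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(m@importance[c(1, 2, 9)], c(0, 0, 0))
  expect_true(all(m@importance[4:6] > 0))
})

test_that("whole-peptide scores equal an independent summation oracle", {
  set.seed(88)
  peps <- c(replicate(30, randomPeptide(sample(3:20, 1))), "CASSLGQAYEQYF")
  for (aa in peps) {
    expect_equal(scorePeptide(aa)$score, unname(oracleImmunoScore(aa)),
                 tolerance = 1e-12)
  }
})

test_that("mask semantics: anchor positions never influence the score", {
  set.seed(89)
  aa <- randomPeptide(12)
  s0 <- scorePeptide(aa)$score
  for (repl in setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       substr(aa, 1, 1))) {
    mut <- paste0(repl, substr(aa, 2, 12))
    expect_equal(scorePeptide(mut)$score, s0)
  }
  lastMut <- paste0(substr(aa, 1, 11), "W")
  expect_equal(scorePeptide(lastMut)$score, s0)
  expect_error(scorePeptide("CA"), "shorter than 3")
  expect_error(scorePeptide("CAX"), "X")
})

test_that("an all-zero enrichment table scores everything non-positive", {
  zero <- ImmunogenicityModel(
    setNames(rep(0, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
    importance = c(0, 0, .1, .3, .3, .3, .25, .2, 0))
  set.seed(90)
  peps <- replicate(20, randomPeptide(sample(4:15, 1)))
  scores <- vapply(peps, function(a) scorePeptide(a, zero)$score, numeric(1))
  expect_true(all(scores == 0))
  calls <- vapply(peps, function(a) scorePeptide(a, zero)$positive,
                  logical(1))
  expect_equal(summarizeImmunogenicity(calls, "z")$percent_positive, 0)
})

test_that("sliding 9-mer mode takes the maximum window score", {
  set.seed(91)
  aa <- randomPeptide(15)
  windows <- vapply(1:7, function(i)
    scorePeptide(substr(aa, i, i + 8))$score, numeric(1))
  expect_equal(scorePeptide(aa, mode = "max9")$score, max(windows))
  short <- randomPeptide(8)
  expect_equal(scorePeptide(short, mode = "max9")$score,
               scorePeptide(short)$score)
})

test_that("percent positive is exact sample arithmetic, order-invariant", {
  calls <- c(rep(TRUE, 7), rep(FALSE, 18))   # 7 of 25
  s <- summarizeImmunogenicity(calls, "s158")
  expect_equal(s$positive_count, 7)
  expect_equal(s$percent_positive, 28.00)
  set.seed(92)
  expect_equal(summarizeImmunogenicity(sample(calls), "x")$percent_positive,
               s$percent_positive)
})

test_that("cohort scoring summarizes per sample and supports variance tests", {
  sim <- simulateCohort(simulationConfig(
    nSamples = c(ARDS = 2L, non_ARDS = 2L),
    cloneRange = list(ARDS = c(40L, 50L), non_ARDS = c(30L, 40L)),
    seed = 13))
  im <- cohortImmunogenicity(sim$cohort)
  expect_setequal(im$summary$sample_id, sampleIds(sim$cohort))
  expect_equal(im$summary$percent_positive,
               round(100 * im$summary$positive_count /
                       im$summary$total_count, 2))
  vt <- immunogenicityVarianceTest(im$scores)
  expect_s3_class(vt, "htest")
  expect_true(vt$p.value >= 0 && vt$p.value <= 1)
})
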