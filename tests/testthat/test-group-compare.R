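test_that("Dunn statistic matches hand-computed rank arithmetic, no ties", {
  res <- dunnsTest(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  z <- (2 - 5) / sqrt((6 * 7 / 12) * (1 / 3 + 1 / 3))
  expect_equal(res$z, z, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("identical group data give z = 0, p = 1; swapping labels flips z", {
  same <- dunnsTest(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  x <- c(1.2, 3.4, 2.2, 0.4)
  y <- c(5.5, 2.0, 7.1)
  ab <- dunnsTest(list(a = x, b = y))
  ba <- dunnsTest(list(a = y, b = x))
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
})

test_that("degenerate and invalid inputs are refused or flagged", {
  expect_error(dunnsTest(list(a = numeric(), b = 1:3)), "zero observations")
  expect_error(dunnsTest(list(a = 1:3)), "two groups")
  expect_warning(flat <- dunnsTest(list(a = c(2, 2), b = c(2, 2))),
                 "undefined")
  expect_true(all(is.na(flat$z)))
})

test_that("z and p match the brute-force oracle on random data with ties", {
  set.seed(140)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    obs <- lapply(seq_len(k), function(j) {
      n <- sample(4:12, 1)
      if (i %% 2) round(rnorm(n), 1) else rnorm(n)  # every other set tied
    })
    names(obs) <- paste0("g", seq_len(k))
    got <- dunnsTest(obs)
    want <- oracleDunnAll(obs)
    expect_equal(got$z, want$z, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("ranks make the test invariant to monotone transformations", {
  set.seed(141)
  obs <- list(a = rexp(10), b = rexp(12), c = rexp(8))
  raw <- dunnsTest(obs)
  logd <- dunnsTest(lapply(obs, log))
  expect_equal(raw$z, logd$z)
  expect_equal(raw$p, logd$p)
})

test_that("multiplicity adjustment is applied across the pairs", {
  set.seed(142)
  obs <- list(a = rnorm(8), b = rnorm(8, 2), c = rnorm(8, 4))
  bon <- dunnsTest(obs, adjust = "bonferroni")
  expect_equal(bon$p_adjusted, pmin(1, bon$p * 3))
  none <- dunnsTest(obs)
  expect_equal(none$p_adjusted, none$p)
})

test_that("the clone-frequency preset compares samples of a cohort", {
  sim <- simulateCohort(simulationConfig(
    nSamples = c(ARDS = 2L, non_ARDS = 2L),
    cloneRange = list(ARDS = c(40L, 60L), non_ARDS = c(25L, 40L)),
    seed = 17))
  res <- cloneFrequencyComparison(sim$cohort)
  expect_equal(nrow(res), choose(4, 2))
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
})
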