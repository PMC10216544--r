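repOfLengths <- function(lens, templates = 1L, sampleId = "s1") {
  set.seed(sum(lens) + 7L)
  nts <- vapply(lens, randomJunction, character(1))
  while (anyDuplicated(nts)) {
    nts[duplicated(nts)] <- vapply(lens[duplicated(nts)], randomJunction,
                                   character(1))
  }
  CDR3Repertoire(sampleId, nts, templates)
}

test_that("per-length frequencies are normalized productive template shares", {
  two45 <- repOfLengths(c(45, 45), templates = c(3L, 1L))
  d <- lengthDistribution(two45)
  expect_equal(as.data.frame(d),
               data.frame(length = 45L, sum_productive_frequency = 1,
                          unique_count = 2L))
  d2 <- lengthDistribution(repOfLengths(c(42, 48), templates = c(1L, 3L)))
  expect_equal(d2$sum_productive_frequency, c(0.25, 0.75))
  # invariant under uniform template scaling
  d3 <- lengthDistribution(repOfLengths(c(42, 48), templates = c(10L, 30L)))
  expect_equal(d2$sum_productive_frequency, d3$sum_productive_frequency)
})

test_that("nonproductive records never contribute to the distribution", {
  rep <- CDR3Repertoire("s1", c("TGTGCCAGCAGTTTT", "TGTTAAAGCTTTTTT"),
                        templates = c(1L, 99L))
  d <- lengthDistribution(rep)
  expect_equal(d$sum_productive_frequency, 1)
  expect_equal(d$unique_count, 1L)
  allBad <- CDR3Repertoire("s2", "TGTTAAAGCTTTTTT", 5L)
  expect_warning(d0 <- lengthDistribution(allBad), "no productive")
  expect_equal(nrow(d0), 0L)
})

test_that("merging repertoires mixes their distributions by template mass", {
  a <- repOfLengths(c(42, 45), templates = c(2L, 2L))
  b <- repOfLengths(c(45, 48), templates = c(4L, 4L), sampleId = "s2")
  merged <- CDR3Repertoire("m", c(rearrangements(a)$cdr3_nt,
                                  rearrangements(b)$cdr3_nt),
                           c(rearrangements(a)$templates,
                             rearrangements(b)$templates))
  dm <- lengthDistribution(merged)
  da <- lengthDistribution(a)
  db <- lengthDistribution(b)
  mix <- c(`42` = 4 / 12 * da$sum_productive_frequency[1],
           `45` = 4 / 12 * da$sum_productive_frequency[2] +
                  8 / 12 * db$sum_productive_frequency[1],
           `48` = 8 / 12 * db$sum_productive_frequency[2])
  expect_equal(dm$sum_productive_frequency, unname(mix))
})

test_that("weighted moments match a brute-force computation on raw draws", {
  set.seed(202)
  support <- seq(21, 69, by = 3)
  probs <- prop.table(runif(length(support)))
  draws <- sample(support, 1000, replace = TRUE, prob = probs)
  rep <- repOfLengths(draws)
  s <- lengthSummary(lengthDistribution(rep), weighted = FALSE)
  m <- mean(draws)
  v <- mean((draws - m)^2)
  expect_equal(s$mean, m, tolerance = 1e-12)
  expect_equal(s$variance, v, tolerance = 1e-12)
  expect_equal(s$skewness, mean((draws - m)^3) / v^1.5, tolerance = 1e-12)
  expect_equal(s$kurtosis, mean((draws - m)^4) / v^2 - 3, tolerance = 1e-12)
})

test_that("degenerate and symmetric distributions give analytic moments", {
  one <- lengthDistribution(repOfLengths(c(45, 45), c(1L, 5L)))
  expect_warning(s1 <- lengthSummary(one), "undefined")
  expect_equal(s1$mean, 45)
  expect_equal(s1$variance, 0)
  expect_true(is.nan(s1$skewness) && is.nan(s1$kurtosis))
  sym <- lengthSummary(lengthDistribution(
    repOfLengths(c(30, 60), c(2L, 2L))))
  expect_equal(sym$mean, 45)
  expect_equal(sym$skewness, 0)
})

test_that("a non-ARDS-like simulated sample keeps nt lengths within 30-66", {
  cfg <- simulationConfig(seed = 5)
  rep <- simulateRepertoire(cfg, "n1", "non_ARDS", nClones = 120)
  d <- lengthDistribution(rep, scale = "nt")
  expect_gte(S4Vectors::metadata(d)$min_length, 30L)
  expect_lte(S4Vectors::metadata(d)$max_length, 66L)
  # aa scale is nt scale over three
  da <- lengthDistribution(rep, scale = "aa")
  expect_equal(sort(unique(da$length)), sort(unique(d$length %/% 3L)))
})
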