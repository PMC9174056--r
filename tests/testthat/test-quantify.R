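test_that("per-neuron metrics count and average by class", {
  calls <- data.frame(
    neuron_id = 1L,
    klass = c("paAL", "paAL", "paAL", "AL", "AL"),
    area_um2 = c(1, 1.2, 1.4, 0.6, 0.8),
    abeta_pos = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    pla_pos = FALSE)
  m <- perNeuronMetrics(calls)
  expect_equal(m$n_paAL, 3)
  expect_equal(m$n_AL, 2)
  expect_equal(m$area_paAL, 1.2)
  expect_equal(m$n_abeta, 3)
  expect_equal(m$frac_abeta_paAL, 2 / 3)
  # 8 of 9 amyloid-positive puncta in pa-AL
  calls2 <- data.frame(neuron_id = 2L,
                       klass = c(rep("paAL", 8), "AL"),
                       area_um2 = 1, abeta_pos = TRUE, pla_pos = FALSE)
  m2 <- perNeuronMetrics(calls2)
  expect_equal(round(m2$frac_abeta_paAL, 3), 0.889)
  # empty neuron: all-zero row
  m3 <- perNeuronMetrics(calls, neuronIds = 1:3)
  expect_equal(m3$n_paAL, c(3, 0, 0))
  # conservation: class counts plus unclassified equal total puncta
  expect_equal(m$n_AP + m$n_AL + m$n_paAL + m$n_LY + m$n_unclassified,
               nrow(calls))
})

test_that("group summary reports mean and sample-sd based s.e.m.", {
  expect_equal(groupSummary(c(2, 2, 2)), list(mean = 2, sem = 0, n = 3))
  gs <- groupSummary(c(1, 2, 3))
  expect_equal(gs$mean, 2)
  expect_equal(gs$sem, 1 / sqrt(3), tolerance = 1e-9)  # sd = 1
  expect_equal(round(gs$sem, 4), 0.5774)
  expect_error(groupSummary(numeric(0)), "at least one")
})

test_that("s.e.m. shrinks as one over sqrt(n) on resampled synthetic counts", {
  set.seed(20)
  pop <- rpois(4000, 9)
  sems <- vapply(c(100, 400, 1600), function(n) {
    groupSummary(pop[seq_len(n)])$sem
  }, 0)
  # ratios approximate 1/2 at each 4-fold increase of n
  expect_equal(sems[2] / sems[1], 0.5, tolerance = 0.2)
  expect_equal(sems[3] / sems[2], 0.5, tolerance = 0.2)
})

test_that("the pooled t-test matches hand computation and stats::t.test", {
  tt <- unpairedTTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1.224745, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.2878641, tolerance = 1e-6)
  # identical groups: t = 0, p = 1
  t0 <- unpairedTTest(c(5, 5, 6), c(5, 5, 6))
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)
  # degenerate zero variance, unequal means
  td <- unpairedTTest(c(1, 1), c(2, 2))
  expect_equal(td$p, 0)
  expect_true(td$degenerate)
  # cross-check against the reference implementation on random draws
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), mean = 0.5)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    got <- unpairedTTest(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the t-test agrees with a permutation oracle on small groups", {
  set.seed(22)
  a <- c(3.1, 4.5, 2.2, 5.0, 3.7)
  b <- c(5.2, 6.1, 4.9, 5.8, 6.5)
  got <- unpairedTTest(a, b)
  pool <- c(a, b)
  nperm <- 20000
  obs <- abs(mean(a) - mean(b))
  hits <- vapply(seq_len(nperm), function(i) {
    idx <- sample(10, 5)
    abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12
  }, TRUE)
  pPerm <- mean(hits)
  # Monte-Carlo error ~ 3 sqrt(p(1-p)/nperm); permutation p of a location
  # shift tracks the pooled-t p at these n
  expect_lt(abs(got$p - pPerm), 3 * sqrt(pPerm * (1 - pPerm) / nperm) + 0.01)
})

test_that("colocalization fractions pool and average as documented", {
  calls <- data.frame(
    neuron_id = rep(1:2, each = 3),
    klass = c("paAL", "paAL", "AL", "paAL", "AL", "LY"),
    area_um2 = 1,
    abeta_pos = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    pla_pos = FALSE)
  cf <- colocalizationFractions(calls, "abeta")
  expect_equal(unname(cf$pooled["paAL"]), 1)
  expect_equal(cf$perNeuron$paAL$mean, 1)
  expect_equal(cf$nPositive, 3)
  none <- colocalizationFractions(
    transform(calls, abeta_pos = FALSE), "abeta")
  expect_equal(none$nPositive, 0)
  expect_match(none$flag, "no marker-positive")
})
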