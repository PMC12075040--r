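test_that("NARMA generator matches hand iteration and the fixed point", {
  # zero input: y1 = 0.1, y2 = 0.3*0.1 + 0.05*0.1*0.1 + 0.1 = 0.1305
  y <- numeric(60)
  y[1] <- 0.1
  for (t in 1:59) {
    y[t + 1] <- 0.3 * y[t] + 0.05 * y[t] * sum(y[max(1, t - 9):t]) + 0.1
  }
  expect_equal(y[2], 0.1305)
  # stable root of 0.5 y^2 - 0.7 y + 0.1 = 0
  expect_equal(y[60], 0.7 - sqrt(0.29), tolerance = 1e-6)
})

test_that("NARMA series match an independent reference step for step", {
  ser <- narma10_series(300, seed = 5)
  expect_equal(ser$output, brute_narma10(ser$input))
  expect_true(all(ser$input >= 0 & ser$input <= 0.5))
  expect_identical(narma10_series(300, seed = 5), narma10_series(300, seed = 5))
  expect_equal(ser$output[1], 0.1)
})

test_that("memory coefficient is the squared correlation, bounded in [0,1]", {
  set.seed(1)
  u <- runif(500, -1, 1)
  expect_equal(memory_coefficient(u, u), 1)          # oracle delayed output
  expect_equal(memory_coefficient(2 * u + 3, u), 1)  # affine invariance
  expect_lt(memory_coefficient(runif(1000, -1, 1), runif(1000, -1, 1)), 0.05)
  expect_warning(mc0 <- memory_coefficient(rep(1, 10), runif(10)),
                 "zero-variance")
  expect_equal(mc0, 0)
})

test_that("critical_k takes the largest crossing, not the first", {
  expect_equal(critical_k(c(0.9, 0.8, 0.6, 0.4, 0.7, 0.3)), 5L)
  expect_equal(critical_k(c(0.9, 0.8, 0.6, 0.4, 0.7, 0.3), rule = "first"), 3L)
  expect_equal(critical_k(c(0.4, 0.3, 0.2)), 0L)
  expect_equal(critical_k(c(0.9, 0.9)), 2L)
  # extending the scan can only raise k*
  mc <- c(0.9, 0.6, 0.3, 0.8, 0.2)
  expect_gte(critical_k(mc), critical_k(mc[1:3]))
})

test_that("a delay-chain reservoir holds memory over several delays", {
  # feed the chain head only, so downstream nodes act as pure delay stages
  sys <- build_reservoir(delay_chain(10), rho = 0.9, seed = 1,
                         input_nodes = "v1")
  prot <- task_protocol(n_series = 6, series_length = 500, n_train = 5,
                        washout = 50, seed = 2)
  r <- critical_memory_capacity(sys, k_max = 15, protocol = prot)
  expect_true(all(r$details$profile >= 0 & r$details$profile <= 1))
  expect_gt(r$details$profile[3], 0.5)
  expect_gte(r$score, 4)
  expect_lte(r$score, 12)

  mc5 <- memory_capacity_at_k(sys, k = 5, protocol = prot)
  expect_equal(mc5$score, r$details$profile[5])
})

test_that("pulse trains have exact pulse shape and refractory spacing", {
  expect_equal(pulse_train(rate = 0, seed = 1), integer(600))
  for (seed in 1:5) {
    x <- pulse_train(600, pulse_duration = 3, rate = 0.05, seed = seed)
    runs <- rle(x)
    expect_true(all(runs$lengths[runs$values == 1] == 3))
    onsets <- which(x == 1 & c(0L, x[-600]) == 0L)
    if (length(onsets) > 1) expect_true(all(diff(onsets) >= 9))
  }
  counts <- vapply(1:40, function(s) {
    sum(rle(pulse_train(600, 3, 0.02, s))$values == 1)
  }, numeric(1))
  expect_gt(mean(counts), 5)   # thinned-Bernoulli expectation ~ 10
  expect_lt(mean(counts), 15)
})

test_that("delayed AND target equals brute-force evaluation", {
  I1 <- integer(30); I1[10:12] <- 1L
  I2 <- integer(30); I2[16:18] <- 1L
  tgt <- delayed_and_target(I1, I2, k = 6)
  expect_equal(which(tgt == 1L), 16:18)
  expect_equal(delayed_and_target(I1, integer(30), 6), integer(30))
  expect_equal(delayed_and_target(I1, I1, 0), I1)
  for (seed in 1:5) {
    set.seed(seed)
    a <- rbinom(50, 1, 0.3); b <- rbinom(50, 1, 0.3)
    k <- sample(0:8, 1)
    expect_equal(delayed_and_target(a, b, k), brute_delayed_and(a, b, k))
  }
})

test_that("binary NRMSE closed form holds for the all-zero predictor", {
  set.seed(2)
  tgt <- rbinom(400, 1, 0.15)
  p <- mean(tgt)
  expect_equal(nrmse(numeric(400), tgt), 1 / sqrt(1 - p))
})

test_that("the delayed AND task is learnable by a full surrogate reservoir", {
  g <- ecoli_core_surrogate(seed = 5)
  sys <- build_reservoir(g, 0.95, n_inputs = 2, seed = 1)
  prot <- task_protocol(n_series = 6, series_length = 600, n_train = 5,
                        washout = 100, seed = 3)
  r <- delayed_and_task(sys, prot)
  expect_lt(r$score, 1)  # beats the constant predictor
  expect_error(delayed_and_task(build_reservoir(g, 0.95, seed = 1), prot),
               "two-input")
})

test_that("NARMA task scores a surrogate reservoir believably", {
  g <- ecoli_core_surrogate(seed = 5)
  sys <- build_reservoir(g, 0.95, seed = 1)
  prot <- task_protocol(n_series = 5, series_length = 600, n_train = 4,
                        washout = 100, seed = 4)
  r <- narma10_task(sys, prot)
  expect_gt(r$score, 0)
  expect_lt(r$score, 1)
  # determinism of the full task
  expect_equal(narma10_task(sys, prot)$score, r$score)
})
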