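paper_bins <- binning_scheme(c(0.1, 0.5, 0.9))

test_that("the confidence surface is a symmetric, calibrated posterior", {
  obs <- second_order_observer(1, 1, 5)
  bg <- expand.grid(beta = seq(-6, 6, by = 1.5), gamma = seq(-8, 8, by = 2))
  cp <- confidence_surface(obs, +1, bg$beta, bg$gamma)
  cm <- confidence_surface(obs, -1, -bg$beta, -bg$gamma)
  expect_equal(cp, cm, tolerance = 1e-12)
  expect_true(all(cp > 0 & cp < 1))
  # overwhelming evidence for the chosen action
  expect_gt(confidence_surface(obs, -1, -30, -30), 1 - 1e-6)
  expect_lt(confidence_surface(obs, -1, 30, 30), 1e-4)
  # calibration: trials rated ~50% are right about half the time
  sim <- simulate(obs, nsim = 2e5, seed = 14)
  mid <- sim$confidence >= 0.45 & sim$confidence <= 0.55 &
    sim$response == -1
  acc <- mean(sim$accuracy[mid])
  se <- sqrt(0.25 / sum(mid))
  expect_lt(abs(acc - 0.5), 4 * se + 0.05)
})

test_that("expected bin statistics integrate to the known marginals", {
  obs <- second_order_observer(1, 1, 5)
  one <- expected_bin_stats(obs, binning_scheme(numeric()))
  expect_equal(one$mass, 1, tolerance = 1e-6)
  expect_equal(one$accuracy, accuracy_from_dprime(1), tolerance = 1e-3)
  st <- expected_bin_stats(obs, paper_bins)
  expect_equal(sum(st$mass), 1, tolerance = 1e-6)
  expect_true(all(st$accuracy >= 0 & st$accuracy <= 1))
  expect_equal(sum(st$mass * st$accuracy), accuracy_from_dprime(1),
               tolerance = 1e-3)
  # an inadequate grid is reported, not silently accepted
  expect_error(expected_bin_stats(obs, paper_bins, span = 1.2),
               "mass deficit")
})

test_that("per-bin conditional entropies match the reference cases", {
  st5 <- expected_bin_stats(second_order_observer(1, 1, 5), paper_bins)
  expect_equal(binary_entropy(st5$accuracy), c(0.42, 0.95, 0.84, 0.34),
               tolerance = 0.03)
  st05 <- expected_bin_stats(second_order_observer(1, 1, 0.5), paper_bins)
  expect_equal(binary_entropy(st05$accuracy), c(0.15, 0.84, 0.82, 0.11),
               tolerance = 0.01)
})

test_that("exact measures reproduce the two reference parameterizations", {
  m5 <- exact_measures(second_order_observer(1, 1, 5), paper_bins)
  expect_lt(abs(m5$H2_r - 0.89), 0.005)
  expect_lt(abs(m5$meta_I - 0.104), 0.005)
  expect_lt(abs(m5$meta_I1r - 2), 0.05)
  expect_lt(abs(m5$meta_I2r - 0.12), 0.01)
  m05 <- exact_measures(second_order_observer(1, 1, 0.5), paper_bins)
  expect_lt(abs(m05$H2_r_given_c - 0.27), 0.005)
  expect_lt(abs(m05$meta_I - 0.62), 0.005)
  expect_lt(abs(m05$meta_I1r - 12), 0.2)
  expect_lt(abs(m05$meta_I2r - 0.7), 0.01)
  # evenly spaced bins move the two cases in opposite directions
  even4 <- even_thresholds(4)
  expect_lt(abs(exact_measures(second_order_observer(1, 1, 5),
                               even4)$meta_I - 0.12), 0.005)
  expect_lt(abs(exact_measures(second_order_observer(1, 1, 0.5),
                               even4)$meta_I - 0.60), 0.005)
})

test_that("measures are identical for both actions", {
  obs <- second_order_observer(1.3, 1, 0.8)
  mm <- exact_measures(obs, paper_bins, a = -1)
  mp <- exact_measures(obs, paper_bins, a = +1)
  expect_equal(mm$meta_I, mp$meta_I, tolerance = 1e-9)
  expect_equal(mm$bin_stats$mass, mp$bin_stats$mass, tolerance = 1e-9)
})

test_that("simulation is seed-reproducible and matches the quadrature", {
  obs <- second_order_observer(1, 1, 0.5)
  s1 <- simulate(obs, nsim = 500, seed = 99)
  s2 <- simulate(obs, nsim = 500, seed = 99)
  expect_identical(s1, s2)
  big <- simulate(obs, nsim = 1e5, seed = 100)
  acc <- accuracy_from_dprime(1)
  expect_lt(abs(mean(big$accuracy) - acc),
            3 * sqrt(acc * (1 - acc) / 1e5))
  # sampled response-specific meta-I against the exact value
  mi_mc <- meta_I(joint_from_trials(big[big$response == -1, ], paper_bins))
  expect_equal(mi_mc, exact_measures(obs, paper_bins)$meta_I,
               tolerance = 0.015)
})

test_that("a sweep over the parameter grid shows the expected structure", {
  sw <- sweep_measures(c(0.5, 1, 2), c(0.1, 1, 10), b = 4,
                       n_nodes = 301, seed = 6)
  # meta-I2r nearly flat in d' when the rater's own signal dominates
  low <- sw[sw$g2 == 0.1, ]
  expect_lt(sd(low$meta_I2r) / mean(low$meta_I2r), 0.10)
  # more unique-signal noise, less information, at every d'
  for (dp in c(0.5, 1, 2)) {
    mi <- sw$meta_I[sw$d_prime == dp][order(sw$g2[sw$d_prime == dp])]
    expect_true(all(diff(mi) < 0))
  }
})

test_that("model-surface granularity gains are never harmful", {
  obs <- second_order_observer(1, 1, 1)
  o2 <- optimize_thresholds(obs, 2, n_nodes = 301, seed = 8)
  o4 <- optimize_thresholds(obs, 4, n_nodes = 301, seed = 8)
  o16 <- optimize_thresholds(obs, 16, n_nodes = 301, seed = 8)
  expect_gte(o4$meta_I, o2$meta_I - 1e-9)
  expect_gte(o16$meta_I, o4$meta_I - 1e-9)
})

test_that("the read-out-only limit recovers the first-order rater", {
  # B -> 0 with vacuous unique signal: the rater sees what the actor saw
  obs <- second_order_observer(1, b_noise = 0, g2 = 1e6)
  op <- optimize_thresholds(obs, 16, seed = 2, n_nodes = 601)
  m <- exact_measures(obs, op$scheme, n_nodes = 601)
  expect_equal(m$meta_I1r, 1, tolerance = 0.05)
})
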