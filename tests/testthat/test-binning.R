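test_that("bin assignment follows the half-open boundary convention", {
  sch <- binning_scheme(0.72, c(0.5, 1))
  expect_equal(assign_bins(0.72, sch), 2L)   # boundary goes up
  expect_equal(assign_bins(0.7199, sch), 1L)
  sch4 <- binning_scheme(c(0.1, 0.5, 0.9))
  expect_equal(assign_bins(c(0.05, 0.1, 0.49, 0.5, 0.95, 1), sch4),
               c(1L, 2L, 2L, 3L, 4L, 4L))
  expect_error(assign_bins(1.1, sch4), "outside")
  expect_error(assign_bins(0.4, sch), "outside")
  # schemes validate their thresholds
  expect_error(binning_scheme(c(0.5, 0.5)), "increasing")
  expect_error(binning_scheme(c(0, 0.5)), "inside")
})

test_that("even thresholds split the range uniformly", {
  expect_equal(even_thresholds(4)$thresholds, c(0.25, 0.5, 0.75))
  expect_equal(even_thresholds(2, c(0.5, 1))$thresholds, 0.75)
  expect_equal(even_thresholds(10)$thresholds, seq(0.1, 0.9, by = 0.1))
  expect_error(even_thresholds(1), ">= 2")
})

test_that("two-bin optimization agrees with an exhaustive scan", {
  obs <- second_order_observer(1, 1, 0.5)
  sim <- simulate(obs, nsim = 150, seed = 41)   # <= 200 distinct values
  expect_lte(length(unique(sim$confidence)), 200)
  opt <- optimize_thresholds(sim, b = 2)
  ref <- best_split_exhaustive(sim$accuracy, sim$confidence)
  expect_equal(opt$meta_I, ref$meta_I, tolerance = 1e-12)
  expect_equal(opt$scheme$thresholds, ref$threshold, tolerance = 1e-12)
  # returned objective equals meta-I of the returned scheme
  expect_equal(opt$meta_I, meta_I(joint_from_trials(sim, opt$scheme)))
})

test_that("a step in accuracy is found as the optimal threshold", {
  set.seed(5)
  cf <- runif(400)
  r <- as.integer(cf > 0.7)
  stim <- rep(1L, 400)
  resp <- ifelse(r == 1, 1L, -1L)
  tt <- trial_table(stim, resp, cf)
  opt <- optimize_thresholds(tt, b = 2)
  expect_equal(opt$scheme$thresholds, 0.7, tolerance = 0.02)
  expect_equal(opt$meta_I, entropy_accuracy(joint_from_trials(tt, opt$scheme)))
})

test_that("optimized bins dominate fixed even bins", {
  obs <- second_order_observer(1, 1, 0.5)
  sim <- simulate(obs, nsim = 20000, seed = 43)
  opt <- optimize_thresholds(sim, b = 4, seed = 2)
  even <- meta_I(joint_from_trials(sim, even_thresholds(4)))
  expect_gte(opt$meta_I, even - 1e-12)
})

test_that("optimization is invariant to trial order and is seeded", {
  obs <- second_order_observer(1, 1, 1)
  sim <- simulate(obs, nsim = 800, seed = 47)
  set.seed(1)
  perm <- sample.int(nrow(sim))
  sim2 <- sim[perm, , drop = FALSE]
  o1 <- optimize_thresholds(sim, b = 5, seed = 7)
  o2 <- optimize_thresholds(sim2, b = 5, seed = 7)
  expect_equal(o1$scheme$thresholds, o2$scheme$thresholds)
  expect_equal(o1$meta_I, o2$meta_I)
  # repeated calls with the same seed are identical
  o3 <- optimize_thresholds(sim, b = 5, seed = 7)
  expect_identical(o1$scheme$thresholds, o3$scheme$thresholds)
})

test_that("granularity ratios start at 1 and never decrease", {
  obs <- second_order_observer(1, 1, 0.5)
  sim <- simulate(obs, nsim = 5000, seed = 53)
  gc <- granularity_curve(sim, b_values = c(2, 4, 8, 16), seed = 11)
  expect_equal(gc$ratio[1], 1)
  expect_true(all(diff(gc$ratio) > -1e-9))
  expect_true(all(gc$ratio >= 1 - 1e-9))
  # effectively binary confidence (two tight clusters perfectly
  # predicting accuracy): extra bins cannot help
  group <- rep(c(1L, 0L), 100)
  cf <- ifelse(group == 1, 0.9, 0.3) +
    rep(seq(0, 0.009, length.out = 100), each = 2)
  tt <- trial_table(rep(1L, 200), ifelse(group == 1, 1L, -1L), cf)
  gc2 <- granularity_curve(tt, b_values = c(2, 4), seed = 1)
  expect_equal(gc2$ratio, c(1, 1), tolerance = 1e-9)
})

test_that("more distinct values than bins are required", {
  tt <- trial_table(rep(1L, 10), rep(c(1L, -1L), 5), rep(c(0.2, 0.8), 5))
  expect_error(optimize_thresholds(tt, b = 3), "distinct")
})
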