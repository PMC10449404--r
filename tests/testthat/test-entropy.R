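test_that("binary entropy matches the closed form and its printed values", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(0), 0)
  expect_equal(binary_entropy(1), 0)
  expect_equal(round(binary_entropy(855 / 998), 3), 0.593)
  expect_equal(round(binary_entropy(415 / 420), 3), 0.093)
  expect_equal(round(binary_entropy(440 / 578), 3), 0.793)
  # symmetry p <-> 1 - p
  p <- c(0.01, 0.2, 0.37, 0.5, 0.9)
  expect_equal(binary_entropy(p), binary_entropy(1 - p))
  expect_error(binary_entropy(1.2), "\\[0, 1\\]")
  expect_error(binary_entropy(-0.1), "\\[0, 1\\]")
})

test_that("trial tabulation counts each (accuracy, bin) cell", {
  tt <- trial_table(stimulus = c(1, -1, 1, 1),
                    response = c(1, 1, 1, 1),
                    confidence = c(0.9, 0.6, 0.8, 0.6),
                    range = c(0.5, 1))
  # accuracies 1 0 1 1; threshold 0.72 -> high bin gets 0.9 and 0.8
  jt <- joint_from_trials(tt, binning_scheme(0.72, c(0.5, 1)))
  expect_equal(unname(jt$counts), rbind(c(1, 0), c(1, 2)))
  # a single bin reduces to the marginal accuracy counts
  jt1 <- joint_from_trials(tt, binning_scheme(numeric(), c(0.5, 1)))
  expect_equal(unname(jt1$counts), cbind(c(1, 3)))
  # brute-force per-trial loop oracle on simulated data
  obs <- second_order_observer(1, 1, 0.5)
  sim <- simulate(obs, nsim = 500, seed = 21)
  sch <- binning_scheme(c(0.1, 0.5, 0.9))
  jt2 <- joint_from_trials(sim, sch)
  expect_equal(unname(jt2$counts),
               count_bins_loop(sim$accuracy, sim$confidence,
                               c(0, 0.1, 0.5, 0.9, 1)))
  expect_equal(sum(jt2$counts), 500)
})

test_that("the binarized worked example reproduces its printed numbers", {
  jt <- worked_example_counts()
  expect_equal(round(entropy_accuracy(jt), 3), 0.593)
  # weighted conditional entropy of the two bins
  expect_equal(round(conditional_entropy_accuracy(jt), 3),
               round(420 / 998 * binary_entropy(415 / 420) +
                       578 / 998 * binary_entropy(440 / 578), 3))
  expect_equal(round(conditional_entropy_accuracy(jt), 3), 0.498)
  expect_equal(round(meta_I(jt), 3), 0.094)
})

test_that("meta-I equals the direct double-sum and obeys its bounds", {
  set.seed(101)
  for (i in 1:25) {
    cnt <- matrix(rpois(8, lambda = sample(3:40, 1)), 2, 4)
    if (sum(cnt) == 0 || any(rowSums(cnt) == 0)) next
    jt <- joint_table(cnt)
    expect_equal(meta_I(jt), mi_direct(cnt), tolerance = 1e-12)
    # symmetry identity: H2(r) - H2(r|c) == H2(c) - H2(c|r)
    p <- cnt / sum(cnt)
    pc <- colSums(p)
    hc <- -sum(pc[pc > 0] * log2(pc[pc > 0]))
    pr <- rowSums(p)
    hc_given_r <- 0
    for (r in 1:2) {
      if (pr[r] > 0) {
        q <- p[r, ] / pr[r]
        hc_given_r <- hc_given_r - pr[r] * sum(q[q > 0] * log2(q[q > 0]))
      }
    }
    expect_lt(abs(meta_I(jt) - (hc - hc_given_r)), 1e-12)
    # 0 <= meta-I <= min(H2(r), H2(c))
    expect_gte(meta_I(jt), -1e-12)
    expect_lte(meta_I(jt), min(entropy_accuracy(jt), hc) + 1e-12)
  }
  # independence: product table has zero information
  prod_tab <- outer(c(0.3, 0.7), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(meta_I(joint_table(prod_tab)), 0, tolerance = 1e-12)
  # perfectly predictive two-bin table removes all uncertainty
  perf <- rbind(c(30, 0), c(0, 70))
  expect_equal(meta_I(joint_table(perf)),
               entropy_accuracy(joint_table(perf)))
})

test_that("meta-I is label-invariant and monotone under bin refinement", {
  set.seed(77)
  for (i in 1:10) {
    cnt <- matrix(rpois(12, 15) + 1, 2, 6)
    base <- meta_I(joint_table(cnt))
    perm <- sample(6)
    expect_equal(meta_I(joint_table(cnt[, perm])), base, tolerance = 1e-12)
    # merging any two adjacent bins never increases meta-I
    for (j in 1:5) {
      merged <- cbind(cnt[, seq_len(j - 1), drop = FALSE],
                      cnt[, j] + cnt[, j + 1],
                      cnt[, seq(j + 2, 7)[seq_len(5 - j)], drop = FALSE])
      expect_lte(meta_I(joint_table(merged)), base + 1e-12)
    }
  }
})

test_that("response-specific meta-I matches stratified computation", {
  obs <- second_order_observer(1, 1, 0.5)
  sim <- simulate(obs, nsim = 20000, seed = 31)
  sch <- binning_scheme(c(0.1, 0.5, 0.9))
  rs <- meta_I_response_specific(sim, sch)
  # the model is action-symmetric, so the strata agree up to sampling error
  expect_equal(unname(rs["-1"]), unname(rs["1"]), tolerance = 0.1)
  # each stratum equals plain meta-I of that subset
  for (a in c(-1, 1)) {
    sub <- sim[sim$response == a, , drop = FALSE]
    expect_equal(unname(rs[as.character(a)]),
                 meta_I(joint_from_trials(sub, sch)))
  }
  # hand-built 8-trial strata against the double-sum oracle
  tt <- trial_table(stimulus = c(1, 1, -1, -1, 1, -1, 1, -1),
                    response = c(1, 1, 1, 1, -1, -1, -1, -1),
                    confidence = c(0.95, 0.2, 0.6, 0.3, 0.8, 0.85, 0.1, 0.4))
  sch2 <- binning_scheme(0.5)
  rs2 <- meta_I_response_specific(tt, sch2)
  for (a in c(-1, 1)) {
    sub <- tt[tt$response == a, , drop = FALSE]
    cnt <- count_bins_loop(sub$accuracy, sub$confidence, c(0, 0.5, 1))
    expect_equal(unname(rs2[as.character(a)]), mi_direct(cnt))
  }
  # a degenerate stratum is flagged and reported as zero, not an error
  tt3 <- trial_table(stimulus = c(1, 1, 1, 1), response = c(1, 1, 1, 1),
                     confidence = c(0.9, 0.2, 0.6, 0.7))
  expect_warning(rs3 <- meta_I_response_specific(tt3, sch2), "degenerate")
  expect_true(is.na(rs3["-1"]))
  expect_true(attr(rs3, "degenerate")["-1"])
})

test_that("efficiency ratios divide by the stated normalizers", {
  r <- efficiency_ratios(0.104, d_prime = 1)
  expect_equal(unname(r["meta_I1r"]), 0.104 / meta_I_dprime(1))
  expect_equal(unname(r["meta_I1r"]), 2, tolerance = 0.01)
  expect_equal(unname(r["meta_I2r"]),
               0.104 / binary_entropy(pnorm(0.5)))
  r2 <- efficiency_ratios(0.62, d_prime = 1)
  expect_equal(unname(r2["meta_I2r"]), 0.7, tolerance = 0.01)
  expect_equal(as.numeric(efficiency_ratios(0, 1)), c(0, 0))
  expect_error(efficiency_ratios(0.1, 0), "d_prime")
  expect_error(efficiency_ratios(0.1, -1), "d_prime")
  # binned normalizer variant is recorded and differs from continuous
  rb <- efficiency_ratios(0.104, 1, b = 4)
  expect_match(attr(rb, "normalizer"), "binned")
  expect_gt(unname(rb["meta_I1r"]), unname(r["meta_I1r"]))
})
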