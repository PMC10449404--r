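#' Second-order confidence observer
#'
#' A generative model splitting one subject into an actor and a rater.
#' On each trial the stimulus is \eqn{d = \pm 1} with equal probability
#' and three conditionally independent Gaussian signals are drawn:
#' \deqn{\alpha = d + A\,\epsilon_\alpha, \quad
#'       \beta = \alpha + B\,\epsilon_\beta, \quad
#'       \gamma = d + \sqrt{G^2}\,\epsilon_\gamma,}
#' with standard-normal \eqn{\epsilon}.  The actor's noise scale is tied
#' to type-1 sensitivity by \eqn{A = 2/d'} and the decision is
#' \eqn{a = \mathrm{sign}(\alpha)} (ties to +1).  The rater observes the
#' action `a`, a noisy read-out `beta` of the actor's evidence
#' (read-out noise sd `b_noise`), and a unique signal `gamma` about the
#' stimulus itself with noise variance `g2` — e.g. post-decisional
#' evidence the actor never used.  Confidence is the exact posterior
#' probability that the action was correct,
#' \eqn{c = P(a = d \mid a, \beta, \gamma)}.
#'
#' The model is parameterized by the unique-signal noise *variance* `g2`
#' (the quantity on which the rater's information quality is naturally
#' compared), and by the read-out noise *sd* `b_noise`.  Limits of
#' interest: `b_noise -> 0, g2 -> Inf` makes the rater a first-order
#' Bayesian with the actor's own information; `b_noise -> Inf, g2 -> 0`
#' gives a rater with perfect error knowledge.
#'
#' @param d_prime Actor's type-1 sensitivity (> 0).
#' @param b_noise Rater read-out noise sd B (>= 0).
#' @param g2 Variance of the rater's unique-signal noise (> 0).
#' @return An object of class `"so_observer"`.
#' @examples
#' obs <- second_order_observer(d_prime = 1, b_noise = 1, g2 = 5)
#' confidence_surface(obs, a = -1, beta = -2, gamma = -1)
#' @export
second_order_observer <- function(d_prime, b_noise = 1, g2 = 1) {
  if (!is.numeric(d_prime) || d_prime <= 0) {
    stop("`d_prime` must be > 0", call. = FALSE)
  }
  if (b_noise < 0) stop("`b_noise` must be >= 0", call. = FALSE)
  if (g2 <= 0) stop("`g2` must be > 0", call. = FALSE)
  structure(list(d_prime = d_prime, A = 2 / d_prime, b_noise = b_noise,
                 g2 = g2, g_sd = sqrt(g2)),
            class = "so_observer")
}

#' @export
print.so_observer <- function(x, ...) {
  cat(sprintf(
    "Second-order observer: d' = %g (actor noise A = %g), B = %g, G^2 = %g\n",
    x$d_prime, x$A, x$b_noise, x$g2))
  cat(sprintf("Actor accuracy Phi(d'/2) = %.4f\n",
              accuracy_from_dprime(x$d_prime)))
  invisible(x)
}

## closed-form pieces of the posterior: P(a, beta | d) =
## N(beta; d, A^2 + B^2) * Phi(a * mu / s) where mu, s are the posterior
## mean/sd of alpha given (beta, d).  Returns the log of the
## unnormalized weight P(a, beta | d) * N(gamma; d, G) for one stimulus
## value d; log scale keeps the posterior well-defined far in the tails.
so_lweight <- function(obs, d, a, beta, gamma) {
  A2 <- obs$A^2
  B2 <- obs$b_noise^2
  vb <- A2 + B2
  ldens_b <- stats::dnorm(beta, d, sqrt(vb), log = TRUE)
  if (obs$b_noise == 0) {
    lp_a <- ifelse(a * beta > 0, 0,
                   ifelse(a * beta < 0, -Inf, log(0.5)))
  } else {
    mu <- d + (A2 / vb) * (beta - d)
    s <- sqrt(A2 * B2 / vb)
    lp_a <- stats::pnorm(a * mu / s, log.p = TRUE)
  }
  ldens_b + lp_a + stats::dnorm(gamma, d, obs$g_sd, log = TRUE)
}

#' Confidence surface of the second-order observer
#'
#' The exact posterior probability that the action was correct given the
#' rater's full information set, \eqn{c = P(d = a \mid a, \beta, \gamma)}.
#' Vectorized over `beta` and `gamma`.
#'
#' @param obs A [second_order_observer].
#' @param a Action, -1 or +1.
#' @param beta,gamma Rater's signals.
#' @return Confidence values in `(0, 1)`.
#' @export
confidence_surface <- function(obs, a, beta, gamma) {
  stopifnot(inherits(obs, "so_observer"), a %in% c(-1, 1))
  lwp <- so_lweight(obs, +1, a, beta, gamma)
  lwm <- so_lweight(obs, -1, a, beta, gamma)
  ## c = w_a / (w_a + w_other) = logistic(lw_a - lw_other)
  if (a == 1) stats::plogis(lwp - lwm) else stats::plogis(lwm - lwp)
}

#' @export
predict.so_observer <- function(object, newdata, ...) {
  stopifnot(all(c("response", "beta", "gamma") %in% names(newdata)))
  out <- numeric(nrow(newdata))
  for (a in c(-1, 1)) {
    i <- newdata$response == a
    if (any(i)) {
      out[i] <- confidence_surface(object, a, newdata$beta[i],
                                   newdata$gamma[i])
    }
  }
  out
}

## tensor-grid quadrature nodes conditioned on one action: returns node
## confidences `c`, normalized node masses `w` (P(beta, gamma | a)), and
## the raw total mass as a convergence check (should be P(a) = 1/2)
so_nodes <- function(obs, a = -1, n_nodes = 801L, span = 8) {
  sb <- sqrt(obs$A^2 + obs$b_noise^2)
  bgrid <- seq(-1 - span * sb, 1 + span * sb, length.out = n_nodes)
  ggrid <- seq(-1 - span * obs$g_sd, 1 + span * obs$g_sd,
               length.out = n_nodes)
  wb <- rep(bgrid[2] - bgrid[1], n_nodes); wb[c(1, n_nodes)] <- wb[1] / 2
  wg <- rep(ggrid[2] - ggrid[1], n_nodes); wg[c(1, n_nodes)] <- wg[1] / 2
  BB <- matrix(bgrid, n_nodes, n_nodes)
  GG <- matrix(ggrid, n_nodes, n_nodes, byrow = TRUE)
  lwp <- so_lweight(obs, +1, a, BB, GG)
  lwm <- so_lweight(obs, -1, a, BB, GG)
  tot <- exp(lwp) + exp(lwm)
  cval <- if (a == 1) stats::plogis(lwp - lwm) else stats::plogis(lwm - lwp)
  W <- outer(wb, wg) * tot * 0.5        # joint with P(d) = 1/2
  raw_mass <- sum(W)
  keep <- as.vector(W) > 0 & is.finite(as.vector(cval))
  list(c = as.vector(cval)[keep], w = as.vector(W)[keep] / raw_mass,
       raw_mass = raw_mass)
}

#' Expected confidence-bin statistics of the second-order observer
#'
#' Per-bin probability mass \eqn{P(c \in \mathrm{bin} \mid a)} and
#' conditional accuracy \eqn{P(r = 1 \mid c \in \mathrm{bin}, a)},
#' obtained by two-dimensional trapezoid quadrature over the rater's
#' signals \eqn{(\beta, \gamma)}.  Because the model's confidence is the
#' exact posterior, the conditional accuracy of a bin is the mass-weighted
#' mean confidence within it.
#'
#' @param obs A [second_order_observer].
#' @param scheme A [binning_scheme] on the confidence range `[0, 1]`.
#' @param a Action stratum, -1 (default) or +1; by symmetry both give the
#'   same statistics.
#' @param n_nodes Quadrature nodes per dimension (default 801).
#' @param span Grid half-width in marginal sds (default 8).
#' @param mass_tol Maximum tolerated deficit of total quadrature mass from
#'   `P(a) = 1/2` before an error is thrown.
#' @return Data frame with columns `bin`, `mass`, `accuracy`.
#' @export
expected_bin_stats <- function(obs, scheme, a = -1, n_nodes = 801L,
                               span = 8, mass_tol = 1e-4) {
  stopifnot(inherits(obs, "so_observer"), inherits(scheme, "binning_scheme"))
  nd <- so_nodes(obs, a = a, n_nodes = n_nodes, span = span)
  deficit <- abs(2 * nd$raw_mass - 1)
  if (deficit > mass_tol) {
    stop(sprintf(
      "quadrature mass deficit %.2e exceeds tolerance %.1e; widen `span` or refine `n_nodes`",
      deficit, mass_tol), call. = FALSE)
  }
  idx <- assign_bins(nd$c, scheme)
  b <- n_bins(scheme)
  f <- factor(idx, levels = seq_len(b))
  mass <- as.numeric(tapply(nd$w, f, sum))
  mass[is.na(mass)] <- 0
  cw <- as.numeric(tapply(nd$w * nd$c, f, sum))
  cw[is.na(cw)] <- 0
  accuracy <- ifelse(mass > 0, cw / mass, NA_real_)
  data.frame(bin = bin_labels(scheme), mass = mass, accuracy = accuracy)
}

bin_stats_to_joint <- function(stats) {
  acc <- ifelse(is.na(stats$accuracy), 0, stats$accuracy)
  joint_table(rbind(stats$mass * (1 - acc), stats$mass * acc),
              bins = stats$bin)
}

#' Exact measures of the second-order observer
#'
#' Assembles the full measure report — \eqn{H_2(r \mid a)},
#' \eqn{H_2(r \mid c, a)}, meta-I and the two efficiency ratios — from
#' the quadrature bin statistics and the first-order normalizers.
#'
#' @inheritParams expected_bin_stats
#' @param normalizer `"continuous"` (default) or an integer `b` for the
#'   matched-granularity meta-I1r normalizer.
#' @return A list of class `"measure_report"`.
#' @examples
#' \donttest{
#' obs <- second_order_observer(1, b_noise = 1, g2 = 5)
#' exact_measures(obs, binning_scheme(c(0.1, 0.5, 0.9)))  # meta-I ~ 0.104
#' }
#' @export
exact_measures <- function(obs, scheme, a = -1, normalizer = "continuous",
                           n_nodes = 801L, span = 8, mass_tol = 1e-4) {
  st <- expected_bin_stats(obs, scheme, a = a, n_nodes = n_nodes,
                           span = span, mass_tol = mass_tol)
  jt <- bin_stats_to_joint(st)
  h2r <- entropy_accuracy(jt)
  h2rc <- conditional_entropy_accuracy(jt)
  mi <- h2r - h2rc
  ratios <- efficiency_ratios(mi, obs$d_prime, b = normalizer)
  structure(
    list(meta_I = mi, H2_r = h2r, H2_r_given_c = h2rc,
         meta_I1r = unname(ratios["meta_I1r"]),
         meta_I2r = unname(ratios["meta_I2r"]),
         normalizer = attr(ratios, "normalizer"),
         bin_stats = st, scheme = scheme, action = a,
         params = c(d_prime = obs$d_prime, b_noise = obs$b_noise,
                    g2 = obs$g2)),
    class = "measure_report"
  )
}

#' @export
print.measure_report <- function(x, digits = 3, ...) {
  cat("Metacognitive measure report\n")
  if (!is.null(x$params)) {
    cat(sprintf("  model: d' = %g, B = %g, G^2 = %g (action a = %d)\n",
                x$params["d_prime"], x$params["b_noise"], x$params["g2"],
                x$action))
  }
  cat(sprintf("  H2(r)    = %.*f bits\n", digits, x$H2_r))
  cat(sprintf("  H2(r|c)  = %.*f bits\n", digits, x$H2_r_given_c))
  cat(sprintf("  meta-I   = %.*f bits\n", digits, x$meta_I))
  cat(sprintf("  meta-I1r = %.*f   (normalizer: %s)\n", digits, x$meta_I1r,
              x$normalizer))
  cat(sprintf("  meta-I2r = %.*f\n", digits, x$meta_I2r))
  invisible(x)
}

#' Simulate trials from the second-order observer
#'
#' Draws i.i.d. trials from the generative model: stimulus uniform on
#' \eqn{\pm 1}, the three Gaussian signals, the sign decision, and the
#' exact posterior confidence.  Bit-reproducible given `seed`.
#'
#' @param object A [second_order_observer].
#' @param nsim Number of trials.
#' @param seed Integer seed (optional but recommended).
#' @param keep_signals If `TRUE`, retain `alpha`, `beta`, `gamma` columns.
#' @param ... Unused.
#' @return A [trial_table] with confidence range `[0, 1]`.
#' @export
simulate.so_observer <- function(object, nsim = 1000, seed = NULL,
                                 keep_signals = FALSE, ...) {
  stopifnot(nsim >= 1)
  with_seed(seed, {
    d <- sample(c(-1L, 1L), nsim, replace = TRUE)
    alpha <- d + object$A * stats::rnorm(nsim)
    beta <- alpha + object$b_noise * stats::rnorm(nsim)
    gamma <- d + object$g_sd * stats::rnorm(nsim)
    a <- ifelse(alpha >= 0, 1L, -1L)      # indifference at 0 resolved to +1
    cf <- numeric(nsim)
    for (av in c(-1L, 1L)) {
      i <- a == av
      if (any(i)) cf[i] <- confidence_surface(object, av, beta[i], gamma[i])
    }
    tt <- trial_table(d, a, cf, range = c(0, 1))
    if (keep_signals) {
      tt$alpha <- alpha
      tt$beta <- beta
      tt$gamma <- gamma
    }
    tt
  })
}

#' @rdname optimize_thresholds
#' @param a Action stratum for the model surface (default -1).
#' @param n_nodes,span Quadrature controls, see [expected_bin_stats()].
#' @export
optimize_thresholds.so_observer <- function(x, b, grid = 200, n_starts = 10,
                                            seed = NULL, a = -1,
                                            n_nodes = 401L, span = 8, ...) {
  nd <- so_nodes(x, a = a, n_nodes = n_nodes, span = span)
  opt_bins_weighted(nd$c, nd$w, nd$w * nd$c, b, range = c(0, 1),
                    grid = grid, n_starts = n_starts, seed = seed)
}

#' Measure sweep over a parameter grid of second-order observers
#'
#' Computes all measures on a grid of `d_prime` and `g2` values (at fixed
#' read-out noise), with confidence bins optimized to maximize meta-I on
#' the exact model surface at each grid point.
#'
#' @param d_prime_values,g2_values Numeric grids (> 0).
#' @param b_noise Read-out noise sd (default 1).
#' @param b Number of optimized confidence bins (default 4).
#' @param n_nodes Quadrature nodes per dimension (default 401, adequate
#'   for the ~1e-3-bit tolerances of grid summaries).
#' @param seed Seed for the threshold search multi-start.
#' @param normalizer Passed to [exact_measures()].
#' @return Data frame with one row per grid point: parameters, optimized
#'   meta-I, meta-I1r, meta-I2r, H2(r).
#' @export
sweep_measures <- function(d_prime_values, g2_values, b_noise = 1, b = 4,
                           n_nodes = 401L, seed = NULL,
                           normalizer = "continuous") {
  grid <- expand.grid(d_prime = d_prime_values, g2 = g2_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    obs <- second_order_observer(grid$d_prime[i], b_noise, grid$g2[i])
    opt <- optimize_thresholds(obs, b, seed = seed, n_nodes = n_nodes)
    m <- exact_measures(obs, opt$scheme, n_nodes = n_nodes,
                        normalizer = normalizer)
    data.frame(d_prime = grid$d_prime[i], g2 = grid$g2[i],
               b_noise = b_noise, b = b, meta_I = m$meta_I,
               meta_I1r = m$meta_I1r, meta_I2r = m$meta_I2r,
               H2_r = m$H2_r)
  })
  do.call(rbind, rows)
}
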