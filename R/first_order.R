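#' First-order signal-detection quantities
#'
#' For an unbiased actor discriminating two equal-variance Gaussian
#' evidence distributions with type-1 sensitivity `d_prime`, the
#' probability of a correct decision is \eqn{\Phi(d'/2)}.
#'
#' @param d_prime Type-1 sensitivity (>= 0).
#' @return Probability correct.
#' @examples
#' accuracy_from_dprime(1)  # 0.691
#' @export
accuracy_from_dprime <- function(d_prime) {
  if (any(d_prime < 0)) stop("`d_prime` must be >= 0", call. = FALSE)
  stats::pnorm(d_prime / 2)
}

#' @rdname accuracy_from_dprime
#' @return For `accuracy_entropy`, the entropy of the accuracy
#'   \eqn{H_2(r) = h_2(\Phi(d'/2))} in bits, strictly decreasing in
#'   `d_prime` for `d_prime > 0`.
#' @examples
#' accuracy_entropy(1)      # 0.891 bits
#' @export
accuracy_entropy <- function(d_prime) {
  binary_entropy(accuracy_from_dprime(d_prime))
}

## density of the evidence alpha under the unit-variance parameterization:
## alpha ~ N(d * d'/2, 1), d = +/-1 with equal probability
fo_density <- function(a, d_prime) {
  m <- d_prime / 2
  0.5 * stats::dnorm(a, m) + 0.5 * stats::dnorm(a, -m)
}

#' meta-I of the ideal first-order rater (continuous confidence)
#'
#' The mutual information, in bits, between accuracy and the continuous
#' confidence of a first-order Bayesian rater who sees the actor's own
#' evidence: evidence \eqn{\alpha \sim N(d\, d'/2, 1)}, decision
#' \eqn{a = \mathrm{sign}(\alpha)}, confidence
#' \eqn{c = 1 / (1 + e^{-d'|\alpha|})} (the exact posterior probability
#' correct).  Computed as \eqn{H_2(r) - E_\alpha[h_2(P(\mathrm{correct}
#' \mid \alpha))]} by adaptive one-dimensional quadrature.  This is the
#' normalizer defining meta-I1r.  The value is invariant to any strictly
#' monotone reparameterization of the evidence scale (only the posterior
#' matters), rises with `d_prime` at low sensitivity and falls again at
#' high sensitivity as the accuracy entropy it is bounded by collapses.
#'
#' @param d_prime Type-1 sensitivity (> 0).
#' @param rel_tol Quadrature tolerance (absolute, bits).
#' @return meta-I(d') in bits.
#' @examples
#' meta_I_dprime(1)  # 0.052 bits
#' @export
meta_I_dprime <- function(d_prime, rel_tol = 1e-6) {
  if (!is.numeric(d_prime) || d_prime <= 0) {
    stop("`d_prime` must be > 0", call. = FALSE)
  }
  m <- d_prime / 2
  f <- function(a) {
    ## h2 is symmetric in p <-> 1 - p, so the posterior for d = +1 serves
    ## for both signs of alpha
    binary_entropy(stats::plogis(d_prime * a)) * fo_density(a, d_prime)
  }
  cond <- stats::integrate(f, -m - 8, m + 8, rel.tol = rel_tol,
                           abs.tol = 1e-8, subdivisions = 400L)$value
  accuracy_entropy(d_prime) - cond
}

## quadrature nodes over x = |alpha| with total and correct weights;
## confidence c = plogis(d' x)
fo_nodes <- function(d_prime, n_nodes = 4001L, span = 8) {
  m <- d_prime / 2
  x <- seq(0, m + span, length.out = n_nodes)
  dx <- x[2] - x[1]
  f <- stats::dnorm(x - m) + stats::dnorm(x + m)   # folded mixture density
  w <- f * dx
  w[c(1, n_nodes)] <- w[c(1, n_nodes)] / 2
  cval <- stats::plogis(d_prime * x)
  list(c = cval, w = w, wc = cval * w)
}

#' meta-I of the ideal first-order rater with b confidence bins
#'
#' The maximal meta-I attainable by quantizing the first-order rater's
#' confidence into `b` bins, found by threshold optimization on the
#' model's exact bin masses (quadrature over the evidence distribution).
#' Bounded above by the continuous [meta_I_dprime()] and non-decreasing in
#' `b`.
#'
#' @inheritParams meta_I_dprime
#' @param b Integer number of bins (>= 2).
#' @param grid,n_starts,seed Search controls, see [optimize_thresholds()].
#' @return meta-I(d', b) in bits.
#' @export
meta_I_dprime_binned <- function(d_prime, b, grid = 200, n_starts = 10,
                                 seed = NULL) {
  if (!is.numeric(d_prime) || d_prime <= 0) {
    stop("`d_prime` must be > 0", call. = FALSE)
  }
  nd <- fo_nodes(d_prime)
  opt_bins_weighted(nd$c, nd$w, nd$wc, b, range = c(0.5, 1), grid = grid,
                    n_starts = n_starts, seed = seed)$meta_I
}

#' meta-I of the all-or-none mixture rater
#'
#' A boundary case of metacognitive hyper-efficiency: the actor/rater pair
#' is completely guessing (true and believed accuracy 0.5) on a fraction
#' \eqn{2 p_{err}} of trials, with \eqn{p_{err} = 1 - \Phi(d'/2)}, and
#' perfectly correct (and sure of it) on the remaining \eqn{1 - 2p_{err}}.
#' The overall accuracy matches a conventional actor at `d_prime`, but the
#' rater knows exactly which trials are guesses, so in closed form
#' \deqn{\mathrm{meta}\mbox{-}I = h_2(\Phi(d'/2)) - 2(1 - \Phi(d'/2)),}
#' which exceeds [meta_I_dprime()] at the same sensitivity.
#'
#' @inheritParams meta_I_dprime
#' @return Named vector `c(meta_I, meta_I1r, meta_I2r)`.
#' @export
mixture_meta_I <- function(d_prime) {
  if (!is.numeric(d_prime) || d_prime <= 0) {
    stop("`d_prime` must be > 0", call. = FALSE)
  }
  p_err <- 1 - accuracy_from_dprime(d_prime)
  if (2 * p_err > 1) {
    stop("mixture proportion 2 * p_err exceeds 1", call. = FALSE)
  }
  mi <- accuracy_entropy(d_prime) - 2 * p_err * binary_entropy(0.5)
  r <- efficiency_ratios(mi, d_prime)
  c(meta_I = mi, meta_I1r = unname(r["meta_I1r"]),
    meta_I2r = unname(r["meta_I2r"]))
}
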