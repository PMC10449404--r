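#' Fit meta-d' to type-2 confidence statistics
#'
#' Reference fitter for the classical model-based measure of
#' metacognitive sensitivity.  The confidence data are treated as if they
#' were produced by a notional first-order signal-detection observer whose
#' sensitivity — meta-d' — is chosen so that the model's type-2
#' confidence statistics match the observed ones.  The model is
#' equal-variance Gaussian: evidence \eqn{x \sim N(\pm \mathrm{meta}\mbox{-}d'/2, 1)},
#' the type-1 criterion re-expressed in meta-d' units as
#' `criterion * meta_d / d_prime`, and ordered type-2 criteria on each
#' response side (parameterized as cumulative positive increments).
#' Fitting maximizes the type-2 likelihood of counts, or minimizes the
#' cross-entropy for expected-probability input (the infinite-data limit
#' of the same objective), via a bounded scalar search over meta-d' with
#' nested criteria optimization.
#'
#' @param x Type-2 data for a single response stratum: either a 2 x b
#'   matrix (row 1 incorrect, row 2 correct; columns confidence bins in
#'   increasing order) of counts or probabilities, or a data frame with
#'   `mass` and `accuracy` columns as returned by [expected_bin_stats()].
#'   Alternatively a [trial_table]; see the method below.
#' @param ... Passed to methods.
#' @return An object of class `"metad_fit"` with components `meta_d`,
#'   `d_prime`, `criterion`, `m_ratio`, `meta_d_diff`, `t2_criteria`,
#'   `value` (the achieved objective), and `convergence`.
#' @examples
#' \donttest{
#' obs <- second_order_observer(1, b_noise = 1, g2 = 5)
#' st <- expected_bin_stats(obs, binning_scheme(c(0.1, 0.5, 0.9)))
#' fit_meta_d(st, d_prime = 1)  # meta-d' ~ 1.7
#' }
#' @export
fit_meta_d <- function(x, ...) UseMethod("fit_meta_d")

#' @rdname fit_meta_d
#' @param d_prime The actor's true type-1 sensitivity (> 0).
#' @param criterion Type-1 criterion (default 0, unbiased).
#' @param response Which response stratum the data describe (-1 or +1);
#'   only the mirror orientation of the criteria depends on it.
#' @param pseudo_count Additive constant for count input to avoid zero
#'   cells; default `1 / (2 * b)`.  Ignored for probability input.
#' @export
fit_meta_d.default <- function(x, d_prime, criterion = 0, response = -1,
                               pseudo_count = NULL, ...) {
  if (is.data.frame(x) && all(c("mass", "accuracy") %in% names(x))) {
    acc <- ifelse(is.na(x$accuracy), 0, x$accuracy)
    m <- rbind(x$mass * (1 - acc), x$mass * acc)
  } else {
    m <- as.matrix(x)
  }
  if (nrow(m) != 2L || ncol(m) < 2L) {
    stop("type-2 input must have 2 rows and at least 2 confidence bins",
         call. = FALSE)
  }
  if (any(m < 0) || anyNA(m)) {
    stop("type-2 entries must be non-negative and finite", call. = FALSE)
  }
  is_prob <- abs(sum(m) - 1) < 1e-6
  if (!is_prob) {
    if (is.null(pseudo_count)) pseudo_count <- 1 / (2 * ncol(m))
    m <- m + pseudo_count
  }
  if (sum(colSums(m) > 0) < 2L) {
    stop("all confidence mass in one bin; meta-d' is unidentifiable",
         call. = FALSE)
  }
  sides <- list(m)
  names(sides) <- as.character(response)
  metad_fit_engine(sides, d_prime, criterion)
}

#' @rdname fit_meta_d
#' @param scheme A [binning_scheme] used to discretize confidence.
#' @details The [trial_table] method tabulates confidence per response,
#'   estimates `d_prime` and `criterion` from the type-1 hit and
#'   false-alarm rates unless supplied, and fits one meta-d' jointly to
#'   both response strata (with side-specific type-2 criteria).
#' @export
fit_meta_d.trial_table <- function(x, scheme, d_prime = NULL,
                                   criterion = NULL, pseudo_count = NULL,
                                   ...) {
  x <- as_trial_table(x)
  if (is.null(d_prime) || is.null(criterion)) {
    n1 <- sum(x$stimulus == 1)
    n0 <- sum(x$stimulus == -1)
    if (n1 == 0 || n0 == 0) {
      stop("both stimulus values are needed to estimate d'", call. = FALSE)
    }
    clamp <- function(p, n) pmin(pmax(p, 0.5 / n), 1 - 0.5 / n)
    hit <- clamp(mean(x$response[x$stimulus == 1] == 1), n1)
    fa <- clamp(mean(x$response[x$stimulus == -1] == 1), n0)
    if (is.null(d_prime)) d_prime <- stats::qnorm(hit) - stats::qnorm(fa)
    if (is.null(criterion)) {
      criterion <- -(stats::qnorm(hit) + stats::qnorm(fa)) / 2
    }
  }
  b <- n_bins(scheme)
  if (is.null(pseudo_count)) pseudo_count <- 1 / (2 * b)
  idx <- assign_bins(x$confidence, scheme)
  sides <- list()
  for (a in c(-1, 1)) {
    rows <- x$response == a
    if (!any(rows)) next
    cnt <- matrix(0, 2, b)
    for (r in 0:1) {
      cnt[r + 1, ] <- tabulate(idx[rows][x$accuracy[rows] == r], nbins = b)
    }
    sides[[as.character(a)]] <- cnt + pseudo_count
  }
  metad_fit_engine(sides, d_prime, criterion)
}

## type-2 conditional probabilities P(bin | r, a) under the notional
## observer.  meta_d > 0; c1 is the type-1 criterion in meta-d' units;
## increments `inc` (> 0) push the type-2 criteria away from c1 on the
## `side` of the response.  Bins are returned low -> high confidence.
metad_t2_probs <- function(meta_d, c1, inc, side) {
  mu <- meta_d / 2
  t2 <- c1 + side * cumsum(inc)           # from c1 outward
  edges <- if (side < 0) c(-Inf, rev(t2), c1) else c(c1, t2, Inf)
  p_of <- function(mean_d) {
    p <- diff(stats::pnorm(edges, mean = mean_d))
    denom <- if (side < 0) stats::pnorm(c1, mean = mean_d)
             else 1 - stats::pnorm(c1, mean = mean_d)
    p <- p / denom
    if (side < 0) rev(p) else p           # ascending confidence
  }
  ## correct means the stimulus matched the response side
  list(correct = p_of(side * mu), incorrect = p_of(-side * mu))
}

metad_fit_engine <- function(sides, d_prime, criterion) {
  if (!is.numeric(d_prime) || d_prime <= 0) {
    stop("`d_prime` must be > 0", call. = FALSE)
  }
  sides_prep <- lapply(names(sides), function(nm) {
    m <- sides[[nm]]
    k <- ncol(m)
    list(side = as.numeric(nm), k = k,
         w_inc = sum(m[1, ]), w_cor = sum(m[2, ]),
         p_inc = m[1, ] / max(sum(m[1, ]), .Machine$double.eps),
         p_cor = m[2, ] / max(sum(m[2, ]), .Machine$double.eps))
  })
  eps <- 1e-12
  obj_given_metad <- function(meta_d) {
    c1 <- criterion * meta_d / d_prime
    nll_inc <- function(par) {
      off <- 0
      tot <- 0
      for (s in sides_prep) {
        inc <- exp(par[(off + 1):(off + s$k - 1)])
        off <- off + s$k - 1
        p <- metad_t2_probs(meta_d, c1, inc, s$side)
        tot <- tot - s$w_cor * sum(s$p_cor * log(pmax(p$correct, eps))) -
          s$w_inc * sum(s$p_inc * log(pmax(p$incorrect, eps)))
      }
      tot
    }
    npar <- sum(vapply(sides_prep, function(s) s$k - 1L, integer(1)))
    init <- rep(log(max(meta_d, 1) / 2 / max(2, npar)), npar)
    op <- stats::optim(init, nll_inc, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12))
    op2 <- stats::optim(op$par, nll_inc, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-13))
    op2
  }
  outer <- stats::optimize(function(md) obj_given_metad(md)$value,
                           interval = c(1e-3, 20), tol = 1e-6)
  meta_d <- outer$minimum
  inner <- obj_given_metad(meta_d)
  c1 <- criterion * meta_d / d_prime
  t2 <- list()
  off <- 0
  for (s in sides_prep) {
    inc <- exp(inner$par[(off + 1):(off + s$k - 1)])
    off <- off + s$k - 1
    t2[[as.character(s$side)]] <- c1 + s$side * cumsum(inc)
  }
  structure(
    list(meta_d = meta_d, d_prime = d_prime, criterion = criterion,
         m_ratio = meta_d / d_prime, meta_d_diff = meta_d - d_prime,
         t2_criteria = t2, value = inner$value,
         convergence = inner$convergence == 0),
    class = "metad_fit"
  )
}

#' @export
print.metad_fit <- function(x, digits = 3, ...) {
  cat("Equal-variance type-2 SDT fit\n")
  cat(sprintf("  d'       = %.*f  (criterion %.*f)\n", digits, x$d_prime,
              digits, x$criterion))
  cat(sprintf("  meta-d'  = %.*f\n", digits, x$meta_d))
  cat(sprintf("  M-ratio  = %.*f   meta-d' - d' = %.*f\n", digits,
              x$m_ratio, digits, x$meta_d_diff))
  if (!x$convergence) cat("  [warning: optimizer did not converge]\n")
  invisible(x)
}

#' @export
coef.metad_fit <- function(object, ...) {
  c(d_prime = object$d_prime, meta_d = object$meta_d,
    m_ratio = object$m_ratio)
}

#' M-ratio and meta-d' difference
#'
#' @param fit A `"metad_fit"` object.
#' @return `m_ratio()`: meta-d' / d'; `meta_d_diff()`: meta-d' - d'.
#' @export
m_ratio <- function(fit) {
  stopifnot(inherits(fit, "metad_fit"))
  if (fit$d_prime == 0) {
    stop("M-ratio undefined at d' = 0 (and unstable for very low d')",
         call. = FALSE)
  }
  fit$meta_d / fit$d_prime
}

#' @rdname m_ratio
#' @export
meta_d_diff <- function(fit) {
  stopifnot(inherits(fit, "metad_fit"))
  fit$meta_d - fit$d_prime
}
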