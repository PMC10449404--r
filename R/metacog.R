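#' Fit the metacognitive information measures to trial data
#'
#' The central entry point: takes trial-level confidence data, bins the
#' confidence ratings (with fixed or optimized thresholds), tabulates the
#' joint accuracy-by-confidence distribution and returns meta-I with its
#' two efficiency ratios, the response-specific values, and (optionally)
#' the permutation bias correction.
#'
#' @param trials A [trial_table] (or data frame with `stimulus`,
#'   `response`, `confidence` columns), or a 2-row count matrix /
#'   [joint_table] of already-binned data (in which case binning options
#'   are ignored and response-specific values are unavailable).
#' @param bins Number of confidence bins when thresholds are optimized
#'   (default 2), or ignored when `thresholds` is given.
#' @param thresholds Fixed interior thresholds; `NULL` (default) optimizes
#'   them to maximize meta-I.
#' @param d_prime The actor's type-1 sensitivity for the efficiency
#'   ratios.  If `NULL` it is estimated model-free from the overall
#'   accuracy as \eqn{d' = 2\Phi^{-1}(\mathrm{acc})}.
#' @param normalizer `"continuous"` (default) or an integer bin count for
#'   the meta-I1r normalizer, see [efficiency_ratios()].
#' @param n_perm Permutations for the bias correction (default 0: none).
#' @param seed Integer seed covering threshold search and permutations.
#' @param grid,n_starts Threshold-search controls,
#'   see [optimize_thresholds()].
#' @return An object of class `"metacog"`: a list with the measures
#'   (`meta_I`, `meta_I1r`, `meta_I2r`, `H2_r`, `H2_r_given_c`),
#'   `meta_I_by_action`, the `scheme`, `d_prime` (with its provenance),
#'   the `correction` report or `NULL`, the `joint` table, and `seed`.
#' @examples
#' obs <- second_order_observer(1, b_noise = 1, g2 = 0.5)
#' tt <- simulate(obs, nsim = 5000, seed = 1)
#' fit <- metacog(tt, thresholds = c(0.1, 0.5, 0.9))
#' coef(fit)
#' @export
metacog <- function(trials, bins = 2, thresholds = NULL, d_prime = NULL,
                    normalizer = "continuous", n_perm = 0, seed = NULL,
                    grid = 200, n_starts = 10) {
  from_counts <- is.matrix(trials) || inherits(trials, "joint_table")
  if (from_counts) {
    joint <- as_joint(trials)
    scheme <- NULL
    by_action <- NULL
    correction <- NULL
  } else {
    trials <- as_trial_table(trials)
    rng <- attr(trials, "conf_range")
    if (is.null(thresholds)) {
      opt <- optimize_thresholds(trials, bins, grid = grid,
                                 n_starts = n_starts, seed = seed)
      scheme <- opt$scheme
      optimized <- TRUE
    } else {
      scheme <- binning_scheme(thresholds, rng)
      optimized <- FALSE
    }
    joint <- joint_from_trials(trials, scheme)
    by_action <- if (all(c(-1, 1) %in% trials$response)) {
      suppressWarnings(meta_I_response_specific(trials, scheme))
    } else NULL
    correction <- if (n_perm > 0) {
      permutation_corrected_meta_I(trials, scheme, n_perm = n_perm,
                                   seed = seed)
    } else NULL
  }
  h2r <- entropy_accuracy(joint)
  h2rc <- conditional_entropy_accuracy(joint)
  mi <- h2r - h2rc
  acc <- sum(joint$p[2, ])
  d_prime_source <- if (is.null(d_prime)) "estimated from accuracy"
                    else "supplied"
  if (is.null(d_prime)) d_prime <- 2 * stats::qnorm(acc)
  ratios <- if (is.finite(d_prime) && d_prime > 0) {
    efficiency_ratios(mi, d_prime, b = normalizer)
  } else {
    c(meta_I1r = NA_real_, meta_I2r = NA_real_)
  }
  structure(
    list(meta_I = mi, H2_r = h2r, H2_r_given_c = h2rc,
         meta_I1r = unname(ratios["meta_I1r"]),
         meta_I2r = unname(ratios["meta_I2r"]),
         meta_I_by_action = by_action,
         accuracy = acc, d_prime = d_prime,
         d_prime_source = d_prime_source,
         normalizer = if (!is.null(attr(ratios, "normalizer")))
           attr(ratios, "normalizer") else as.character(normalizer),
         scheme = scheme,
         thresholds_optimized = if (!from_counts) optimized else FALSE,
         correction = correction, joint = joint, n_perm = n_perm,
         seed = seed,
         version = as.character(utils::packageVersion("metaI"))),
    class = "metacog"
  )
}

#' @export
print.metacog <- function(x, digits = 3, ...) {
  cat("Metacognitive information measures\n")
  cat(sprintf("  accuracy = %.*f (d' = %.*f, %s)\n", digits, x$accuracy,
              digits, x$d_prime, x$d_prime_source))
  cat(sprintf("  H2(r) = %.*f bits, H2(r|c) = %.*f bits\n", digits,
              x$H2_r, digits, x$H2_r_given_c))
  cat(sprintf("  meta-I   = %.*f bits\n", digits, x$meta_I))
  cat(sprintf("  meta-I1r = %.*f   (normalizer: %s)\n", digits,
              x$meta_I1r, x$normalizer))
  cat(sprintf("  meta-I2r = %.*f\n", digits, x$meta_I2r))
  if (!is.null(x$scheme)) {
    cat(sprintf("  bins%s: %s\n",
                if (x$thresholds_optimized) " (optimized)" else "",
                paste(bin_labels(x$scheme), collapse = " ")))
  }
  if (!is.null(x$meta_I_by_action)) {
    cat(sprintf("  meta-I by action: a=-1: %.*f, a=+1: %.*f bits\n",
                digits, x$meta_I_by_action["-1"], digits,
                x$meta_I_by_action["1"]))
  }
  if (!is.null(x$correction)) {
    cat(sprintf("  permutation-corrected meta-I = %.*f bits (null mean %.*f, %d perms)\n",
                digits, x$correction$corrected, digits,
                x$correction$null_mean, x$correction$n_perm))
  }
  invisible(x)
}

#' @export
coef.metacog <- function(object, ...) {
  c(meta_I = object$meta_I, meta_I1r = object$meta_I1r,
    meta_I2r = object$meta_I2r, H2_r = object$H2_r,
    H2_r_given_c = object$H2_r_given_c, d_prime = object$d_prime)
}

#' @export
summary.metacog <- function(object, ...) {
  print(object, digits = 4)
  if (!is.null(object$joint)) {
    cat("\nJoint table:\n")
    print(object$joint)
  }
  invisible(object)
}

#' Serialize a metacog report to JSON
#'
#' Full-precision machine-readable report (requires the `jsonlite`
#' package); numbers are emitted unrounded, with seeds and tool version.
#'
#' @param x A `"metacog"` object.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "metacog"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the `jsonlite` package is required for JSON reports",
         call. = FALSE)
  }
  lst <- list(
    meta_I = x$meta_I, meta_I1r = x$meta_I1r, meta_I2r = x$meta_I2r,
    H2_r = x$H2_r, H2_r_given_c = x$H2_r_given_c,
    meta_I_by_action = if (!is.null(x$meta_I_by_action))
      as.list(stats::setNames(as.numeric(x$meta_I_by_action),
                              names(x$meta_I_by_action))),
    accuracy = x$accuracy, d_prime = x$d_prime,
    d_prime_source = x$d_prime_source, normalizer = x$normalizer,
    thresholds = if (!is.null(x$scheme)) x$scheme$thresholds,
    thresholds_optimized = x$thresholds_optimized,
    correction = if (!is.null(x$correction))
      x$correction[c("raw", "null_mean", "null_sd", "corrected",
                     "n_perm", "exact")],
    n_perm = x$n_perm, seed = x$seed, version = x$version)
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
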