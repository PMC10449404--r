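#' Entropy of a Bernoulli random variable
#'
#' Computes \eqn{h_2(p) = -p \log_2 p - (1-p)\log_2(1-p)} in bits, with the
#' usual convention \eqn{0 \log 0 := 0}.  Vectorized over `p`.
#'
#' @param p Probability (or vector of probabilities) in `[0, 1]`.
#' @return Entropy in bits, same length as `p`.
#' @examples
#' binary_entropy(0.5)        # 1 bit
#' binary_entropy(855 / 998)  # 0.593 bits
#' @export
binary_entropy <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("probabilities must lie in [0, 1]; got ", p[which(bad)[1]],
         call. = FALSE)
  }
  t1 <- ifelse(!is.na(p) & p > 0, -p * log2(p), 0)
  t2 <- ifelse(!is.na(p) & p < 1, -(1 - p) * log2(1 - p), 0)
  out <- t1 + t2
  out[is.na(p)] <- NA_real_
  out
}

#' Joint accuracy-by-confidence table
#'
#' Builds the joint distribution \eqn{P(r, c)} of accuracy
#' (\eqn{r \in \{0, 1\}}, rows) and binned confidence (columns) from a
#' 2-row matrix of counts or probabilities.  Row 1 is incorrect
#' (\eqn{r = 0}), row 2 correct (\eqn{r = 1}); columns are confidence bins
#' in increasing order.  Counts are normalized once at construction.
#'
#' @param counts Numeric matrix with 2 rows (incorrect, correct) and one
#'   column per confidence bin; entries are counts or probabilities.
#' @param bins Optional character vector of bin labels.
#' @param smooth Additive smoothing constant added to every cell before
#'   normalization (default 0, i.e. the plug-in estimate).
#' @return An object of class `"joint_table"`: a list with the probability
#'   matrix `p`, the original `counts` (or `NA` if probabilities were
#'   supplied), the total count `n`, and bin labels.
#' @examples
#' # correct/high 415, correct/low 440, incorrect/high 5, incorrect/low 138
#' jt <- joint_table(rbind(c(138, 5), c(440, 415)), bins = c("low", "high"))
#' meta_I(jt)  # 0.094 bits
#' @export
joint_table <- function(counts, bins = NULL, smooth = 0) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L) {
    stop("`counts` must have 2 rows (incorrect, correct)", call. = FALSE)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop("all entries must be non-negative and finite", call. = FALSE)
  }
  if (smooth < 0) stop("`smooth` must be >= 0", call. = FALSE)
  tot <- sum(counts)
  if (tot <= 0) stop("table has zero total mass", call. = FALSE)
  is_prob <- abs(tot - 1) < 1e-6
  m <- counts + smooth
  p <- m / sum(m)
  if (is.null(bins)) bins <- colnames(counts)
  if (is.null(bins)) bins <- paste0("bin", seq_len(ncol(counts)))
  dimnames(p) <- list(r = c("0", "1"), c = bins)
  structure(
    list(p = p,
         counts = if (is_prob) NULL else counts,
         n = if (is_prob) NA_real_ else tot,
         bins = bins),
    class = "joint_table"
  )
}

#' @export
print.joint_table <- function(x, digits = 3, ...) {
  cat("Joint accuracy x confidence table",
      if (!is.na(x$n)) sprintf(" (n = %g)", x$n), "\n", sep = "")
  print(round(x$p, digits))
  cat(sprintf("P(r = 1) = %.*f   meta-I = %.*f bits\n",
              digits, sum(x$p[2, ]), digits, meta_I(x)))
  invisible(x)
}

as_joint <- function(x) {
  if (inherits(x, "joint_table")) return(x)
  if (is.matrix(x)) return(joint_table(x))
  stop("expected a joint_table or a 2-row matrix of counts", call. = FALSE)
}

#' Tabulate trials into a joint accuracy-by-confidence table
#'
#' @param trials A [trial_table].
#' @param scheme A [binning_scheme]; its range must cover the confidences.
#' @param stratify_by_action If `TRUE`, return a list of joint tables, one
#'   per response value present in the data.
#' @param smooth Passed to [joint_table()].
#' @return A `joint_table`, or a named list of them (names `"-1"`, `"1"`)
#'   when `stratify_by_action = TRUE`.
#' @export
joint_from_trials <- function(trials, scheme, stratify_by_action = FALSE,
                              smooth = 0) {
  trials <- as_trial_table(trials)
  if (nrow(trials) == 0L) stop("no trials supplied", call. = FALSE)
  idx <- assign_bins(trials$confidence, scheme)
  b <- n_bins(scheme)
  tab_one <- function(rows) {
    cnt <- matrix(0, 2, b)
    for (r in 0:1) {
      t <- tabulate(idx[rows][trials$accuracy[rows] == r], nbins = b)
      cnt[r + 1, ] <- t
    }
    joint_table(cnt, bins = bin_labels(scheme), smooth = smooth)
  }
  if (!stratify_by_action) return(tab_one(seq_len(nrow(trials))))
  acts <- sort(unique(trials$response))
  out <- lapply(acts, function(a) tab_one(which(trials$response == a)))
  names(out) <- as.character(acts)
  out
}

#' Entropy of the accuracy, H2(r)
#'
#' Binary entropy of the marginal probability correct of a joint table.
#'
#' @param joint A [joint_table] (or 2-row count matrix).
#' @return Entropy in bits.
#' @export
entropy_accuracy <- function(joint) {
  joint <- as_joint(joint)
  binary_entropy(sum(joint$p[2, ]))
}

#' Conditional entropy of accuracy given confidence, H2(r|c)
#'
#' \eqn{\sum_c P(c)\, h_2(P(r = 1 | c))}; bins with zero mass contribute 0.
#'
#' @inheritParams entropy_accuracy
#' @return Conditional entropy in bits.
#' @export
conditional_entropy_accuracy <- function(joint) {
  joint <- as_joint(joint)
  pc <- colSums(joint$p)
  occ <- pc > 0
  if (!any(occ)) return(0)
  sum(pc[occ] * binary_entropy(joint$p[2, occ] / pc[occ]))
}

#' Mutual information between accuracy and confidence (meta-I)
#'
#' The metacognitive-sensitivity measure
#' \eqn{\mathrm{meta}\mbox{-}I = H_2(r) - H_2(r | c)}: how much of the
#' uncertainty about whether the decision was correct is removed by
#' observing the confidence rating.  Measured in bits; it is symmetric
#' (equals \eqn{H_2(c) - H_2(c|r)}) and invariant to relabelling of the
#' confidence bins.
#'
#' @inheritParams entropy_accuracy
#' @return meta-I in bits (non-negative up to floating point).
#' @examples
#' meta_I(rbind(c(138, 5), c(440, 415)))  # 0.094 bits
#' @export
meta_I <- function(joint) {
  joint <- as_joint(joint)
  entropy_accuracy(joint) - conditional_entropy_accuracy(joint)
}

degenerate_joint <- function(joint) {
  pr <- sum(joint$p[2, ])
  pc <- colSums(joint$p)
  pr <= 0 || pr >= 1 || sum(pc > 0) < 2L
}

#' Response-specific meta-I
#'
#' meta-I computed separately on the trials with each response
#' \eqn{a \in \{-1, +1\}}.  A stratum in which all retained trials share a
#' single accuracy value (or a single occupied bin) carries no mutual
#' information; it is reported as 0 with a warning flag rather than an
#' error.
#'
#' @inheritParams joint_from_trials
#' @return Named numeric vector (names `"-1"`, `"1"`) of meta-I values in
#'   bits, with attribute `degenerate`: logical flags per stratum (`NA` for
#'   a stratum with no trials, which is also flagged).
#' @export
meta_I_response_specific <- function(trials, scheme) {
  trials <- as_trial_table(trials)
  acts <- c(-1, 1)
  vals <- numeric(2)
  degen <- logical(2)
  for (i in 1:2) {
    rows <- trials$response == acts[i]
    if (!any(rows)) {
      vals[i] <- NA_real_
      degen[i] <- TRUE
      next
    }
    jt <- joint_from_trials(trials[rows, , drop = FALSE], scheme)
    if (degenerate_joint(jt)) {
      vals[i] <- 0
      degen[i] <- TRUE
      warning("response stratum a = ", acts[i],
              " is degenerate (single accuracy value or occupied bin); ",
              "meta-I set to 0", call. = FALSE)
    } else {
      vals[i] <- meta_I(jt)
    }
  }
  names(vals) <- as.character(acts)
  attr(vals, "degenerate") <- stats::setNames(degen, as.character(acts))
  vals
}

#' Metacognitive efficiency ratios meta-I1r and meta-I2r
#'
#' Normalizes a meta-I value by (i) the meta-I of an ideal first-order
#' rater at the actor's sensitivity, giving the relative efficiency
#' meta-I1r = meta-I / meta-I(d'), and (ii) the entropy of the accuracy,
#' the theoretical upper bound on meta-I, giving the absolute efficiency
#' meta-I2r = meta-I / H2(Phi(d'/2)), which lies in `[0, 1]`.
#'
#' @param meta_I_value meta-I in bits (non-negative).
#' @param d_prime Type-1 sensitivity of the actor (> 0).
#' @param b `"continuous"` (default) to normalize meta-I1r by the
#'   continuous-confidence first-order rater, or an integer number of bins
#'   to use the matched-granularity normalizer [meta_I_dprime_binned()].
#' @return Named numeric vector `c(meta_I1r, meta_I2r)` with attribute
#'   `normalizer` recording the variant used.
#' @export
efficiency_ratios <- function(meta_I_value, d_prime, b = "continuous") {
  if (!is.numeric(d_prime) || d_prime <= 0) {
    stop("`d_prime` must be > 0 (normalizers are undefined otherwise)",
         call. = FALSE)
  }
  if (meta_I_value < 0) {
    if (meta_I_value < -1e-9) {
      stop("`meta_I_value` must be >= 0", call. = FALSE)
    }
    meta_I_value <- 0
  }
  continuous <- identical(b, "continuous")
  norm1 <- if (continuous) meta_I_dprime(d_prime)
           else meta_I_dprime_binned(d_prime, as.integer(b))
  out <- c(meta_I1r = meta_I_value / norm1,
           meta_I2r = meta_I_value / accuracy_entropy(d_prime))
  attr(out, "normalizer") <-
    if (continuous) "continuous" else sprintf("binned(b=%d)", as.integer(b))
  out
}
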