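#' Confidence binning scheme
#'
#' An ordered set of thresholds partitioning the confidence range into
#' `length(thresholds) + 1` half-open bins
#' `[lo, t1), [t1, t2), ..., [t_{b-1}, hi]`; the last bin is closed.  A
#' boundary value falls in the upper bin.
#'
#' @param thresholds Strictly increasing numeric vector of interior
#'   thresholds; may be empty (a single bin).
#' @param range Length-2 numeric confidence range, default `c(0, 1)`.
#' @return An object of class `"binning_scheme"`.
#' @examples
#' binning_scheme(c(0.1, 0.5, 0.9))
#' @export
binning_scheme <- function(thresholds = numeric(), range = c(0, 1)) {
  range <- sort(as.numeric(range))
  thresholds <- as.numeric(thresholds)
  if (length(thresholds)) {
    if (any(diff(thresholds) <= 0)) {
      stop("`thresholds` must be strictly increasing", call. = FALSE)
    }
    if (thresholds[1] <= range[1] ||
        thresholds[length(thresholds)] >= range[2]) {
      stop("`thresholds` must lie strictly inside the confidence range",
           call. = FALSE)
    }
  }
  structure(list(thresholds = thresholds, range = range,
                 b = length(thresholds) + 1L),
            class = "binning_scheme")
}

n_bins <- function(scheme) scheme$b

bin_labels <- function(scheme) {
  e <- c(scheme$range[1], scheme$thresholds, scheme$range[2])
  b <- scheme$b
  sprintf("[%g,%g%s", e[-length(e)], e[-1],
          c(rep(")", b - 1L), "]"))
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("Binning scheme: %d bin(s) on [%g, %g]\n", x$b,
              x$range[1], x$range[2]))
  cat(" ", paste(bin_labels(x), collapse = " "), "\n")
  invisible(x)
}

#' Assign confidences to bins
#'
#' @param confidences Numeric vector within the scheme's range.
#' @param scheme A [binning_scheme].
#' @return Integer bin indices in `1:b`; a value equal to a threshold goes
#'   to the upper bin.
#' @export
assign_bins <- function(confidences, scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  rng <- scheme$range
  bad <- which(!is.finite(confidences) | confidences < rng[1] |
                 confidences > rng[2])
  if (length(bad)) {
    stop(sprintf("confidence %s at position %d is outside [%g, %g]",
                 format(confidences[bad[1]]), bad[1], rng[1], rng[2]),
         call. = FALSE)
  }
  findInterval(confidences, c(rng[1], scheme$thresholds), left.open = FALSE)
}

#' Evenly spaced binning scheme
#'
#' @param b Integer number of bins, at least 2.
#' @param range Confidence range.
#' @return A [binning_scheme] with `b - 1` equally spaced thresholds.
#' @examples
#' even_thresholds(4)$thresholds  # 0.25 0.50 0.75
#' @export
even_thresholds <- function(b, range = c(0, 1)) {
  b <- as.integer(b)
  if (is.na(b) || b < 2L) stop("`b` must be an integer >= 2", call. = FALSE)
  range <- sort(as.numeric(range))
  thr <- range[1] + diff(range) * seq_len(b - 1L) / b
  binning_scheme(thr, range)
}

## ---- weighted threshold optimizer (shared by data, first-order and
## ---- second-order model surfaces) ------------------------------------

## values: confidence values; w: probability weights (need not sum to 1);
## wc: weight that is also correct (0 <= wc <= w).  Maximizes the mutual
## information of the 2 x b table induced by thresholds on `values`.
opt_bins_weighted <- function(values, w, wc, b, range, grid = 200,
                              n_starts = 10, seed = NULL) {
  b <- as.integer(b)
  if (b < 2L) stop("`b` must be >= 2", call. = FALSE)
  ord <- order(values)
  v <- values[ord]
  w <- w[ord]
  wc <- wc[ord]
  tot <- sum(w)
  w <- w / tot
  wc <- wc / tot
  dup <- duplicated(v)
  vd <- v[!dup]
  if (length(vd) < b) {
    stop(sprintf("need at least %d distinct confidence values for %d bins",
                 b, b), call. = FALSE)
  }
  ## candidate thresholds: midpoints between consecutive distinct values
  cand <- (vd[-1] + vd[-length(vd)]) / 2
  if (length(cand) > grid) {
    ## thin to ~grid candidates, evenly spaced through the sorted list
    keep <- unique(round(seq(1, length(cand), length.out = grid)))
    cand <- cand[keep]
  }
  nc <- length(cand)
  ## cumulative weight strictly below each candidate threshold
  pos <- findInterval(cand, v)          # v[i] <= cand < v[i+1]
  cw <- cumsum(w)
  cwc <- cumsum(wc)
  cumW <- cw[pos]
  cumWC <- cwc[pos]
  totC <- sum(wc)
  h2r <- binary_entropy(totC)

  mi_of <- function(idx) {
    ## idx: strictly increasing candidate indices, length b - 1
    mw <- diff(c(0, cumW[idx], 1))
    mc <- diff(c(0, cumWC[idx], totC))
    occ <- mw > 0
    h2r - sum(mw[occ] * binary_entropy(pmin(pmax(mc[occ] / mw[occ], 0), 1)))
  }

  best_idx <- NULL
  best_mi <- -Inf
  consider <- function(idx, mi) {
    if (is.null(best_idx) || mi > best_mi + 1e-15) {
      best_mi <<- mi
      best_idx <<- idx
    } else if (mi >= best_mi - 1e-15) {
      d <- which(idx != best_idx)     # tie: keep smallest threshold vector
      if (length(d) && idx[d[1]] < best_idx[d[1]]) best_idx <<- idx
    }
  }

  if (b == 2L) {
    mis <- vapply(seq_len(nc), function(i) mi_of(i), numeric(1))
    best_i <- which.max(mis)            # first max: lexicographically smallest
    best_idx <- best_i
    best_mi <- mis[best_i]
  } else if (b == 3L) {
    for (i in seq_len(nc - 1L)) {
      mis <- vapply((i + 1L):nc, function(j) mi_of(c(i, j)), numeric(1))
      j <- which.max(mis)
      if (mis[j] > best_mi + 1e-15) {
        best_mi <- mis[j]
        best_idx <- c(i, i + j)
      }
    }
  } else {
    ascent <- function(idx) {
      repeat {
        changed <- FALSE
        for (k in seq_len(b - 1L)) {
          lo <- if (k == 1L) 1L else idx[k - 1L] + 1L
          hi <- if (k == b - 1L) nc else idx[k + 1L] - 1L
          if (lo > hi) next
          sweep_idx <- lo:hi
          mis <- vapply(sweep_idx, function(j) {
            tmp <- idx; tmp[k] <- j; mi_of(tmp)
          }, numeric(1))
          jbest <- sweep_idx[which.max(mis)]
          if (jbest != idx[k] && max(mis) > mi_of(idx) + 1e-15) {
            idx[k] <- jbest
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      idx
    }
    starts <- list(unique(pmin(nc, pmax(1L, round(seq(1, nc,
                                                      length.out = b + 1L))[2:b]))))
    if (length(starts[[1]]) != b - 1L) {
      starts <- list(seq_len(b - 1L))
    }
    extra <- with_seed(seed, {
      lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
        sort(sample.int(nc, b - 1L))
      })
    })
    for (st in c(starts, extra)) {
      idx <- ascent(st)
      consider(idx, mi_of(idx))
    }
  }
  list(scheme = binning_scheme(cand[best_idx], range), meta_I = best_mi)
}

## run expr with a temporary RNG state (no-op pass-through if seed NULL)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Optimize confidence-bin thresholds to maximize meta-I
#'
#' Searches for the `b - 1` thresholds that maximize the mutual
#' information between accuracy and binned confidence.  Candidate
#' thresholds are midpoints between consecutive distinct observed
#' confidences (thinned to at most `grid` candidates); the search is
#' exhaustive for `b <= 3` and greedy coordinate ascent with seeded
#' multi-start for larger `b`.  For a [second_order_observer] the exact
#' model surface (quadrature node masses) is optimized instead of sampled
#' data.
#'
#' @param x A [trial_table] or a [second_order_observer].
#' @param b Number of bins (>= 2).
#' @param ... Passed to methods.
#' @return A list with elements `scheme` (the [binning_scheme]) and
#'   `meta_I` (its meta-I in bits, which equals `meta_I()` of the joint
#'   table built with the returned scheme).
#' @export
optimize_thresholds <- function(x, b, ...) UseMethod("optimize_thresholds")

#' @rdname optimize_thresholds
#' @param grid Maximum number of candidate thresholds retained (default 200).
#' @param n_starts Multi-start count for the `b > 3` coordinate ascent.
#' @param seed Integer seed making the multi-start deterministic.
#' @export
optimize_thresholds.trial_table <- function(x, b, grid = 200, n_starts = 10,
                                            seed = NULL, ...) {
  rng <- attr(x, "conf_range")
  opt_bins_weighted(x$confidence, rep(1, nrow(x)), as.numeric(x$accuracy),
                    b, rng, grid = grid, n_starts = n_starts, seed = seed)
}

#' Granularity curve: gain of extra confidence bins
#'
#' Ratio of the optimized meta-I at each requested number of bins to the
#' optimized meta-I at 2 bins.  Up to optimizer tolerance the ratios are
#' `>= 1` and non-decreasing in `b` (a finer partition can only add
#' information).
#'
#' @inheritParams optimize_thresholds.trial_table
#' @param x A [trial_table] (or anything [optimize_thresholds()] accepts).
#' @param b_values Integer vector of bin counts, all `>= 2`.
#' @return Data frame with columns `b`, `meta_I`, `ratio`.
#' @export
granularity_curve <- function(x, b_values = c(2, 4, 8, 16), grid = 200,
                              n_starts = 10, seed = NULL, ...) {
  b_values <- as.integer(b_values)
  if (any(b_values < 2L)) stop("all `b_values` must be >= 2", call. = FALSE)
  opt <- lapply(b_values, function(b) {
    optimize_thresholds(x, b, grid = grid, n_starts = n_starts,
                        seed = seed, ...)$meta_I
  })
  mi <- unlist(opt)
  base <- if (2L %in% b_values) mi[match(2L, b_values)] else {
    optimize_thresholds(x, 2L, grid = grid, n_starts = n_starts,
                        seed = seed, ...)$meta_I
  }
  data.frame(b = b_values, meta_I = mi, ratio = mi / base)
}
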