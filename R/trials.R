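#' Trial-level confidence data
#'
#' Assembles one row per trial of a binary decision task: the stimulus
#' \eqn{d = \pm 1}, the response \eqn{a = \pm 1}, and a confidence rating
#' `c` in the declared range.  Accuracy is always derived as
#' \eqn{r = 1} iff \eqn{d = a}; a stored accuracy column is never trusted.
#'
#' @param stimulus Integer/numeric vector of -1/+1 stimulus identities.
#' @param response Integer/numeric vector of -1/+1 responses.
#' @param confidence Numeric confidence ratings within `range`.
#' @param range Length-2 numeric, the confidence scale, e.g. `c(0, 1)` or
#'   `c(0.5, 1)`.
#' @param subject,condition Optional grouping labels, recycled to length.
#' @return A data frame of class `"trial_table"` with columns `stimulus`,
#'   `response`, `confidence`, `accuracy` (0/1) and any labels, carrying
#'   the confidence range as attribute `conf_range`.
#' @examples
#' tt <- trial_table(c(1, -1, 1, 1), c(1, 1, 1, -1),
#'                   c(0.9, 0.6, 0.8, 0.6), range = c(0.5, 1))
#' tt$accuracy  # 1 0 1 0
#' @export
trial_table <- function(stimulus, response, confidence, range = c(0, 1),
                        subject = NULL, condition = NULL) {
  n <- length(confidence)
  if (length(stimulus) != n || length(response) != n) {
    stop("`stimulus`, `response` and `confidence` must have equal length",
         call. = FALSE)
  }
  if (n == 0L) stop("no trials supplied", call. = FALSE)
  check_pm1 <- function(x, what) {
    bad <- which(!(x %in% c(-1, 1)))
    if (length(bad)) {
      stop(sprintf("%s must be -1 or +1 (first offending trial: row %d, value %s)",
                   what, bad[1], format(x[bad[1]])), call. = FALSE)
    }
  }
  check_pm1(stimulus, "`stimulus`")
  check_pm1(response, "`response`")
  range <- sort(as.numeric(range))
  bad <- which(!is.finite(confidence) | confidence < range[1] |
                 confidence > range[2])
  if (length(bad)) {
    stop(sprintf("confidence outside declared range [%g, %g] at row %d (value %s)",
                 range[1], range[2], bad[1], format(confidence[bad[1]])),
         call. = FALSE)
  }
  out <- data.frame(stimulus = as.integer(stimulus),
                    response = as.integer(response),
                    confidence = as.numeric(confidence),
                    accuracy = as.integer(stimulus == response))
  if (!is.null(subject)) out$subject <- rep_len(as.character(subject), n)
  if (!is.null(condition)) out$condition <- rep_len(as.character(condition), n)
  structure(out, conf_range = range,
            class = c("trial_table", "data.frame"))
}

as_trial_table <- function(x) {
  if (inherits(x, "trial_table")) return(x)
  if (is.data.frame(x) &&
      all(c("stimulus", "response", "confidence") %in% names(x))) {
    rng <- attr(x, "conf_range")
    if (is.null(rng)) rng <- c(min(0, min(x$confidence)), max(1, max(x$confidence)))
    return(trial_table(x$stimulus, x$response, x$confidence, range = rng,
                       subject = x$subject, condition = x$condition))
  }
  stop("expected a trial_table or a data frame with columns ",
       "stimulus/response/confidence", call. = FALSE)
}

#' @export
print.trial_table <- function(x, ...) {
  rng <- attr(x, "conf_range")
  cat(sprintf("Trial table: %d trials, confidence on [%g, %g], accuracy %.3f\n",
              nrow(x), rng[1], rng[2], mean(x$accuracy)))
  NextMethod()
}

#' Read trial-level data from a delimited text file
#'
#' Reads a header-ed delimited file with (at least) stimulus, response and
#' confidence columns, validates it, and derives accuracy.
#'
#' @param path File path.
#' @param columns Named character vector mapping the required fields to
#'   column names in the file, default
#'   `c(stimulus = "stimulus", response = "response", confidence = "confidence")`.
#' @param range Declared confidence scale (see [trial_table()]).
#' @param sep Field separator (default comma).
#' @return A [trial_table].
#' @export
read_trials <- function(path,
                        columns = c(stimulus = "stimulus",
                                    response = "response",
                                    confidence = "confidence"),
                        range = c(0, 1), sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- columns[c("stimulus", "response", "confidence")]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  trial_table(df[[need[["stimulus"]]]], df[[need[["response"]]]],
              df[[need[["confidence"]]]], range = range,
              subject = df[["subject"]], condition = df[["condition"]])
}

#' Write trial-level data to a delimited text file
#'
#' @param trials A [trial_table].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, sep = ",") {
  trials <- as_trial_table(trials)
  utils::write.table(trials, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
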