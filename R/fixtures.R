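#' Worked-example joint counts
#'
#' The binarized accuracy-by-confidence counts of the in-text worked
#' example (one subject, easiest condition, confidence binarized at
#' 0.72): 415 correct/high, 440 correct/low, 5 incorrect/high,
#' 138 incorrect/low.
#'
#' @return A [joint_table] with bins `low`, `high` (998 trials).
#' @examples
#' meta_I(worked_example_counts())  # 0.094 bits
#' @export
worked_example_counts <- function() {
  joint_table(rbind(c(138, 5), c(440, 415)), bins = c("low", "high"))
}

#' Generate the package's reference fixture datasets
#'
#' Writes small delimited-text datasets used in examples and tests:
#' the worked-example count table; sampled second-order datasets at the
#' three reference parameterizations (d' = 1, B = 1 with unique-noise
#' variance 5 and 0.5, plus a near-first-order limit with B = 0.05 and
#' large unique noise); and an independence dataset (confidence shuffled
#' against accuracy) for bias-correction checks.  All sampling is seeded;
#' regenerating with the same seed reproduces the files byte-for-byte.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n Trials per sampled dataset (default 2000).
#' @return Data frame manifest (one row per file with its generator
#'   parameters), also written to `manifest.csv` in `dir`; invisibly.
#' @export
make_fixtures <- function(dir, seed = 1, n = 2000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(file, what, params) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, what = what, params = params)
  }

  jt <- worked_example_counts()
  cnt <- rbind(`0` = c(138, 5), `1` = c(440, 415))
  utils::write.csv(data.frame(r = rownames(cnt), low = cnt[, 1],
                              high = cnt[, 2]),
                   file.path(dir, "worked_example_counts.csv"),
                   row.names = FALSE, quote = FALSE)
  add("worked_example_counts.csv", "binarized joint counts",
      "threshold 0.72 on [0.5, 1]")

  cases <- list(
    c(file = "so_g2_5.csv", d_prime = 1, b_noise = 1, g2 = 5),
    c(file = "so_g2_0.5.csv", d_prime = 1, b_noise = 1, g2 = 0.5),
    c(file = "so_first_order_limit.csv", d_prime = 1, b_noise = 0.05,
      g2 = 1000)
  )
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    obs <- second_order_observer(as.numeric(cs["d_prime"]),
                                 as.numeric(cs["b_noise"]),
                                 as.numeric(cs["g2"]))
    tt <- simulate(obs, nsim = n, seed = seed + i)
    write_trials(tt, file.path(dir, cs[["file"]]))
    add(cs[["file"]], "sampled second-order trials",
        sprintf("d'=%s B=%s G^2=%s n=%d seed=%d", cs["d_prime"],
                cs["b_noise"], cs["g2"], n, seed + i))
  }

  ## independence dataset: confidence permuted against accuracy
  obs <- second_order_observer(1, 1, 0.5)
  tt <- simulate(obs, nsim = n, seed = seed + 10)
  tt$confidence <- with_seed(seed + 11,
                             tt$confidence[sample.int(nrow(tt))])
  write_trials(tt, file.path(dir, "independent.csv"))
  add("independent.csv", "confidence shuffled against accuracy",
      sprintf("base d'=1 B=1 G^2=0.5 n=%d seed=%d/%d", n, seed + 10,
              seed + 11))

  mf <- do.call(rbind, manifest)
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(mf)
}
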