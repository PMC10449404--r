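# independent oracles kept deliberately naive

# mutual information by the direct double sum over the joint table
mi_direct <- function(counts) {
  p <- counts / sum(counts)
  pr <- rowSums(p)
  pc <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        s <- s + p[i, j] * log2(p[i, j] / (pr[i] * pc[j]))
      }
    }
  }
  s
}

# per-trial loop tally of (accuracy, bin) combinations
count_bins_loop <- function(r, confidence, edges) {
  b <- length(edges) - 1L
  cnt <- matrix(0, 2, b)
  for (t in seq_along(r)) {
    j <- b
    for (k in seq_len(b - 1L)) {
      if (confidence[t] < edges[k + 1L]) {
        j <- k
        break
      }
    }
    cnt[r[t] + 1L, j] <- cnt[r[t] + 1L, j] + 1
  }
  cnt
}

# exhaustive single-threshold scan over all midpoints of consecutive
# distinct confidence values
best_split_exhaustive <- function(r, confidence) {
  v <- sort(unique(confidence))
  cands <- (v[-1] + v[-length(v)]) / 2
  best <- -Inf
  best_t <- NA
  for (t in cands) {
    hi <- confidence >= t
    cnt <- rbind(c(sum(!hi & r == 0), sum(hi & r == 0)),
                 c(sum(!hi & r == 1), sum(hi & r == 1)))
    mi <- mi_direct(cnt)
    if (mi > best + 1e-15) {
      best <- mi
      best_t <- t
    }
  }
  list(threshold = best_t, meta_I = best)
}

# expected first-order type-2 statistics for an unbiased observer:
# per-bin mass and accuracy for one response side, criteria below 0
fo_type2_stats <- function(d_prime, t2) {
  m <- d_prime / 2
  edges <- c(-Inf, rev(t2), 0)
  pc <- diff(pnorm(edges, -m)) / pnorm(0, -m)
  pi <- diff(pnorm(edges, m)) / pnorm(0, m)
  wC <- pnorm(0, -m) / (pnorm(0, -m) + pnorm(0, m))
  mass <- rev(pc) * wC + rev(pi) * (1 - wC)
  data.frame(mass = mass, accuracy = rev(pc) * wC / mass)
}
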