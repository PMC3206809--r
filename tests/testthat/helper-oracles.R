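# Independent oracles used to cross-check the implementation.

# Brute-force signed KS score: ECDFs evaluated literally at every pooled
# value, sign from the same median/mean convention.
oracle_signed_ks <- function(treated, control) {
  grid <- sort(unique(c(treated, control)))
  d <- 0
  for (v in grid) {
    d <- max(d, abs(mean(treated <= v) - mean(control <= v)))
  }
  if (d == 0) {
    return(0)
  }
  s <- sign(median(treated) - median(control))
  if (s == 0) s <- sign(mean(treated) - mean(control))
  if (s == 0) {
    return(0)
  }
  s * d
}

# Naive leave-one-out Spearman maximiser (loops, stats::cor only).
oracle_spearman_outlier <- function(x, y, max_outliers = 1) {
  rho_full <- suppressWarnings(cor(x, y, method = "spearman"))
  if (max_outliers == 0) {
    return(list(rho = rho_full, outlier = NA_integer_))
  }
  best <- rho_full
  best_i <- NA_integer_
  for (i in seq_along(x)) {
    r <- suppressWarnings(cor(x[-i], y[-i], method = "spearman"))
    if (!is.na(r) && (is.na(best) || r > best)) {
      best <- r
      best_i <- i
    }
  }
  list(rho = best, outlier = best_i)
}

# Naive exhaustive weight optimisation, written independently of the
# package internals: expand.grid enumeration, per-vector loops.
oracle_optimize <- function(S, y, max_outliers = 1, clip = TRUE) {
  m <- ncol(S)
  grids <- rep(list(0:2), m)
  W <- as.matrix(expand.grid(grids))
  achieved <- matrix(NA_integer_, nrow = 0, ncol = m)
  for (r in seq_len(nrow(W))) {
    e <- as.numeric(S %*% W[r, ])
    if (clip) e <- pmax(e, 0)
    rho <- oracle_spearman_outlier(e, y, max_outliers)$rho
    if (!is.na(rho) && rho > 1 - 1e-9) achieved <- rbind(achieved, W[r, ])
  }
  if (nrow(achieved) == 0) {
    return(NULL)
  }
  weights <- apply(achieved, 2, function(col) {
    cnt <- tabulate(col + 1L, 3L)
    which.max(cnt) - 1L # which.max ties -> first, i.e. smallest weight
  })
  list(
    weights = unname(weights),
    count = nrow(achieved),
    freq = apply(achieved, 2, function(col) tabulate(col + 1L, 3L))
  )
}
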