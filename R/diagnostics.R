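# MCMC convergence diagnostics (split-Rhat and a basic effective sample
# size). Self-contained because no dedicated diagnostics package is a
# dependency; formulas are the standard split-chain potential scale
# reduction factor and the autocorrelation-sum ESS with Geyer's initial
# positive sequence truncation.

.split_halves <- function(x, chain) {
  segs <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    n <- length(v) %/% 2L
    segs <- c(segs, list(v[seq_len(n)], v[n + seq_len(n)]))
  }
  segs
}

.split_rhat <- function(x, chain) {
  segs <- .split_halves(x, chain)
  m <- length(segs)
  n <- length(segs[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(segs, mean, 0)
  vars <- vapply(segs, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess_basic <- function(x, chain) {
  segs <- .split_halves(x, chain)
  n <- length(segs[[1]])
  if (n < 4L) return(NA_real_)
  # average autocorrelation across segments, Geyer initial positive pairs
  max_lag <- min(n - 2L, 200L)
  acf_avg <- rowMeans(vapply(segs, function(v) {
    if (stats::var(v) == 0) return(rep(0, max_lag + 1L))
    stats::acf(v, lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[, 1, 1]
  }, numeric(max_lag + 1L)))
  s <- 0
  lag <- 1L
  while (lag + 1L <= max_lag) {
    pair <- acf_avg[lag + 1L] + acf_avg[lag + 2L]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    lag <- lag + 2L
  }
  total <- length(segs) * n
  max(1, total / (1 + 2 * s))
}
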