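# Monte-Carlo oracle for the model's category distribution: draw latent
# appraisals around the consensus location and bin them by the
# team-shifted thresholds.
mc_category_oracle <- function(T, lam, beta, gamma, n = 1e5, seed = 1) {
  set.seed(seed)
  y <- rnorm(n, T, lam)
  cuts <- c(-Inf, gamma + beta, Inf)
  tabulate(findInterval(y, cuts), nbins = length(gamma) + 1L) / n
}

# Independent fine-grid trapezoid quadrature for the Pearson correlation
# Bayes factors (the implementation uses adaptive quadrature instead).
pearson_grid_oracle <- function(x, y, kappa = 1, n_grid = 200001L) {
  n <- length(x)
  r <- cor(x, y)
  grid <- seq(-1 + 1e-8, 1 - 1e-8, length.out = n_grid)
  lik <- vapply(grid, function(p) sees:::.pearson_r_density(r, p, n), 0)
  lik <- lik / sees:::.pearson_r_density(r, 0, n)
  pri <- sees:::.dsbeta(grid, kappa)
  trap <- function(v, g) sum((v[-1] + v[-length(v)]) / 2 * diff(g))
  pos <- grid >= 0
  m_all <- trap(lik * pri, grid)
  m_pos <- trap((lik * pri)[pos], grid[pos])
  prior_pos <- trap(pri[pos], grid[pos])
  list(bf10 = m_all,
       bf_plus0 = m_pos / prior_pos,
       bf_minus0 = (m_all - m_pos) / (1 - prior_pos))
}

# light model configuration for fast fits in unit tests
tiny_config <- function(seed = 1L) {
  model_config(chains = 2L, draws_per_chain = 300L, warmup = 300L,
               seed = seed)
}

synthetic_instrument <- function(items, C = 4L) {
  sees:::.synthetic_instrument(items, C)
}
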