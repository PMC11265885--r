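#' Response-category probability of the latent truth rater model
#'
#' In the ordinal cultural-consensus (latent truth rater) model a team's
#' appraisal of item `i` is a noisy draw around the item's consensus
#' location `T` with item-specific dispersion `lam` ("difficulty"), and
#' is mapped to a response category by ordered thresholds shifted by the
#' team's scepticism `beta`:
#' \deqn{P(X = c) = \Phi\!\left(\frac{\gamma_c + \beta - T}{\lambda}\right)
#'   - \Phi\!\left(\frac{\gamma_{c-1} + \beta - T}{\lambda}\right)}
#' with \eqn{\gamma_0 = -\infty}, \eqn{\gamma_C = +\infty}. Larger
#' `beta` pushes responses toward lower categories; larger `lam` makes
#' responses to the item more polarized.
#'
#' @param T Consensus location (scalar).
#' @param lam Item dispersion, `> 0`.
#' @param beta Scepticism threshold shift.
#' @param gamma Strictly increasing thresholds, length `C - 1`.
#' @param c Category index in `1..C`; may be a vector.
#' @return Probability (vector over `c`).
#' @examples
#' sum(category_probability(0, 1, 0, c(-1, 0, 1), 1:4)) # 1
#' @export
category_probability <- function(T, lam, beta, gamma, c) {
  if (any(lam <= 0)) stop("lam must be > 0", call. = FALSE)
  if (length(gamma) < 1L || is.unsorted(gamma, strictly = TRUE)) {
    stop("gamma must be strictly increasing", call. = FALSE)
  }
  C <- length(gamma) + 1L
  if (any(c < 1L | c > C)) stop("category index out of range", call. = FALSE)
  g <- c(-Inf, gamma, Inf)
  stats::pnorm((g[c + 1L] + beta - T) / lam) -
    stats::pnorm((g[c] + beta - T) / lam)
}

# Pointwise log-likelihood matrix of a response table.
#
# X: K x I integer matrix with NA for missing; T, lam length I; beta
# length K; gamma length C-1. Missing cells contribute 0 (ignorable
# missingness). Returns K x I matrix.
.ltrm_loglik_matrix <- function(X, T, lam, beta, gamma) {
  K <- nrow(X); I <- ncol(X)
  g <- c(-Inf, gamma, Inf)
  Xi <- X
  Xi[is.na(Xi)] <- 1L # placeholder, masked below
  GU <- matrix(g[Xi + 1L], K, I)
  GL <- matrix(g[Xi], K, I)
  Tm <- matrix(T, K, I, byrow = TRUE)
  Lm <- matrix(lam, K, I, byrow = TRUE)
  Bm <- matrix(beta, K, I)
  p <- stats::pnorm((GU + Bm - Tm) / Lm) - stats::pnorm((GL + Bm - Tm) / Lm)
  ll <- log(pmax(p, 1e-300))
  ll[is.na(X)] <- 0
  ll
}
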