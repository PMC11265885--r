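#' Configuration for fitting the consensus model
#'
#' @param C Number of response categories.
#' @param chains Number of MCMC chains (>= 2).
#' @param draws_per_chain Post-warmup draws kept per chain.
#' @param warmup Adaptation iterations discarded per chain.
#' @param seed Integer seed; chain `j` uses `seed + j - 1`.
#' @param priors Named list of prior scales: `hyper_mean_scale` (sd of the
#'   normal prior on the subscale hyper-mean), `hyper_sd_scale`
#'   (half-normal scale of the consensus hyper-sd), `scepticism_sd_scale`
#'   (half-normal scale of the scepticism sd), `difficulty_log_scale`
#'   (sd of the normal prior on log difficulty), `threshold_loc_scale`
#'   (sd of the prior on the first threshold), `threshold_logstep_scale`
#'   (sd of the prior on log threshold increments). All must be > 0.
#' @param target_accept Target acceptance rate of the adaptive
#'   random-walk Metropolis updates (per scalar coordinate).
#' @return A `sees_model_config` list.
#' @export
model_config <- function(C = 4L, chains = 4L, draws_per_chain = 1000L,
                         warmup = 1000L, seed = 1L,
                         priors = list(), target_accept = 0.44) {
  defaults <- list(hyper_mean_scale = 1, hyper_sd_scale = 1,
                   scepticism_sd_scale = 1, difficulty_log_scale = 0.5,
                   threshold_loc_scale = 2, threshold_logstep_scale = 1)
  priors <- utils::modifyList(defaults, priors)
  stopifnot(C >= 2L, chains >= 2L, draws_per_chain >= 100L, warmup >= 100L,
            all(unlist(priors) > 0), target_accept > 0, target_accept < 1)
  structure(list(C = as.integer(C), chains = as.integer(chains),
                 draws_per_chain = as.integer(draws_per_chain),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 priors = priors, target_accept = target_accept),
            class = "sees_model_config")
}

# One adaptive Metropolis-within-Gibbs chain for the latent truth rater
# model. Block structure exploits conditional independence: each T_i and
# lambda_i touches only column i of the likelihood matrix, each beta_k
# only row k, so whole vectors are proposed at once and accepted
# coordinate-wise. The hyper-mean is updated by an exact Gibbs step.
.ltrm_chain <- function(X, C, warmup, draws, priors, seed, target_accept) {
  set.seed(seed)
  K <- nrow(X); I <- ncol(X)
  n_gpar <- C - 1L

  # empirical initial values
  freq <- tabulate(X[!is.na(X)], nbins = C)
  cum <- pmin(pmax(cumsum(freq / sum(freq))[seq_len(C - 1L)], 0.02), 0.98)
  g1 <- stats::qnorm(cum[1])
  logstep <- if (C > 2L) log(pmax(diff(stats::qnorm(cum)), 0.05)) else numeric(0)
  T <- (colMeans(X, na.rm = TRUE) - mean(X, na.rm = TRUE)) * 0.8
  T[is.na(T)] <- 0
  loglam <- rep(0, I)
  beta <- rep(0, K)
  mu <- mean(T)
  logsigma <- 0
  logsigma_beta <- log(0.5)

  gamma_of <- function(g1, logstep) g1 + cumsum(c(0, exp(logstep)))
  gamma <- gamma_of(g1, logstep)

  cur <- .ltrm_loglik_matrix(X, T, exp(loglam), beta, gamma)

  # adaptive step sizes (log scale)
  lsT <- rep(log(0.5), I); lsL <- rep(log(0.4), I); lsB <- rep(log(0.6), K)
  lsG <- rep(log(0.25), n_gpar); lsS <- log(0.5); lsSB <- log(0.5)
  lsR <- rep(log(0.3), 3L) # ridge moves: threshold/scepticism shift, scale
  accT <- numeric(I); accL <- numeric(I); accB <- numeric(K)
  accG <- numeric(n_gpar); accS <- 0; accSB <- 0; accR <- numeric(3L)

  # joint log-prior in sampled coordinates (log-scale parameters carry
  # their half-normal priors plus Jacobian); used by the ridge moves,
  # which leave the likelihood exactly invariant
  logprior_all <- function(T, loglam, beta, g1, logstep, mu, logsigma,
                           logsigma_beta) {
    sigma <- exp(logsigma); sigma_beta <- exp(logsigma_beta)
    sum(stats::dnorm(T, mu, sigma, log = TRUE)) +
      sum(stats::dnorm(loglam, 0, priors$difficulty_log_scale, log = TRUE)) +
      sum(stats::dnorm(beta, 0, sigma_beta, log = TRUE)) +
      stats::dnorm(g1, 0, priors$threshold_loc_scale, log = TRUE) +
      sum(stats::dnorm(logstep, 0, priors$threshold_logstep_scale,
                       log = TRUE)) +
      stats::dnorm(mu, 0, priors$hyper_mean_scale, log = TRUE) +
      stats::dnorm(sigma, 0, priors$hyper_sd_scale, log = TRUE) + logsigma +
      stats::dnorm(sigma_beta, 0, priors$scepticism_sd_scale, log = TRUE) +
      logsigma_beta
  }

  total <- warmup + draws
  keep <- list(T = matrix(NA_real_, draws, I),
               lam = matrix(NA_real_, draws, I),
               beta = matrix(NA_real_, draws, K),
               gamma = matrix(NA_real_, draws, n_gpar),
               mu = numeric(draws), sigma = numeric(draws),
               sigma_beta = numeric(draws))
  batch <- 0L

  for (it in seq_len(total)) {
    sigma <- exp(logsigma); sigma_beta <- exp(logsigma_beta)

    # -- consensus locations T (column-wise vector update)
    propT <- T + exp(lsT) * stats::rnorm(I)
    prop_ll <- .ltrm_loglik_matrix(X, propT, exp(loglam), beta, gamma)
    logr <- colSums(prop_ll) - colSums(cur) +
      stats::dnorm(propT, mu, sigma, log = TRUE) -
      stats::dnorm(T, mu, sigma, log = TRUE)
    acc <- log(stats::runif(I)) < logr
    T[acc] <- propT[acc]; cur[, acc] <- prop_ll[, acc]; accT <- accT + acc

    # -- log difficulties (column-wise)
    propL <- loglam + exp(lsL) * stats::rnorm(I)
    prop_ll <- .ltrm_loglik_matrix(X, T, exp(propL), beta, gamma)
    logr <- colSums(prop_ll) - colSums(cur) +
      stats::dnorm(propL, 0, priors$difficulty_log_scale, log = TRUE) -
      stats::dnorm(loglam, 0, priors$difficulty_log_scale, log = TRUE)
    acc <- log(stats::runif(I)) < logr
    loglam[acc] <- propL[acc]; cur[, acc] <- prop_ll[, acc]; accL <- accL + acc

    # -- scepticism shifts (row-wise)
    propB <- beta + exp(lsB) * stats::rnorm(K)
    prop_ll <- .ltrm_loglik_matrix(X, T, exp(loglam), propB, gamma)
    logr <- rowSums(prop_ll) - rowSums(cur) +
      stats::dnorm(propB, 0, sigma_beta, log = TRUE) -
      stats::dnorm(beta, 0, sigma_beta, log = TRUE)
    acc <- log(stats::runif(K)) < logr
    beta[acc] <- propB[acc]; cur[acc, ] <- prop_ll[acc, ]; accB <- accB + acc

    # -- thresholds: first location, then log increments
    gpar <- c(g1, logstep)
    for (j in seq_len(n_gpar)) {
      propg <- gpar
      propg[j] <- propg[j] + exp(lsG[j]) * stats::rnorm(1)
      pg <- gamma_of(propg[1], propg[-1])
      prop_ll <- .ltrm_loglik_matrix(X, T, exp(loglam), beta, pg)
      lp_prop <- stats::dnorm(propg[1], 0, priors$threshold_loc_scale,
                              log = TRUE) +
        sum(stats::dnorm(propg[-1], 0, priors$threshold_logstep_scale,
                         log = TRUE))
      lp_cur <- stats::dnorm(gpar[1], 0, priors$threshold_loc_scale,
                             log = TRUE) +
        sum(stats::dnorm(gpar[-1], 0, priors$threshold_logstep_scale,
                         log = TRUE))
      if (log(stats::runif(1)) < sum(prop_ll) - sum(cur) + lp_prop - lp_cur) {
        gpar <- propg; cur <- prop_ll; accG[j] <- accG[j] + 1
      }
    }
    g1 <- gpar[1]; logstep <- gpar[-1]; gamma <- gamma_of(g1, logstep)

    # -- hyper-mean: exact Gibbs (normal prior x normal likelihood)
    v <- 1 / (1 / priors$hyper_mean_scale^2 + I / sigma^2)
    mu <- stats::rnorm(1, v * sum(T) / sigma^2, sqrt(v))

    # -- consensus hyper-sd (log-scale MH; half-normal prior + Jacobian)
    prop <- logsigma + exp(lsS) * stats::rnorm(1)
    logr <- sum(stats::dnorm(T, mu, exp(prop), log = TRUE)) -
      sum(stats::dnorm(T, mu, exp(logsigma), log = TRUE)) +
      stats::dnorm(exp(prop), 0, priors$hyper_sd_scale, log = TRUE) -
      stats::dnorm(exp(logsigma), 0, priors$hyper_sd_scale, log = TRUE) +
      prop - logsigma
    if (log(stats::runif(1)) < logr) { logsigma <- prop; accS <- accS + 1 }

    # -- scepticism sd
    prop <- logsigma_beta + exp(lsSB) * stats::rnorm(1)
    logr <- sum(stats::dnorm(beta, 0, exp(prop), log = TRUE)) -
      sum(stats::dnorm(beta, 0, exp(logsigma_beta), log = TRUE)) +
      stats::dnorm(exp(prop), 0, priors$scepticism_sd_scale, log = TRUE) -
      stats::dnorm(exp(logsigma_beta), 0, priors$scepticism_sd_scale,
                   log = TRUE) +
      prop - logsigma_beta
    if (log(stats::runif(1)) < logr) { logsigma_beta <- prop; accSB <- accSB + 1 }

    # -- ridge moves: the likelihood depends on parameters only through
    # (gamma_c + beta_k - T_i) / lambda_i, so a common shift of
    # (thresholds, locations), a common shift of (scepticism, locations),
    # and a common rescaling of everything are invariant directions that
    # coordinate-wise updates traverse slowly; Metropolis moves along
    # them use only the prior ratio.
    lp_cur <- logprior_all(T, loglam, beta, g1, logstep, mu, logsigma,
                           logsigma_beta)
    d <- exp(lsR[1]) * stats::rnorm(1)
    lp_new <- logprior_all(T + d, loglam, beta, g1 + d, logstep, mu + d,
                           logsigma, logsigma_beta)
    if (log(stats::runif(1)) < lp_new - lp_cur) {
      T <- T + d; g1 <- g1 + d; mu <- mu + d
      gamma <- gamma_of(g1, logstep)
      lp_cur <- lp_new; accR[1] <- accR[1] + 1
    }
    d <- exp(lsR[2]) * stats::rnorm(1)
    lp_new <- logprior_all(T + d, loglam, beta + d, g1, logstep, mu + d,
                           logsigma, logsigma_beta)
    if (log(stats::runif(1)) < lp_new - lp_cur) {
      T <- T + d; beta <- beta + d; mu <- mu + d
      lp_cur <- lp_new; accR[2] <- accR[2] + 1
    }
    eps <- exp(lsR[3]) * stats::rnorm(1)
    phi <- exp(eps)
    lp_new <- logprior_all(phi * T, loglam + eps, phi * beta, phi * g1,
                           logstep + eps, phi * mu, logsigma + eps,
                           logsigma_beta + eps)
    # log-Jacobian of the multiplicative coordinates (T, beta, g1, mu)
    if (log(stats::runif(1)) < lp_new - lp_cur + (I + K + 2) * eps) {
      T <- phi * T; beta <- phi * beta; g1 <- phi * g1; mu <- phi * mu
      loglam <- loglam + eps; logstep <- logstep + eps
      logsigma <- logsigma + eps; logsigma_beta <- logsigma_beta + eps
      gamma <- gamma_of(g1, logstep)
      cur <- .ltrm_loglik_matrix(X, T, exp(loglam), beta, gamma)
      accR[3] <- accR[3] + 1
    }

    # -- step-size adaptation in batches of 50 during warmup
    if (it <= warmup && it %% 50L == 0L) {
      batch <- batch + 1L
      rate <- min(0.9, 5 / sqrt(batch))
      lsT <- lsT + rate * (accT / 50 - target_accept)
      lsL <- lsL + rate * (accL / 50 - target_accept)
      lsB <- lsB + rate * (accB / 50 - target_accept)
      lsG <- lsG + rate * (accG / 50 - target_accept)
      lsS <- lsS + rate * (accS / 50 - target_accept)
      lsSB <- lsSB + rate * (accSB / 50 - target_accept)
      lsR <- lsR + rate * (accR / 50 - target_accept)
      accT[] <- 0; accL[] <- 0; accB[] <- 0; accG[] <- 0; accS <- 0
      accSB <- 0; accR[] <- 0
    }

    if (it > warmup) {
      d <- it - warmup
      keep$T[d, ] <- T
      keep$lam[d, ] <- exp(loglam)
      keep$beta[d, ] <- beta
      keep$gamma[d, ] <- gamma
      keep$mu[d] <- mu
      keep$sigma[d] <- exp(logsigma)
      keep$sigma_beta[d] <- exp(logsigma_beta)
    }
  }
  keep
}

#' Fit the latent truth rater consensus model to one subscale
#'
#' Estimates, for every item of the chosen subscale, the latent consensus
#' location of the analysis teams, together with ordered response-category
#' thresholds shared across items, a scepticism shift per team, a
#' dispersion ("difficulty") per item, and a subscale-level hyper-mean and
#' hyper-sd. Missing / not-applicable cells contribute no likelihood term.
#'
#' Sampling uses an adaptive Metropolis-within-Gibbs scheme with blocked
#' column/row updates. The likelihood is invariant under a common shift of
#' all thresholds and locations (and of scepticism against locations), so
#' each stored draw is identified by recentering: thresholds and
#' scepticism shifts are constrained to mean zero, with the compensating
#' shift absorbed into the consensus locations and hyper-mean. A warning
#' is raised when any split-Rhat exceeds 1.01.
#'
#' @param table A `sees_responses` (reverse coding already applied).
#' @param instrument A `sees_instrument`.
#' @param subscale `"subjective_evidence"` or
#'   `"methodological_appropriateness"`.
#' @param config A [model_config()].
#' @return A `sees_fit` with elements `draws` (list of matrices/vectors:
#'   `T`, `lam`, `beta`, `gamma`, `mu`, `sigma`, `sigma_beta`), `chain`
#'   (chain index per draw), `item_ids`, `team_ids`, `subscale`, `C`,
#'   `config` and `diagnostics` (`rhat`, `ess`, `divergences`).
#' @export
fit_consensus <- function(table, instrument, subscale,
                          config = model_config()) {
  stopifnot(inherits(table, "sees_responses"),
            inherits(instrument, "sees_instrument"),
            inherits(config, "sees_model_config"))
  if (!isTRUE(table$reversed)) {
    stop("responses must be recoded (reverse coding applied) before fitting",
         call. = FALSE)
  }
  X <- .subscale_values(table, instrument, subscale)
  if (ncol(X) < 2L) stop("subscale must have >= 2 items", call. = FALSE)
  responding <- rowSums(!is.na(X)) > 0L
  if (sum(responding) < 5L) {
    stop("need >= 5 teams with at least one response", call. = FALSE)
  }
  if (all(is.na(X))) stop("no non-missing responses for subscale", call. = FALSE)

  chains <- lapply(seq_len(config$chains), function(j) {
    .ltrm_chain(X, config$C, config$warmup, config$draws_per_chain,
                config$priors, config$seed + j - 1L, config$target_accept)
  })
  draws <- list(
    T = do.call(rbind, lapply(chains, `[[`, "T")),
    lam = do.call(rbind, lapply(chains, `[[`, "lam")),
    beta = do.call(rbind, lapply(chains, `[[`, "beta")),
    gamma = do.call(rbind, lapply(chains, `[[`, "gamma")),
    mu = unlist(lapply(chains, `[[`, "mu")),
    sigma = unlist(lapply(chains, `[[`, "sigma")),
    sigma_beta = unlist(lapply(chains, `[[`, "sigma_beta"))
  )
  chain_id <- rep(seq_len(config$chains), each = config$draws_per_chain)

  # identification: recenter every draw so mean(gamma) = 0 and
  # mean(beta) = 0, absorbing the shifts into T and the hyper-mean
  a <- rowMeans(draws$gamma)
  b <- rowMeans(draws$beta)
  draws$gamma <- draws$gamma - a
  draws$beta <- draws$beta - b
  draws$T <- draws$T - (a + b)
  draws$mu <- draws$mu - (a + b)

  colnames(draws$T) <- colnames(X)
  colnames(draws$lam) <- colnames(X)
  colnames(draws$beta) <- rownames(X)

  mon <- cbind(draws$T, draws$gamma, draws$mu, draws$sigma, draws$sigma_beta)
  colnames(mon) <- c(paste0("T_", colnames(X)),
                     paste0("gamma_", seq_len(ncol(draws$gamma))),
                     "mu", "sigma", "sigma_beta")
  rhat <- apply(mon, 2, .split_rhat, chain = chain_id)
  ess <- apply(mon, 2, .ess_basic, chain = chain_id)
  if (any(rhat > 1.01, na.rm = TRUE)) {
    warning(sprintf(
      "convergence warning: max split-Rhat = %.3f (%s); consider more draws",
      max(rhat, na.rm = TRUE), names(which.max(rhat))), call. = FALSE)
  }

  structure(
    list(draws = draws, chain = chain_id, item_ids = colnames(X),
         team_ids = rownames(X), subscale = subscale, C = config$C,
         config = config,
         diagnostics = list(rhat = rhat, ess = ess, divergences = 0L)),
    class = "sees_fit"
  )
}

#' @export
print.sees_fit <- function(x, ...) {
  cat(sprintf("<sees_fit> subscale '%s': %d items, %d teams, %d draws (%d chains)\n",
              x$subscale, length(x$item_ids), length(x$team_ids),
              length(x$draws$mu), x$config$chains))
  cat(sprintf("  max split-Rhat %.3f, min ESS %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}
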