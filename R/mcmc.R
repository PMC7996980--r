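#' Adaptive random-walk Metropolis sampler
#'
#' Generic Metropolis engine used by [emm_fit()]: a multivariate Gaussian
#' random walk whose proposal covariance is adapted during burn-in (running
#' empirical covariance, Haario-style, with a global scale tuned towards an
#' acceptance rate of ~0.3) and frozen afterwards so the kept portion of
#' the chain satisfies detailed balance.
#'
#' @param log_lik function(theta) -> log-likelihood (theta on the sampling
#'   scale); `-Inf` rejects the proposal.
#' @param log_prior function(theta) -> log prior density on the sampling
#'   scale.
#' @param init numeric starting point.
#' @param n_iter total iterations.
#' @param n_burn burn-in iterations discarded (adaptation stops here).
#' @param seed integer RNG seed; fixed seed gives bit-identical chains.
#' @param step0 initial proposal standard deviation per coordinate.
#' @param target_acc acceptance rate targeted during adaptation.
#' @return List with `samples` (kept draws, rows = iterations), `log_lik`
#'   (kept log-likelihood values), `acc_rate` (post-burn-in acceptance),
#'   and `warnings` (character, e.g. for near-zero acceptance).
#' @export
amh_sample <- function(log_lik, log_prior, init, n_iter, n_burn, seed,
                       step0 = 0.1, target_acc = 0.3) {
  stopifnot(n_burn < n_iter, n_burn >= 0)
  set.seed(as.integer(seed))
  d <- length(init)
  n_keep <- n_iter - n_burn

  theta <- as.numeric(init)
  ll <- log_lik(theta)
  lp <- log_prior(theta)
  if (!is.finite(ll + lp)) stop("initial point has zero posterior density")

  samples <- matrix(NA_real_, n_keep, d)
  ll_kept <- numeric(n_keep)

  # running moments for covariance adaptation
  mu <- theta
  cov_acc <- diag(1e-12, d)
  lambda <- step0
  chol_prop <- diag(1, d)
  use_cov <- FALSE
  n_acc_post <- 0L
  acc_window <- 0L

  for (i in seq_len(n_iter)) {
    z <- rnorm(d)
    prop <- theta + lambda * as.numeric(chol_prop %*% z)
    lp_p <- log_prior(prop)
    if (is.finite(lp_p)) {
      ll_p <- log_lik(prop)
      accept <- is.finite(ll_p) && log(runif(1)) < (ll_p + lp_p) - (ll + lp)
    } else accept <- FALSE
    if (accept) {
      theta <- prop; ll <- ll_p; lp <- lp_p
      acc_window <- acc_window + 1L
      if (i > n_burn) n_acc_post <- n_acc_post + 1L
    }

    if (i <= n_burn) {
      # rank-1 covariance update
      w <- 1 / (i + 1)
      dtheta <- theta - mu
      mu <- mu + w * dtheta
      cov_acc <- (1 - w) * (cov_acc + w * tcrossprod(dtheta))
      if (i %% 100L == 0L) {
        acc_rate <- acc_window / 100
        lambda <- lambda * exp((acc_rate - target_acc) / sqrt(i / 100))
        acc_window <- 0L
        if (i >= 500L) {
          ch <- try(chol(cov_acc + diag(1e-10, d)), silent = TRUE)
          if (!inherits(ch, "try-error")) {
            chol_prop <- t(ch) * (2.38 / sqrt(d))
            use_cov <- TRUE
          }
        }
      }
    } else {
      samples[i - n_burn, ] <- theta
      ll_kept[i - n_burn] <- ll
    }
  }

  warns <- character(0)
  acc_rate_post <- n_acc_post / n_keep
  if (acc_rate_post < 0.01)
    warns <- "acceptance rate below 1% after adaptation; chain is poorly mixed"
  list(samples = samples, log_lik = ll_kept, acc_rate = acc_rate_post,
       adapted_cov = use_cov, warnings = warns)
}
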