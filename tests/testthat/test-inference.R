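test_that("log-likelihood matches direct normal-density evaluation", {
  # single observation equal to the prediction: LL = -log(sigma*sqrt(2*pi))
  expect_equal(dnorm(5, 5, 0.1, log = TRUE), -log(0.1 * sqrt(2 * pi)))
  expect_equal(dnorm(5, 5, 0.1, log = TRUE), 1.383647, tolerance = 1e-6)

  # model-based likelihood against an independent density computation
  p <- ref_params()
  d <- ref_dataset(seed = 7)
  ll <- emm_loglik(p, d)
  ins <- forcing_fn(d$times, d$insulin)
  tr <- emm_simulate(p, ins, d$session, d$times, init = steady_state(p),
                     rtol = 1e-8, atol = 1e-10)
  ll_oracle <- sum(dnorm(d$glucose, tr$G, 0.02 * tr$G, log = TRUE))
  expect_equal(ll, ll_oracle, tolerance = 1e-5)

  # residual scaling: with zero residuals LL is the sigma-only constant,
  # and a residual of r sigmas costs r^2/2
  d0 <- ref_dataset(seed = 7, noise_cv = 0)
  ll0 <- emm_loglik(p, d0)
  expect_equal(ll0, -sum(log(0.02 * attr(d0, "truth") * sqrt(2 * pi))),
               tolerance = 1e-6)
})

test_that("same seed reproduces the chain bit for bit", {
  d <- ref_dataset(seed = 3)
  f1 <- emm_fit(d, variant = 6, n_iter = 600, n_burn = 400, seed = 9)
  f2 <- emm_fit(d, variant = 6, n_iter = 600, n_burn = 400, seed = 9)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$deviance, f2$deviance)
  f3 <- emm_fit(d, variant = 6, n_iter = 600, n_burn = 400, seed = 10)
  expect_false(identical(f1$chains, f3$chains))
})

test_that("stored deviance replays exactly from the stored draws", {
  d <- ref_dataset(seed = 5)
  fit <- emm_fit(d, variant = 6, n_iter = 1500, n_burn = 1000, seed = 2)
  idx <- c(1, 250, 500)
  for (i in idx) {
    par <- fit$chains[i, c("Gp0", "p1", "p2", "p3", "e1", "e2")]
    expect_identical(fit$deviance[i], -2 * fit$loglik_fun(par))
  }
  # a 5-parameter variant stores e1 in the insulin-sensitivity slot
  fit2 <- emm_fit(d, variant = 2, n_iter = 1200, n_burn = 1000, seed = 2)
  expect_named(fit2$chains[1, ], c("Gp0", "p1", "p2", "p3", "e1"))
})

test_that("with a flat likelihood the sampler reproduces the prior", {
  ll_flat <- function(theta) 0
  prior_mean <- c(0.4, -1.1)
  prior_sd <- c(0.7, 0.3)
  lp <- function(theta) sum(dnorm(theta, prior_mean, prior_sd, log = TRUE))
  res <- amh_sample(ll_flat, lp, init = prior_mean,
                    n_iter = 30000, n_burn = 10000, seed = 4)
  thin <- res$samples[seq(1, nrow(res$samples), by = 10), ]
  for (j in 1:2) {
    ks <- suppressWarnings(
      stats::ks.test(thin[, j], "pnorm", prior_mean[j], prior_sd[j]))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("conjugate normal-mean toy matches the closed-form posterior", {
  # y_i ~ N(mu, sigma^2), mu ~ N(m0, tau^2): posterior is Gaussian
  sigma <- 1; tau <- 2; m0 <- 0
  set.seed(8)
  y <- rnorm(12, 1.5, sigma)
  n <- length(y)
  post_var <- 1 / (n / sigma^2 + 1 / tau^2)
  post_mean <- post_var * (sum(y) / sigma^2 + m0 / tau^2)
  res <- amh_sample(function(mu) sum(dnorm(y, mu, sigma, log = TRUE)),
                    function(mu) dnorm(mu, m0, tau, log = TRUE),
                    init = 0, n_iter = 40000, n_burn = 10000, seed = 5)
  mc_se <- sqrt(post_var / 200) # generous: heavy autocorrelation
  expect_lt(abs(mean(res$samples) - post_mean), 6 * mc_se)
  expect_lt(abs(sd(res$samples) - sqrt(post_var)), 0.1 * sqrt(post_var))
})

test_that("posterior summaries have the documented form", {
  m <- cbind(a = rep(3, 50))
  s <- posterior_summary(m)
  expect_equal(s["a", "median"], 3)
  expect_equal(s["a", "q25"], 3)
  expect_equal(s["a", "q75"], 3)
  expect_equal(s["a", "cv"], 0)
  s2 <- posterior_summary(cbind(x = 1:101))
  expect_equal(s2["x", "median"], 51)
  # log-normal CV closed form: sqrt(exp(sdlog^2) - 1)
  set.seed(11)
  draws <- cbind(z = exp(rnorm(200000, 0, 0.25)))
  s3 <- posterior_summary(draws)
  expect_equal(s3["z", "cv"], sqrt(exp(0.0625) - 1), tolerance = 0.01)
})

test_that("hypoglycemia exclusion rule is applied to pre/during samples", {
  ses <- ref_session()
  mk <- function(id, g_min, sym, when = 1100) {
    tt <- build_schedule()
    g <- rep(8, length(tt))
    g[which.min(abs(tt - when))] <- g_min
    subject_dataset(id, tt, g, rep(12, length(tt)), rep(3.5, length(tt)),
                    ses, symptoms = tt == tt[which.min(abs(tt - when))] & sym)
  }
  d_sym <- mk("sym32", 3.2, TRUE)
  d_asym_29 <- mk("asym29", 2.9, FALSE)
  d_asym_34 <- mk("asym34", 3.4, FALSE)
  d_sym_34 <- mk("sym34", 3.4, TRUE)
  # low glucose after exercise does not exclude
  d_post <- mk("post29", 2.9, FALSE, when = 1170)
  d_post$glucose[d_post$times <= ses$t_end] <- 8

  kept <- filter_sessions(list(d_sym, d_asym_29, d_asym_34, d_sym_34, d_post),
                          quiet = TRUE)
  ids <- vapply(kept, function(d) d$subject_id, "")
  expect_setequal(ids, c("asym34", "sym34", "post29"))
  expect_setequal(attr(kept, "excluded"), c("sym32", "asym29"))

  # missing flags: warn, treat as asymptomatic
  d_na <- mk("na32", 3.2, TRUE)
  d_na$symptoms[] <- NA
  expect_warning(kept2 <- filter_sessions(list(d_na), quiet = TRUE),
                 "asymptomatic")
  expect_length(kept2, 1)
})

test_that("denser sampling tightens the exercise-gain posteriors", {
  # quadrupling the observation count shrinks the posterior sd of the
  # exercise gains on average over replicate datasets (single replicates
  # can fluctuate: the gains are partly prior-dominated at 14 points)
  p <- ref_params()
  ses <- ref_session()
  sparse <- build_schedule()
  dense <- sort(unique(c(seq(930, 1080, 10), seq(1082.5, 1140, 2.5),
                         seq(1143.75, 1170, 3.75))))
  sd_sparse <- sd_dense <- c(e1 = 0, e2 = 0)
  for (r in 1:3) {
    d_sparse <- generate_dataset(p, sparse, ses, seed = 20 + r)
    d_dense <- generate_dataset(p, dense, ses, seed = 20 + r)
    f_sparse <- emm_fit(d_sparse, variant = 6, fast = TRUE, seed = 6 + r)
    f_dense <- emm_fit(d_dense, variant = 6, fast = TRUE, seed = 6 + r)
    for (g in c("e1", "e2")) {
      sd_sparse[g] <- sd_sparse[g] + sd(f_sparse$chains[, g]) / 3
      sd_dense[g] <- sd_dense[g] + sd(f_dense$chains[, g]) / 3
    }
  }
  expect_lt(sd_dense[["e1"]], sd_sparse[["e1"]])
  expect_lt(sd_dense[["e2"]], sd_sparse[["e2"]])
})
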