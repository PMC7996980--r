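#' Fit one exercise-model variant to one subject by MCMC
#'
#' Bayesian estimation of the minimal-model parameters from a single
#' exercise visit: adaptive random-walk Metropolis on the log-transformed
#' parameters targeting (log-normal prior) x (2%-CV Gaussian likelihood),
#' with the subject's measured plasma insulin and VO2 as forcing signals.
#' Basal insulin `Insb` is fixed to the mean of the pre-exercise insulin
#' observations; variants 2 and 3 estimate a single exercise gain `e1`,
#' the others estimate both `e1` and `e2`.
#'
#' The default run length is 100,000 iterations keeping the last 20,000
#' draws; `fast = TRUE` switches to 10,000/2,000 for quick exploratory
#' fits and automated test runs.
#'
#' @param data a [subject_dataset()].
#' @param variant exercise-model variant, integer 1..6.
#' @param prior an [emm_prior()].
#' @param n_iter,n_burn total and burned iterations (kept draws =
#'   `n_iter - n_burn`).
#' @param seed integer seed; a fixed seed gives bit-identical chains.
#' @param fast logical; use the short run length (overridden by explicit
#'   `n_iter`/`n_burn`).
#' @param Insb optionally override the fixed basal insulin (mU/L).
#' @param rtol,atol ODE solver tolerances inside the likelihood.
#' @return An object of class `emm_fit` with components `chains` (matrix of
#'   kept draws on the natural scale), `deviance` (per-draw `-2 log p(y|theta)`),
#'   `acc_rate`, `variant`, `Insb`, `data`, `prior`, `seed`, `n_iter`,
#'   `n_burn`.  Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`, `simulate`, plus [compute_dic()].
#' @examples
#' \donttest{
#' sch <- build_schedule()
#' p <- emm_params(32.1, 0.0021, 0.031, 1.6e-5, Insb = 12,
#'                 e1 = 1.6, e2 = 0.778, variant = 6)
#' ses <- default_exercise_trace(0.6, 60)
#' d <- generate_dataset(p, sch, session = ses, seed = 1)
#' fit <- emm_fit(d, variant = 6, fast = TRUE, seed = 1)
#' summary(fit)
#' }
#' @export
emm_fit <- function(data, variant = 6, prior = emm_prior(),
                    n_iter = 100000, n_burn = 80000, seed = 1,
                    fast = FALSE, Insb = NULL,
                    rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(data, "subject_dataset"), inherits(prior, "emm_prior"))
  variant <- as.integer(variant)
  if (!(variant %in% 1:6)) stop("'variant' must be in 1..6")
  if (fast) {
    if (missing(n_iter)) n_iter <- 10000
    if (missing(n_burn)) n_burn <- 8000
  }

  est <- if (variant %in% c(2L, 3L)) c("Gp0", "p1", "p2", "p3", "e1")
         else c("Gp0", "p1", "p2", "p3", "e1", "e2")
  d <- length(est)

  llfun <- make_loglik(data, variant, Insb = Insb, rtol = rtol, atol = atol)
  Insb <- attr(llfun, "Insb")

  nat <- function(lt) {
    par <- exp(lt)
    if (d == 5L) c(par, 0) else par
  }
  log_lik <- function(lt) llfun(nat(lt))
  meanlog <- prior$meanlog[est]; sdlog <- prior$sdlog[est]
  log_prior <- function(lt) sum(dnorm(lt, meanlog, sdlog, log = TRUE))

  res <- amh_sample(log_lik, log_prior, init = meanlog,
                    n_iter = n_iter, n_burn = n_burn, seed = seed,
                    step0 = 0.15)
  for (w in res$warnings) warning(w)

  chains <- exp(res$samples)
  colnames(chains) <- est
  structure(
    list(chains = chains, deviance = -2 * res$log_lik,
         acc_rate = res$acc_rate, variant = variant, Insb = Insb,
         data = data, prior = prior, seed = as.integer(seed),
         n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
         loglik_fun = llfun, warnings = res$warnings,
         call = match.call()),
    class = "emm_fit"
  )
}

#' Posterior summary of MCMC draws
#'
#' Per-parameter median, interquartile range, mean, standard deviation and
#' coefficient of variation (sd/mean) of a chain matrix.
#'
#' @param x an `emm_fit` or a numeric matrix of draws (columns =
#'   parameters).
#' @return Data frame with one row per parameter and columns `median`,
#'   `q25`, `q75`, `mean`, `sd`, `cv`.
#' @export
posterior_summary <- function(x) {
  m <- if (inherits(x, "emm_fit")) x$chains else as.matrix(x)
  if (nrow(m) == 0L) stop("empty chains")
  out <- data.frame(
    median = apply(m, 2, median),
    q25 = apply(m, 2, quantile, 0.25, names = FALSE),
    q75 = apply(m, 2, quantile, 0.75, names = FALSE),
    mean = colMeans(m),
    sd = apply(m, 2, sd)
  )
  out$cv <- out$sd / out$mean
  rownames(out) <- colnames(m)
  out
}

#' @export
print.emm_fit <- function(x, ...) {
  cat(sprintf("Exercise minimal model fit (variant %d), subject %s\n",
              x$variant, x$data$subject_id))
  cat(sprintf("  %d kept draws of %d iterations (burn-in %d), acceptance %.1f%%\n",
              nrow(x$chains), x$n_iter, x$n_burn, 100 * x$acc_rate))
  cat(sprintf("  Insb fixed at %.3g mU/L; posterior medians:\n", x$Insb))
  print(signif(apply(x$chains, 2, median), 4))
  invisible(x)
}

#' @rdname emm_fit
#' @param object,x an `emm_fit`.
#' @param ... unused.
#' @export
summary.emm_fit <- function(object, ...) {
  structure(list(table = posterior_summary(object),
                 variant = object$variant,
                 subject_id = object$data$subject_id,
                 acc_rate = object$acc_rate,
                 n_kept = nrow(object$chains)),
            class = "summary.emm_fit")
}

#' @export
print.summary.emm_fit <- function(x, ...) {
  cat(sprintf("Posterior summary, variant %d, subject %s (%d draws):\n",
              x$variant, x$subject_id, x$n_kept))
  print(signif(x$table, 4))
  cat(sprintf("CV range %.0f%%-%.0f%%; acceptance %.1f%%\n",
              100 * min(x$table$cv), 100 * max(x$table$cv), 100 * x$acc_rate))
  invisible(x)
}

#' @export
coef.emm_fit <- function(object, ...) {
  apply(object$chains, 2, median)
}

# posterior-median parameter set as an emm_params
median_params <- function(fit) {
  cf <- coef(fit)
  emm_params(Gp0 = cf[["Gp0"]], p1 = cf[["p1"]], p2 = cf[["p2"]],
             p3 = cf[["p3"]], Insb = fit$Insb,
             e1 = cf[["e1"]], e2 = if ("e2" %in% names(cf)) cf[["e2"]] else 0,
             variant = fit$variant)
}

#' @rdname emm_fit
#' @param newtimes output times (min); defaults to the observation times.
#' @export
predict.emm_fit <- function(object, newtimes = NULL, ...) {
  if (is.null(newtimes)) newtimes <- object$data$times
  p <- median_params(object)
  ins <- forcing_fn(object$data$times, object$data$insulin)
  tr <- emm_simulate(p, ins, object$data$session, newtimes,
                     init = steady_state(p))
  setNames(tr$G, newtimes)
}

#' @export
fitted.emm_fit <- function(object, ...) predict(object)

#' @rdname emm_fit
#' @param type `"weighted"` (residual / measurement sd, the fit diagnostic)
#'   or `"raw"` (mmol/L).
#' @export
residuals.emm_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  ghat <- fitted(object)
  r <- object$data$glucose - ghat
  if (type == "weighted") r / (0.02 * ghat) else r
}

#' @rdname emm_fit
#' @param nsim number of posterior-predictive replicates.
#' @export
simulate.emm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dat <- object$data
  ins <- forcing_fn(dat$times, dat$insulin)
  rows <- sample.int(nrow(object$chains), nsim, replace = TRUE)
  out <- matrix(NA_real_, length(dat$times), nsim)
  for (j in seq_len(nsim)) {
    cf <- object$chains[rows[j], ]
    p <- emm_params(cf[["Gp0"]], cf[["p1"]], cf[["p2"]], cf[["p3"]],
                    Insb = object$Insb, e1 = cf[["e1"]],
                    e2 = if ("e2" %in% names(cf)) cf[["e2"]] else 0,
                    variant = object$variant)
    tr <- emm_simulate(p, ins, dat$session, dat$times,
                       init = steady_state(p))
    out[, j] <- tr$G * (1 + 0.02 * rnorm(length(tr$G)))
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(data.frame(time = dat$times), out)
}

#' @rdname emm_fit
#' @export
plot.emm_fit <- function(x, ...) {
  dat <- x$data
  grid <- seq(min(dat$times), max(dat$times), length.out = 200)
  ghat <- predict(x, newtimes = grid)
  ylim <- range(dat$glucose, ghat)
  plot(dat$times, dat$glucose, pch = 16, xlab = "time (min)",
       ylab = "plasma glucose (mmol/L)", ylim = ylim,
       main = sprintf("Variant %d fit, subject %s", x$variant, dat$subject_id),
       ...)
  ses <- dat$session
  rect(ses$t_start, ylim[1] - 1, ses$t_end, ylim[2] + 1,
       col = grDevices::adjustcolor("grey", 0.3), border = NA)
  graphics::lines(grid, ghat, lwd = 2)
  graphics::points(dat$times, dat$glucose, pch = 16)
  invisible(x)
}

#' @export
logLik.emm_fit <- function(object, ...) {
  ll <- -0.5 * min(object$deviance)
  structure(ll, df = ncol(object$chains), class = "logLik")
}
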