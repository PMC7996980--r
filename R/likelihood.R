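# Likelihood hot path: build everything that does not depend on the
# parameter draw once (solver grid, forcing matrices), then evaluate the
# 2%-CV Gaussian log-likelihood per draw with a single compiled ODE solve.
make_loglik <- function(data, variant, Insb = NULL,
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(data, "subject_dataset"))
  session <- data$session
  if (is.null(Insb))
    Insb <- mean(data$insulin[data$times <= session$t_start])
  if (!is.finite(Insb) || Insb <= 0)
    stop("cannot fix Insb: no positive pre-exercise insulin observations")

  t_grid <- data$times
  t0 <- t_grid[1]; t1 <- t_grid[length(t_grid)]
  brk <- c(session$t_start, session$t_end, attr(session$vo2_trace, "times"))
  times <- sort(unique(c(t_grid, brk[brk > t0 & brk < t1])))
  idx <- match(t_grid, times)

  ins_fn <- forcing_fn(data$times, data$insulin)
  ins_mat <- forcing_matrix(ins_fn, t0, t1)
  vo2_mat <- forcing_matrix(session$vo2_trace, t0, t1)
  ra_mat <- cbind(c(t0, t1), c(0, 0))
  forcings <- list(ins_mat, vo2_mat, ra_mat)
  fcontrol <- list(method = "linear", rule = 2, f = 0, ties = "ordered")
  sess_parms <- c(session$t_start, session$t_end,
                  session$vo2_rest, session$vo2_max, 1)
  y <- data$glucose

  f <- function(par) {
    # par: named or positional c(Gp0, p1, p2, p3, e1, e2) on natural scale
    X0 <- par[4] / par[3] * Insb
    G0 <- par[1] * par[2] / (par[2] + X0)
    parms <- c(par[2], par[3], par[4], par[1], par[5], par[6],
               variant, sess_parms)
    out <- try(suppressWarnings(deSolve::ode(
      y = c(G0, X0), times = times, func = "minmodex_deriv", parms = parms,
      dllname = "minmodex", initfunc = "minmodex_initpar",
      initforc = "minmodex_initforc", forcings = forcings,
      fcontrol = fcontrol, method = "lsoda",
      rtol = rtol, atol = atol, maxsteps = 100000
    )), silent = TRUE)
    if (inherits(out, "try-error")) return(-Inf)
    ghat <- out[idx, 2L]
    if (anyNA(ghat) || any(ghat <= 0)) return(-Inf)
    sigma <- 0.02 * ghat
    sum(dnorm(y, ghat, sigma, log = TRUE))
  }
  attr(f, "Insb") <- Insb
  f
}

#' Log-likelihood of a subject dataset under the model
#'
#' Gaussian measurement model with a 2% coefficient of variation: each
#' glucose observation is `Normal(Ghat(t_i), 0.02 * Ghat(t_i))` where
#' `Ghat` is the model prediction under the subject's measured insulin and
#' VO2 forcing, started from the basal steady state.  The standard
#' deviation is proportional to the prediction (not the observation) so the
#' likelihood remains a proper density in the parameters.  The deviance
#' used for model comparison is `-2` times this value.
#'
#' @param params an [emm_params()] object (its `Insb` fixes the basal
#'   insulin; its `variant` selects the exercise model).
#' @param data a [subject_dataset()].
#' @param rtol,atol solver tolerances.
#' @return Log-likelihood (scalar); `-Inf` if the solver fails.
#' @export
emm_loglik <- function(params, data, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "emm_params"))
  f <- make_loglik(data, params$variant, Insb = params$Insb,
                   rtol = rtol, atol = atol)
  f(c(params$Gp0, params$p1, params$p2, params$p3, params$e1, params$e2))
}
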