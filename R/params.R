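#' Physiological parameters of one virtual subject
#'
#' Bundles the minimal-model constants of a single subject together with the
#' exercise-model variant used to simulate them.  Units follow the minimal
#' model: glucose in mmol/L, insulin in mU/L, rates in 1/min.
#'
#' @param Gp0 glucose level at zero plasma insulin (mmol/L).
#' @param p1 glucose effectiveness (1/min).
#' @param p2 time constant of the remote-insulin compartment (1/min).
#' @param p3 insulin sensitivity (1/min^2 per mU/L).
#' @param Insb basal plasma insulin (mU/L).
#' @param e1 exercise-induced increase in glucose effectiveness, as a
#'   dimensionless fraction (an increase printed as "160%" is 1.60).
#' @param e2 exercise-induced increase in insulin sensitivity (fraction).
#' @param variant exercise-model variant, an integer in 1..6 (see
#'   [inc_terms()] for the variant definitions).
#' @return An object of class `emm_params`: a named list of the above.
#' @examples
#' emm_params(Gp0 = 32.1, p1 = 0.0021, p2 = 0.031, p3 = 1.6e-5,
#'            Insb = 10, e1 = 1.60, e2 = 0.778, variant = 6)
#' @export
emm_params <- function(Gp0, p1, p2, p3, Insb, e1 = 0, e2 = 0, variant = 6L) {
  for (nm in c("Gp0", "p1", "p2", "p3", "Insb")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single strictly positive number", nm))
  }
  for (nm in c("e1", "e2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm))
  }
  variant <- as.integer(variant)
  if (length(variant) != 1L || is.na(variant) || !(variant %in% 1:6))
    stop("'variant' must be an integer in 1..6")
  structure(
    list(Gp0 = Gp0, p1 = p1, p2 = p2, p3 = p3, Insb = Insb,
         e1 = e1, e2 = e2, variant = variant),
    class = "emm_params"
  )
}

#' @export
print.emm_params <- function(x, ...) {
  cat("Exercise minimal model parameters (variant", x$variant, ")\n")
  cat(sprintf("  Gp0 = %.4g mmol/L   p1 = %.4g /min   p2 = %.4g /min\n",
              x$Gp0, x$p1, x$p2))
  cat(sprintf("  p3 = %.4g /min^2 per mU/L   Insb = %.4g mU/L\n",
              x$p3, x$Insb))
  cat(sprintf("  e1 = %.4g (%.0f%%)   e2 = %.4g (%.0f%%)\n",
              x$e1, 100 * x$e1, x$e2, 100 * x$e2))
  invisible(x)
}

#' @export
as.data.frame.emm_params <- function(x, ...) {
  data.frame(Gp0 = x$Gp0, p1 = x$p1, p2 = x$p2, p3 = x$p3, Insb = x$Insb,
             e1 = x$e1, e2 = x$e2, variant = x$variant)
}

#' Steady state of the glucose-insulin system
#'
#' The resting state of the model at basal insulin with no exercise:
#' `X0 = (p3/p2) * Insb` and `G0 = Gp0 * p1 / (p1 + X0)`, the unique state
#' at which both derivatives vanish when plasma insulin is held at `Insb`.
#'
#' @param params an [emm_params()] object.
#' @return Named numeric vector `c(G = , X = )`.
#' @examples
#' p <- emm_params(32.1, 0.0021, 0.031, 1.6e-5, Insb = 10)
#' steady_state(p)
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "emm_params"))
  X0 <- params$p3 / params$p2 * params$Insb
  G0 <- params$Gp0 * params$p1 / (params$p1 + X0)
  c(G = G0, X = X0)
}
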