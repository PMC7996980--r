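#' Fraction of maximal oxygen consumption above rest
#'
#' Normalises an oxygen-uptake reading to the subject's aerobic range:
#' `(vo2 - vo2_rest) / (vo2_max - vo2_rest)`, clipped to \[0, 1\].  Measured
#' breath-by-breath data routinely overshoot the range slightly, so values
#' outside it are clipped rather than rejected.
#'
#' @param vo2 oxygen consumption reading(s); any units shared with the
#'   reference values.
#' @param vo2_rest resting oxygen consumption.
#' @param vo2_max maximal oxygen consumption; must exceed `vo2_rest`.
#' @return Numeric in \[0, 1\], vectorised over `vo2`.
#' @examples
#' pvo2max(20, vo2_rest = 3.5, vo2_max = 40)
#' @export
pvo2max <- function(vo2, vo2_rest, vo2_max) {
  if (!is.numeric(vo2_max) || !is.numeric(vo2_rest) || vo2_max <= vo2_rest)
    stop("invalid session: vo2_max must exceed vo2_rest")
  pmin(1, pmax(0, (vo2 - vo2_rest) / (vo2_max - vo2_rest)))
}

#' Elapsed exercise time, normalised by one hour
#'
#' Time since the start of exercise divided by 60 min, the dimensionless
#' duration signal used by the duration-dependent model variants.  Before
#' the session starts the elapsed fraction is 0.
#'
#' @param t absolute time (min), vectorised.
#' @param t_start session start (min, same timeline).
#' @return `(t - t_start)/60`, floored at 0.
#' @export
exercise_time <- function(t, t_start) {
  pmax(0, (t - t_start) / 60)
}

#' Exercise increments of glucose effectiveness and insulin sensitivity
#'
#' The six model variants differ only in how the two multiplicative
#' increments `inc1` (on glucose effectiveness) and `inc2` (on insulin
#' sensitivity) are built from the fixed gains `e1`, `e2`, the exercise
#' intensity signal `pvo2`, and the normalised elapsed time `te`:
#'
#' \tabular{lll}{
#'   variant \tab inc1 \tab inc2 \cr
#'   1 \tab e1 \tab e2 \cr
#'   2 \tab 0 \tab e1 \cr
#'   3 \tab e1 \tab 0 \cr
#'   4 \tab e1 * pvo2 \tab e2 * pvo2 \cr
#'   5 \tab e1 * te \tab e2 * te \cr
#'   6 \tab e1 * pvo2 \tab e2 * (pvo2 + te) \cr
#' }
#'
#' Outside the exercise window both increments are 0 for every variant
#' (no post-exercise carry-over is modelled).
#'
#' @param variant integer 1..6.
#' @param e1,e2 non-negative gain fractions.
#' @param pvo2 intensity fraction in \[0, 1\] (see [pvo2max()]).
#' @param te normalised elapsed exercise time (see [exercise_time()]).
#' @param in_exercise logical; is `t` inside the exercise window?
#' @return Named numeric vector `c(inc1 = , inc2 = )`.
#' @examples
#' inc_terms(6, e1 = 1.60, e2 = 0.778, pvo2 = 0.5, te = 0.5, in_exercise = TRUE)
#' @export
inc_terms <- function(variant, e1, e2, pvo2 = 0, te = 0, in_exercise = TRUE) {
  variant <- as.integer(variant)
  if (length(variant) != 1L || is.na(variant) || !(variant %in% 1:6))
    stop("unknown model variant: must be an integer in 1..6")
  if (!in_exercise)
    return(c(inc1 = 0, inc2 = 0))
  out <- switch(variant,
    c(e1, e2),                        # 1
    c(0, e1),                         # 2
    c(e1, 0),                         # 3
    c(e1 * pvo2, e2 * pvo2),          # 4
    c(e1 * te, e2 * te),              # 5
    c(e1 * pvo2, e2 * (pvo2 + te))    # 6
  )
  names(out) <- c("inc1", "inc2")
  out
}

#' Model right-hand side
#'
#' Time derivatives of the two-state exercise minimal model at a given
#' state, plasma insulin level, and exercise increments:
#' \deqn{dX/dt = -p_2 X + p_3 (1 + inc_2) Ins}
#' \deqn{dG/dt = -p_1 (1 + inc_1) G - X G + p_1 G_{p0}}
#'
#' This is the pure in-memory kernel; forward integration against forcing
#' signals is done by [emm_simulate()] using a compiled equivalent.
#'
#' @param state named numeric `c(G = , X = )` (mmol/L, 1/min).
#' @param params an [emm_params()] object.
#' @param ins plasma insulin (mU/L), non-negative.
#' @param inc1,inc2 exercise increments (fractions).
#' @param t time (min); unused by the autonomous equations, kept for
#'   signature symmetry with ODE solvers.
#' @return Named numeric vector `c(dG = , dX = )`.
#' @export
emm_rhs <- function(state, params, ins, inc1 = 0, inc2 = 0, t = 0) {
  stopifnot(inherits(params, "emm_params"), ins >= 0)
  G <- state[["G"]]
  X <- state[["X"]]
  dX <- -params$p2 * X + params$p3 * (1 + inc2) * ins
  dG <- -params$p1 * (1 + inc1) * G - X * G + params$p1 * params$Gp0
  c(dG = dG, dX = dX)
}
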