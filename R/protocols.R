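#' Subcutaneous insulin kinetics configuration
#'
#' Linear two-compartment subcutaneous absorption chain with first-order
#' plasma clearance, the standard description of rapid-acting insulin
#' kinetics: depot `S1 -> S2` with time constant `tmax`, plasma appearance
#' `S2/tmax`, clearance `ke` from a distribution volume `V_I`.
#'
#' @param tmax absorption time constant (min); plasma concentration after a
#'   bolus peaks near this time.
#' @param ke plasma elimination rate (1/min).
#' @param V_I_per_kg insulin distribution volume (L/kg).
#' @param weight body weight (kg).
#' @return Named list of kinetic constants (with `V_I` in litres).
#' @export
insulin_kinetics <- function(tmax = 55, ke = 0.138, V_I_per_kg = 0.12,
                             weight = 70) {
  stopifnot(tmax > 0, ke > 0, V_I_per_kg > 0, weight > 0)
  list(tmax = tmax, ke = ke, V_I = V_I_per_kg * weight)
}

#' Plasma insulin from pump basal/bolus delivery
#'
#' Solves the linear subcutaneous absorption chain under a (piecewise
#' constant) basal rate profile and discrete boluses, returning the plasma
#' insulin concentration as a forcing signal for the glucose model.  A
#' constant basal rate `u` (U/h) converges to the analytic plateau
#' `Insb = u * 1000/60 / (ke * V_I)` mU/L; by linearity a bolus reduced by
#' some fraction scales the plasma increment by the same fraction.
#'
#' @param basal either a single rate (U/h) or a data frame with columns
#'   `time` (min) and `rate` (U/h), piecewise constant from each time on.
#' @param boluses optional data frame with columns `time` (min) and
#'   `units` (U); doses must be non-negative.
#' @param config kinetics from [insulin_kinetics()].
#' @param t_range simulation span (min), length 2.
#' @param init `"steady"` starts the chain at the plateau of the initial
#'   basal rate; or a numeric `c(S1, S2, I)` state.
#' @param dt output resolution (min).
#' @return A [forcing_fn()] of plasma insulin (mU/L) with the steady basal
#'   plateau attached as attribute `"Insb"`.
#' @export
insulin_submodel <- function(basal, boluses = NULL,
                             config = insulin_kinetics(),
                             t_range = c(0, 600), init = "steady", dt = 1) {
  if (is.numeric(basal) && length(basal) == 1L)
    basal <- data.frame(time = t_range[1], rate = basal)
  stopifnot(is.data.frame(basal), all(c("time", "rate") %in% names(basal)))
  if (any(basal$rate < 0)) stop("negative basal rate")
  if (!is.null(boluses)) {
    stopifnot(all(c("time", "units") %in% names(boluses)))
    if (any(boluses$units < 0)) stop("negative bolus dose")
  }
  tmax <- config$tmax; ke <- config$ke; V_I <- config$V_I
  # rates in mU/min
  u_of_t <- stats::stepfun(basal$time, c(basal$rate[1], basal$rate) * 1000 / 60)
  u0 <- u_of_t(t_range[1])
  y0 <- if (identical(init, "steady"))
    c(S1 = u0 * tmax, S2 = u0 * tmax, I = u0 / (ke * V_I))
  else c(S1 = init[1], S2 = init[2], I = init[3])

  rhs <- function(t, y, parms) {
    u <- u_of_t(t)
    list(c(u - y[1] / tmax,
           (y[1] - y[2]) / tmax,
           y[2] / (tmax * V_I) - ke * y[3]))
  }
  times <- seq(t_range[1], t_range[2], by = dt)
  times <- sort(unique(c(times, basal$time[basal$time > t_range[1] &
                                             basal$time < t_range[2]])))
  events <- NULL
  if (!is.null(boluses) && nrow(boluses) > 0) {
    events <- list(data = data.frame(var = "S1", time = boluses$time,
                                     value = boluses$units * 1000,
                                     method = "add"))
    times <- sort(unique(c(times, boluses$time)))
  }
  out <- deSolve::ode(y0, times, rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-8, events = events)
  f <- forcing_fn(out[, "time"], pmax(0, out[, "I"]))
  attr(f, "Insb") <- u0 / (ke * V_I)
  f
}

#' Meal glucose-appearance kinetics configuration
#'
#' @param tmax gut absorption time constant (min); appearance peaks at
#'   `tmax` after the meal.
#' @param bioavail fraction of ingested carbohydrate reaching plasma.
#' @param V_G_per_kg glucose distribution volume (L/kg).
#' @param weight body weight (kg).
#' @param mmol_per_g mmol of glucose per gram of carbohydrate.
#' @return Named list of constants (with `V_G` in litres).
#' @export
meal_kinetics <- function(tmax = 40, bioavail = 0.8, V_G_per_kg = 0.16,
                          weight = 70, mmol_per_g = 1000 / 180.16) {
  stopifnot(tmax > 0, bioavail > 0, bioavail <= 1, V_G_per_kg > 0)
  list(tmax = tmax, bioavail = bioavail, V_G = V_G_per_kg * weight,
       mmol_per_g = mmol_per_g)
}

#' Meal glucose appearance (per distribution volume)
#'
#' Standard single-meal gut absorption curve
#' `Ra(t') = D * t' * exp(-t'/tmax) / tmax^2` (t' = time since the meal),
#' scaled so its time-integral equals
#' `carbs * mmol_per_g * bioavail / V_G` mmol/L — the quantity added to the
#' glucose equation by [emm_simulate()]'s `meal` argument.
#'
#' @param carbs carbohydrate content (g), >= 0.
#' @param meal_time meal time (min, absolute timeline).
#' @param config kinetics from [meal_kinetics()].
#' @param horizon minutes after the meal over which the curve is tabulated.
#' @return A [forcing_fn()] (mmol/L/min); the closed-form total rise is
#'   attached as attribute `"total"`.
#' @export
meal_submodel <- function(carbs, meal_time, config = meal_kinetics(),
                          horizon = 600) {
  stopifnot(carbs >= 0)
  total <- carbs * config$mmol_per_g * config$bioavail / config$V_G
  tt <- seq(meal_time, meal_time + horizon, by = 1)
  td <- tt - meal_time
  ra <- total * td * exp(-td / config$tmax) / config$tmax^2
  f <- forcing_fn(c(meal_time - 1, tt), c(0, ra))
  attr(f, "total") <- total
  f
}

#' Validation-protocol specification
#'
#' One arm of an in-silico exercise-management experiment: a meal with a
#' (possibly reduced) premeal bolus, or a basal-rate strategy, followed by
#' an exercise session.  Exactly one insulin-reduction strategy is active:
#' a bolus reduction, a basal reduction (with its lead time), or a pump
#' suspension.
#'
#' @param meal_carbs meal size (g); 0 for no meal.
#' @param meal_time meal time (min).
#' @param bolus_reduction fraction of the premeal bolus withheld, in
#'   \[0, 1\].
#' @param basal_reduction fraction of the basal rate withheld, in \[0, 1\].
#' @param basal_lead minutes before exercise at which the basal change
#'   starts.
#' @param pump_suspend suspend the pump at exercise onset.
#' @param intensity exercise intensity (fraction of VO2max).
#' @param duration exercise duration (min; for bout sessions the work time).
#' @param start_offset exercise start, minutes after `meal_time`.
#' @param bouts optional list(n, work, rest) describing an intermittent
#'   session; `NULL` for continuous exercise.
#' @return Object of class `protocol_spec`.
#' @export
protocol_spec <- function(meal_carbs = 0, meal_time = 480,
                          bolus_reduction = 0, basal_reduction = 0,
                          basal_lead = 90, pump_suspend = FALSE,
                          intensity = 0.5, duration = 60,
                          start_offset = 90, bouts = NULL) {
  if (bolus_reduction < 0 || bolus_reduction > 1 ||
      basal_reduction < 0 || basal_reduction > 1)
    stop("reductions must lie in [0, 1]")
  active <- c(bolus = bolus_reduction > 0, basal = basal_reduction > 0,
              pump = isTRUE(pump_suspend))
  if (sum(active) > 1L)
    stop("exactly one insulin-reduction strategy may be active")
  if (!is.null(bouts)) {
    stopifnot(all(c("n", "work", "rest") %in% names(bouts)))
    if (bouts$n * bouts$work != duration)
      stop("bout work durations must sum to the stated exercise duration")
  }
  structure(list(meal_carbs = meal_carbs, meal_time = meal_time,
                 bolus_reduction = bolus_reduction,
                 basal_reduction = basal_reduction, basal_lead = basal_lead,
                 pump_suspend = pump_suspend, intensity = intensity,
                 duration = duration, start_offset = start_offset,
                 bouts = bouts),
            class = "protocol_spec")
}

#' The eight postprandial-exercise protocols of the bolus-reduction study
#'
#' Intensity (fraction of VO2max), exercise duration (min) and premeal
#' bolus reduction for the eight arms: a 75-g breakfast with exercise 90
#' min later.
#'
#' @return Data frame with columns `protocol`, `intensity`, `duration`,
#'   `bolus_reduction`.
#' @export
study1_protocols <- function() {
  data.frame(
    protocol = 1:8,
    intensity = c(0.25, 0.25, 0.50, 0.50, 0.50, 0.50, 0.75, 0.75),
    duration = c(60, 60, 60, 60, 30, 30, 30, 30),
    bolus_reduction = c(0, 0.50, 0.50, 0.75, 0, 0.50, 0, 0.75)
  )
}

# basal to sustain the subject's Insb, in U/h
basal_for_insb <- function(Insb, config) {
  Insb * config$ke * config$V_I * 60 / 1000
}

# simulate one subject under one protocol arm; returns a dense trajectory
simulate_protocol <- function(params, spec, config = insulin_kinetics(),
                              meal_cfg = meal_kinetics(), icr = 10,
                              post_window = 60, dt = 1) {
  t_ex <- spec$meal_time + spec$start_offset
  session <- if (is.null(spec$bouts)) {
    default_exercise_trace(spec$intensity, spec$duration, t_start = t_ex)
  } else {
    bout_trace(spec$intensity, n_bouts = spec$bouts$n,
               work = spec$bouts$work, rest = spec$bouts$rest,
               t_start = t_ex)
  }
  t0 <- min(spec$meal_time, t_ex - spec$basal_lead) - 120
  t1 <- session$t_end + post_window

  u_b <- basal_for_insb(params$Insb, config)
  basal <- data.frame(time = t0, rate = u_b)
  if (spec$pump_suspend)
    basal <- rbind(basal, data.frame(time = t_ex, rate = 0))
  if (spec$basal_reduction > 0)
    basal <- rbind(basal, data.frame(time = t_ex - spec$basal_lead,
                                     rate = u_b * (1 - spec$basal_reduction)))
  boluses <- NULL
  meal <- NULL
  if (spec$meal_carbs > 0) {
    meal <- meal_submodel(spec$meal_carbs, spec$meal_time, meal_cfg)
    full_bolus <- spec$meal_carbs / icr
    boluses <- data.frame(time = spec$meal_time,
                          units = full_bolus * (1 - spec$bolus_reduction))
  }
  ins <- insulin_submodel(basal, boluses, config, t_range = c(t0, t1))
  grid <- seq(t0, t1, by = dt)
  tr <- emm_simulate(params, ins, session, grid,
                     init = steady_state(params), meal = meal)
  attr(tr, "t_exercise") <- c(t_ex, session$t_end)
  tr
}

#' Replay the postprandial bolus-reduction study on a virtual cohort
#'
#' Simulates one protocol arm (75-g breakfast, premeal bolus with the arm's
#' reduction, exercise 90 min post-meal at the arm's intensity and
#' duration) for every subject of the cohort with the selected model, and
#' reports glycemic outcomes over exercise plus 60 min post-exercise.
#'
#' @param cohort list of [emm_params()] (see [sample_cohort()]).
#' @param protocol_id arm number 1..8 (see [study1_protocols()]).
#' @param meal_carbs breakfast size (g).
#' @param icr insulin-to-carbohydrate ratio (g/U) setting the full bolus.
#' @param config,meal_cfg submodel kinetics.
#' @return List with `trajectories` (per subject), `outcomes` (an
#'   [glycemic_outcomes()] report over exercise + 60 min),
#'   `end_exercise_glucose` (per-subject mmol/L at the end of exercise),
#'   and `protocol` (the arm's row of [study1_protocols()]).
#' @export
run_study1 <- function(cohort, protocol_id, meal_carbs = 75, icr = 10,
                       config = insulin_kinetics(),
                       meal_cfg = meal_kinetics()) {
  arms <- study1_protocols()
  if (!(protocol_id %in% arms$protocol)) stop("'protocol_id' must be in 1..8")
  arm <- arms[arms$protocol == protocol_id, ]
  spec <- protocol_spec(meal_carbs = meal_carbs, meal_time = 480,
                        bolus_reduction = arm$bolus_reduction,
                        intensity = arm$intensity, duration = arm$duration,
                        start_offset = 90)
  trs <- lapply(cohort, simulate_protocol, spec = spec, config = config,
                meal_cfg = meal_cfg, icr = icr)
  tex <- attr(trs[[1]], "t_exercise")
  outcomes <- glycemic_outcomes(trs, window = c(tex[1], tex[2] + 60))
  end_g <- vapply(trs, function(tr) tr$G[which.min(abs(tr$time - tex[2]))], 0)
  list(trajectories = trs, outcomes = outcomes,
       end_exercise_glucose = end_g, protocol = arm)
}

#' Replay the basal-reduction study on a virtual cohort
#'
#' Intermittent exercise (four 15-min bouts at 50% VO2max with 5-min rests)
#' under one of three insulin strategies: pump stop at exercise onset, an
#' 80% basal reduction set 90 min pre-exercise, or a 50% basal reduction
#' set 90 min pre-exercise.  Reports the start-to-end-of-exercise glucose
#' drop and time-in-range outcomes over the exercise window.
#'
#' @param cohort list of [emm_params()].
#' @param strategy one of `"pump-stop"`, `"80%-basal-90min"`,
#'   `"50%-basal-90min"`.
#' @param config insulin kinetics.
#' @return List with `trajectories`, `outcomes` (over the exercise window),
#'   `glucose_drop` (per-subject start-to-end drop, mmol/L), `strategy`.
#' @export
run_study2 <- function(cohort,
                       strategy = c("pump-stop", "80%-basal-90min",
                                    "50%-basal-90min"),
                       config = insulin_kinetics()) {
  strategy <- match.arg(strategy)
  spec <- switch(strategy,
    "pump-stop" = protocol_spec(pump_suspend = TRUE, intensity = 0.5,
                                duration = 60, start_offset = 90,
                                bouts = list(n = 4, work = 15, rest = 5)),
    "80%-basal-90min" = protocol_spec(basal_reduction = 0.8, basal_lead = 90,
                                      intensity = 0.5, duration = 60,
                                      start_offset = 90,
                                      bouts = list(n = 4, work = 15, rest = 5)),
    "50%-basal-90min" = protocol_spec(basal_reduction = 0.5, basal_lead = 90,
                                      intensity = 0.5, duration = 60,
                                      start_offset = 90,
                                      bouts = list(n = 4, work = 15, rest = 5))
  )
  trs <- lapply(cohort, simulate_protocol, spec = spec, config = config)
  tex <- attr(trs[[1]], "t_exercise")
  drop <- vapply(trs, function(tr) {
    g0 <- tr$G[which.min(abs(tr$time - tex[1]))]
    g1 <- tr$G[which.min(abs(tr$time - tex[2]))]
    g0 - g1
  }, 0)
  outcomes <- glycemic_outcomes(trs, window = tex)
  list(trajectories = trs, outcomes = outcomes, glucose_drop = drop,
       strategy = strategy)
}
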