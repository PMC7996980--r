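#' Blood-sampling schedule of an exercise visit
#'
#' Sample times follow the study design: every 30 min from the start of
#' closed-loop control to the start of exercise, every 10 min during
#' exercise, and every 15 min during recovery.  Times are absolute minutes
#' from 00:00 of the visit day (15:30 is 930).  The defaults reproduce the
#' 14-point schedule of a 2.5-h control period, 60-min exercise and 30-min
#' recovery.
#'
#' @param control_start start of closed-loop control (min).
#' @param exercise_start start of exercise (min), after `control_start`.
#' @param exercise_dur exercise duration (min), > 0.
#' @param recovery recovery duration (min), >= 0.
#' @return Sorted vector of sample times (min).
#' @examples
#' length(build_schedule()) # 14
#' @export
build_schedule <- function(control_start = 930, exercise_start = 1080,
                           exercise_dur = 60, recovery = 30) {
  if (control_start >= exercise_start)
    stop("control must start before exercise")
  if (exercise_dur <= 0 || recovery < 0)
    stop("durations must be positive (recovery may be zero)")
  pre <- seq(control_start, exercise_start, by = 30)
  during <- if (exercise_dur >= 10)
    seq(exercise_start + 10, exercise_start + exercise_dur, by = 10)
  else numeric(0)
  ex_end <- exercise_start + exercise_dur
  post <- if (recovery >= 15) seq(ex_end + 15, ex_end + recovery, by = 15)
  else numeric(0)
  sort(unique(c(pre, during, post)))
}

#' Specification of a virtual cohort
#'
#' Per-parameter log-normal sampling distributions for a population of
#' virtual subjects.  Default locations are the selected model's posterior
#' medians from moderate-exercise closed-loop data (variant 6), with a
#' moderate between-subject spread.
#'
#' @param n_subjects cohort size.
#' @param location geometric means for `Gp0, p1, p2, p3, Insb, e1, e2`.
#' @param log_sd between-subject log-scale standard deviations (a single
#'   value is recycled).
#' @param variant model variant assigned to every subject.
#' @param noise_cv measurement coefficient of variation for generated
#'   glucose observations.
#' @param seed cohort RNG seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 12,
                        location = c(Gp0 = 32.1, p1 = 0.0021, p2 = 0.031,
                                     p3 = 1.6e-5, Insb = 12,
                                     e1 = 1.60, e2 = 0.778),
                        log_sd = 0.25, variant = 6, noise_cv = 0.02,
                        seed = 1) {
  nm <- c("Gp0", "p1", "p2", "p3", "Insb", "e1", "e2")
  if (!all(nm %in% names(location)))
    stop("location needs named entries for ", paste(nm, collapse = ", "))
  if (n_subjects < 1) stop("'n_subjects' must be >= 1")
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  log_sd <- rep_len(log_sd, length(nm))
  names(log_sd) <- nm
  if (any(log_sd < 0)) stop("'log_sd' must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), location = location[nm],
                 log_sd = log_sd, variant = as.integer(variant),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw a virtual cohort
#'
#' Samples `n_subjects` parameter sets from the spec's log-normal
#' distributions.  A fixed seed reproduces the cohort exactly.
#'
#' @param spec a [cohort_spec()].
#' @return List of [emm_params()] objects.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  mu <- log(spec$location); s <- spec$log_sd
  lapply(seq_len(spec$n_subjects), function(i) {
    v <- exp(rnorm(length(mu), mu, s))
    names(v) <- names(mu)
    emm_params(Gp0 = v[["Gp0"]], p1 = v[["p1"]], p2 = v[["p2"]],
               p3 = v[["p3"]], Insb = v[["Insb"]],
               e1 = v[["e1"]], e2 = v[["e2"]], variant = spec$variant)
  })
}

#' Default plasma-insulin profile for a synthetic exercise visit
#'
#' A stand-in for closed-loop dosing during an exercise study: plasma
#' insulin holds at basal until exercise begins, declines piecewise
#' linearly while the pump is largely suspended during exercise, and
#' partially recovers afterwards.  It is a synthetic profile, not a model
#' of any specific controller.  The default end-of-exercise level (70% of
#' basal after 60 min) matches what the package's subcutaneous absorption
#' chain ([insulin_submodel()], tmax 55 min, ke 0.138/min) produces under
#' a pump suspension at exercise onset — plasma insulin cannot fall faster
#' than the subcutaneous depot drains.
#'
#' @param Insb basal plasma insulin (mU/L).
#' @param session the visit's [exercise_session()].
#' @param suspend_frac fraction of basal reached at the end of exercise.
#' @param recover_frac fraction of basal recovered 45 min after exercise.
#' @return A [forcing_fn()].
#' @export
default_insulin_profile <- function(Insb, session, suspend_frac = 0.7,
                                    recover_frac = 0.85) {
  forcing_fn(
    c(session$t_start, session$t_end, session$t_end + 45),
    Insb * c(1, suspend_frac, recover_frac)
  )
}

#' Generate one synthetic subject dataset
#'
#' Simulates the subject's noiseless glucose trajectory on the sampling
#' schedule under the given insulin profile and exercise session, then adds
#' multiplicative Gaussian measurement noise
#' `y_i = Ghat(t_i) * (1 + noise_cv * eps_i)`.  Non-positive observations
#' are redrawn (and counted in attribute `"redraws"`).
#'
#' @param params an [emm_params()] virtual subject.
#' @param schedule sample times (see [build_schedule()]).
#' @param session an [exercise_session()].
#' @param insulin_profile a [forcing_fn()]; defaults to
#'   [default_insulin_profile()] at the subject's `Insb`.
#' @param noise_cv measurement coefficient of variation (0.02 = 2%).
#' @param seed RNG seed; fixed seed gives an identical dataset.
#' @param subject_id identifier stored in the dataset.
#' @return A [subject_dataset()]; the noiseless predictions are attached as
#'   attribute `"truth"`.
#' @export
generate_dataset <- function(params, schedule, session,
                             insulin_profile = NULL, noise_cv = 0.02,
                             seed = 1, subject_id = "S1") {
  stopifnot(inherits(params, "emm_params"))
  if (is.null(insulin_profile))
    insulin_profile <- default_insulin_profile(params$Insb, session)
  tr <- emm_simulate(params, insulin_profile, session, schedule,
                     init = steady_state(params))
  set.seed(as.integer(seed))
  n <- length(schedule)
  obs <- tr$G * (1 + noise_cv * rnorm(n))
  redraws <- 0L
  while (any(obs <= 0)) {
    bad <- which(obs <= 0)
    redraws <- redraws + length(bad)
    obs[bad] <- tr$G[bad] * (1 + noise_cv * rnorm(length(bad)))
  }
  if (redraws > 0L)
    message(sprintf("subject %s: redrew %d non-positive observation(s)",
                    subject_id, redraws))
  d <- subject_dataset(subject_id, schedule, obs,
                       insulin = insulin_profile(schedule),
                       vo2 = session$vo2_trace(schedule),
                       session = session, symptoms = FALSE)
  attr(d, "truth") <- tr$G
  attr(d, "redraws") <- redraws
  d
}

#' Generate a full synthetic study (cohort + datasets)
#'
#' Draws a cohort from the spec and generates one study-design dataset per
#' subject on the default 14-point schedule with a 60-min session at 60%
#' VO2max.
#'
#' @param spec a [cohort_spec()].
#' @param schedule sample times; default [build_schedule()].
#' @param intensity exercise intensity (fraction of VO2max).
#' @param exercise_start,exercise_dur session placement (min).
#' @return List with `cohort` (list of [emm_params()]) and `datasets`
#'   (list of [subject_dataset()]).
#' @export
generate_study <- function(spec, schedule = build_schedule(),
                           intensity = 0.6, exercise_start = 1080,
                           exercise_dur = 60) {
  cohort <- sample_cohort(spec)
  session <- default_exercise_trace(intensity, exercise_dur,
                                    t_start = exercise_start)
  datasets <- lapply(seq_along(cohort), function(i) {
    generate_dataset(cohort[[i]], schedule, session,
                     noise_cv = spec$noise_cv,
                     seed = spec$seed + 10000L + i,
                     subject_id = sprintf("S%02d", i))
  })
  list(cohort = cohort, datasets = datasets)
}
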