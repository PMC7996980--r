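#' Describe one exercise session
#'
#' An exercise session is a time window on the absolute visit timeline plus
#' the oxygen-uptake trace that drives the intensity signal.  The model's
#' exercise increments are active only inside `[t_start, t_start + duration]`.
#'
#' @param t_start session start (min on the absolute timeline; the study
#'   convention is minutes from 00:00, so 18:00 is 1080).
#' @param duration window length (min), > 0.  For intermittent sessions this
#'   is the whole work+rest window.
#' @param vo2_rest resting oxygen consumption (mL/kg/min by convention; only
#'   the normalised intensity matters).
#' @param vo2_max maximal oxygen consumption; must exceed `vo2_rest`.
#' @param vo2_trace a [forcing_fn()] giving VO2 over time, or a single
#'   number for a constant trace.  Values outside `[vo2_rest, vo2_max]` are
#'   clipped by [pvo2max()] before use.
#' @return Object of class `exercise_session`.
#' @seealso [default_exercise_trace()] for a constant-intensity session with
#'   on/off ramps, [bout_trace()] for intermittent work/rest sessions.
#' @export
exercise_session <- function(t_start, duration, vo2_rest = 3.5, vo2_max = 40,
                             vo2_trace = NULL) {
  if (!is.numeric(duration) || duration <= 0) stop("invalid session: duration must be > 0")
  if (vo2_max <= vo2_rest) stop("invalid session: vo2_max must exceed vo2_rest")
  if (is.null(vo2_trace)) vo2_trace <- vo2_rest
  if (is.numeric(vo2_trace) && length(vo2_trace) == 1L)
    vo2_trace <- forcing_fn(t_start, vo2_trace)
  if (!inherits(vo2_trace, "forcing_fn"))
    stop("'vo2_trace' must be a forcing_fn or a single number")
  structure(
    list(t_start = t_start, duration = duration, t_end = t_start + duration,
         vo2_rest = vo2_rest, vo2_max = vo2_max, vo2_trace = vo2_trace),
    class = "exercise_session"
  )
}

#' @export
print.exercise_session <- function(x, ...) {
  cat(sprintf("Exercise session: [%g, %g] min (%g min), VO2 rest/max = %g/%g\n",
              x$t_start, x$t_end, x$duration, x$vo2_rest, x$vo2_max))
  invisible(x)
}

#' Constant-intensity exercise session with on/off ramps
#'
#' Builds a session whose VO2 trace rises linearly from rest to the target
#' intensity over a short ramp, holds the plateau, and ramps back down at
#' the end, mimicking the smooth onset of measured breath-by-breath data.
#'
#' @param intensity target intensity as a fraction of the aerobic range
#'   (0.6 = 60% VO2max); values above 1 are clipped by the intensity signal.
#' @param duration session length (min).
#' @param t_start session start (min); defaults to the study's 18:00.
#' @param vo2_rest,vo2_max aerobic range of the subject.
#' @param ramp ramp length (min), at most 2; shortened for very short
#'   sessions.
#' @return An [exercise_session()].
#' @examples
#' default_exercise_trace(0.6, 60)
#' @export
default_exercise_trace <- function(intensity, duration, t_start = 1080,
                                   vo2_rest = 3.5, vo2_max = 40, ramp = 2) {
  if (!is.numeric(intensity) || intensity <= 0) stop("'intensity' must be > 0")
  if (duration <= 0) stop("'duration' must be > 0")
  ramp <- min(ramp, duration / 4)
  plateau <- vo2_rest + intensity * (vo2_max - vo2_rest)
  tr <- forcing_fn(
    c(t_start, t_start + ramp, t_start + duration - ramp, t_start + duration),
    c(vo2_rest, plateau, plateau, vo2_rest)
  )
  exercise_session(t_start, duration, vo2_rest, vo2_max, tr)
}

#' Intermittent (bout-structured) exercise session
#'
#' Work bouts at a constant intensity separated by rest periods during which
#' VO2 returns to rest, as in pump-management studies of intermittent
#' aerobic exercise.  The session window spans the whole work+rest block, so
#' the duration-dependent model terms keep accumulating through rests while
#' the intensity-dependent terms fall to zero.
#'
#' @param intensity work-bout intensity (fraction of the aerobic range).
#' @param n_bouts number of work bouts.
#' @param work work-bout length (min).
#' @param rest rest length between bouts (min).
#' @param t_start session start (min).
#' @param vo2_rest,vo2_max aerobic range.
#' @param ramp on/off ramp per transition (min).
#' @return An [exercise_session()] spanning
#'   `n_bouts * work + (n_bouts - 1) * rest` minutes.
#' @examples
#' bout_trace(0.5, n_bouts = 4, work = 15, rest = 5)
#' @export
bout_trace <- function(intensity, n_bouts = 4, work = 15, rest = 5,
                       t_start = 1080, vo2_rest = 3.5, vo2_max = 40, ramp = 1) {
  stopifnot(n_bouts >= 1, work > 0, rest >= 0)
  plateau <- vo2_rest + intensity * (vo2_max - vo2_rest)
  tt <- numeric(0); vv <- numeric(0)
  t <- t_start
  for (b in seq_len(n_bouts)) {
    tt <- c(tt, t, t + ramp, t + work - ramp, t + work)
    vv <- c(vv, vo2_rest, plateau, plateau, vo2_rest)
    t <- t + work + if (b < n_bouts) rest else 0
  }
  duration <- n_bouts * work + (n_bouts - 1) * rest
  exercise_session(t_start, duration, vo2_rest, vo2_max,
                   forcing_fn(tt, vv))
}
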