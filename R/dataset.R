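#' One subject's exercise-visit observations
#'
#' The unit of data the likelihood consumes: timestamped plasma glucose,
#' plasma insulin and VO2 observations from one visit, together with the
#' exercise session and per-sample symptomatic-hypoglycemia flags.
#'
#' @param subject_id identifier.
#' @param times observation times (min, absolute timeline), strictly
#'   increasing.
#' @param glucose plasma glucose (mmol/L), strictly positive.
#' @param insulin plasma insulin (mU/L), non-negative.
#' @param vo2 oxygen consumption at the sample times.
#' @param session the visit's [exercise_session()].
#' @param symptoms logical per-sample flags for symptomatic hypoglycemia;
#'   a single value is recycled.
#' @return Object of class `subject_dataset`.
#' @export
subject_dataset <- function(subject_id, times, glucose, insulin, vo2,
                            session, symptoms = FALSE) {
  n <- length(times)
  if (n < 2L || is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing with at least two samples")
  if (length(glucose) != n || length(insulin) != n || length(vo2) != n)
    stop("glucose, insulin and vo2 must match 'times' in length")
  if (any(!is.finite(glucose)) || any(glucose <= 0))
    stop("glucose observations must be finite and strictly positive")
  if (any(insulin < 0)) stop("insulin observations must be non-negative")
  stopifnot(inherits(session, "exercise_session"))
  symptoms <- rep_len(as.logical(symptoms), n)
  structure(
    list(subject_id = subject_id, times = times, glucose = glucose,
         insulin = insulin, vo2 = vo2, session = session,
         symptoms = symptoms),
    class = "subject_dataset"
  )
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("Subject %s: %d samples on [%g, %g] min, glucose %.2f-%.2f mmol/L\n",
              x$subject_id, length(x$times), min(x$times), max(x$times),
              min(x$glucose), max(x$glucose)))
  print(x$session)
  invisible(x)
}

#' Exclude sessions with hypoglycemia before or during exercise
#'
#' Applies the study exclusion rule to a list of visits: a session is
#' dropped when any sample taken before or during exercise has plasma
#' glucose below 3.3 mmol/L with symptoms, or below 3.0 mmol/L irrespective
#' of symptoms.  Missing symptom flags are treated as asymptomatic with a
#' warning.
#'
#' @param datasets list of [subject_dataset()] objects.
#' @param symptomatic_threshold glucose threshold (mmol/L) applied to
#'   symptomatic samples.
#' @param absolute_threshold glucose threshold applied to every sample.
#' @param quiet suppress the per-exclusion messages.
#' @return The retained datasets; excluded subject ids are attached as
#'   attribute `"excluded"`.
#' @export
filter_sessions <- function(datasets, symptomatic_threshold = 3.3,
                            absolute_threshold = 3.0, quiet = FALSE) {
  keep <- logical(length(datasets))
  excluded <- character(0)
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    sym <- d$symptoms
    if (anyNA(sym)) {
      warning(sprintf("subject %s: missing symptom flags treated as asymptomatic",
                      d$subject_id))
      sym[is.na(sym)] <- FALSE
    }
    pre <- d$times <= d$session$t_end
    hypo <- (d$glucose < symptomatic_threshold & sym) |
      (d$glucose < absolute_threshold)
    keep[i] <- !any(pre & hypo)
    if (!keep[i]) {
      excluded <- c(excluded, as.character(d$subject_id))
      if (!quiet)
        message(sprintf("excluding subject %s: hypoglycemia before/during exercise (min G = %.2f mmol/L)",
                        d$subject_id, min(d$glucose[pre])))
    }
  }
  structure(datasets[keep], excluded = excluded)
}
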