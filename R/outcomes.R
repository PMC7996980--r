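# Exact time a piecewise-linear glucose trace spends inside [lo, hi],
# in minutes, over its whole span.
band_occupancy <- function(time, G, lo = -Inf, hi = Inf) {
  dt <- diff(time)
  g0 <- G[-length(G)]; g1 <- G[-1]
  a <- pmin(g0, g1); b <- pmax(g0, g1)
  flat <- b == a
  frac <- numeric(length(dt))
  frac[flat] <- as.numeric(a[flat] >= lo & a[flat] <= hi)
  if (any(!flat)) {
    ov <- pmax(0, pmin(b[!flat], hi) - pmax(a[!flat], lo))
    frac[!flat] <- ov / (b[!flat] - a[!flat])
  }
  sum(dt * frac)
}

#' Glycemic time-in-range outcomes
#'
#' Percentage of a time window spent in the standard glycemic bands
#' (4-8 mmol/L, 4-10 mmol/L, below 4, below 3.3), computed exactly for the
#' piecewise-linear trajectory on the solver grid, per subject, with cohort
#' mean (sd) and median (IQR).
#'
#' @param trajectories one `emm_trajectory` or a list of them (one per
#'   subject).
#' @param window length-2 numeric, the evaluation window (min); must lie
#'   within every trajectory's span and be non-empty.
#' @param bands named list of `c(lo, hi)` glucose bands (mmol/L).
#' @return Object of class `outcome_report`: `per_subject` (matrix of
#'   percentages, subjects x bands), `cohort` (mean, sd, median, q25, q75
#'   per band), `window`.
#' @examples
#' p <- emm_params(32.1, 0.0021, 0.031, 1.6e-5, Insb = 10)
#' tr <- emm_simulate(p, 10, t_grid = seq(0, 120, 1))
#' glycemic_outcomes(tr, window = c(0, 120))
#' @export
glycemic_outcomes <- function(trajectories, window,
                              bands = list(`4-8` = c(4, 8),
                                           `4-10` = c(4, 10),
                                           `<4` = c(-Inf, 4),
                                           `<3.3` = c(-Inf, 3.3))) {
  if (inherits(trajectories, "emm_trajectory"))
    trajectories <- list(trajectories)
  if (length(window) != 2L || window[2] <= window[1])
    stop("'window' must be a non-empty interval c(start, end)")
  per <- t(vapply(trajectories, function(tr) {
    if (window[1] < min(tr$time) || window[2] > max(tr$time))
      stop("'window' must lie within the trajectory span")
    keep <- tr$time >= window[1] & tr$time <= window[2]
    tt <- tr$time[keep]; gg <- tr$G[keep]
    # clip the boundary segments to the window edges
    if (tt[1] > window[1]) {
      i <- which(tr$time < window[1]); i <- i[length(i)]
      g_edge <- approx(tr$time[c(i, i + 1)], tr$G[c(i, i + 1)], window[1])$y
      tt <- c(window[1], tt); gg <- c(g_edge, gg)
    }
    if (tt[length(tt)] < window[2]) {
      i <- which(tr$time > window[2])[1]
      g_edge <- approx(tr$time[c(i - 1, i)], tr$G[c(i - 1, i)], window[2])$y
      tt <- c(tt, window[2]); gg <- c(gg, g_edge)
    }
    total <- window[2] - window[1]
    vapply(bands, function(b)
      100 * band_occupancy(tt, gg, b[1], b[2]) / total, 0)
  }, numeric(length(bands))))
  colnames(per) <- names(bands)
  cohort <- data.frame(
    mean = colMeans(per),
    sd = apply(per, 2, sd),
    median = apply(per, 2, median),
    q25 = apply(per, 2, quantile, 0.25, names = FALSE),
    q75 = apply(per, 2, quantile, 0.75, names = FALSE)
  )
  structure(list(per_subject = per, cohort = cohort, window = window),
            class = "outcome_report")
}

#' @export
print.outcome_report <- function(x, ...) {
  cat(sprintf("Glycemic outcomes over [%g, %g] min (n = %d):\n",
              x$window[1], x$window[2], nrow(x$per_subject)))
  lab <- c(`4-8` = "Time spent between 4-8 mmol/L",
           `4-10` = "Time spent between 4-10 mmol/L",
           `<4` = "Time spent below 4 mmol/L",
           `<3.3` = "Time spent below 3.3 mmol/L")
  for (nm in rownames(x$cohort)) {
    lb <- if (nm %in% names(lab)) lab[[nm]] else nm
    cat(sprintf("  %-33s %5.1f%% (sd %4.1f), median %5.1f%% (IQR %.1f-%.1f)\n",
                lb, x$cohort[nm, "mean"], x$cohort[nm, "sd"],
                x$cohort[nm, "median"], x$cohort[nm, "q25"],
                x$cohort[nm, "q75"]))
  }
  invisible(x)
}

#' Write an outcome report to CSV
#'
#' @param report an `outcome_report`.
#' @param path output CSV path (per-subject percentages; the cohort summary
#'   goes to `<path>.summary.txt`).
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(report, path) {
  stopifnot(inherits(report, "outcome_report"))
  df <- data.frame(subject = seq_len(nrow(report$per_subject)),
                   report$per_subject, check.names = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  con <- file(paste0(path, ".summary.txt"), "w")
  sink(con); print(report); sink(); close(con)
  invisible(path)
}
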