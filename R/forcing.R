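#' Build a forcing signal from timestamped samples
#'
#' Turns measured samples (e.g. plasma insulin, VO2) into a callable forcing
#' function for the ODE right-hand side: piecewise linear between samples,
#' constant beyond the sampled range, exact at the sample points.  A single
#' sample yields a constant signal.
#'
#' @param times sample times (min), strictly increasing.
#' @param values sampled values, non-negative, same length as `times`.
#' @return A function of time of class `forcing_fn`, with the breakpoints
#'   retained as attributes `times` and `values`.
#' @examples
#' f <- forcing_fn(c(0, 10), c(10, 20))
#' f(5) # 15
#' @export
forcing_fn <- function(times, values) {
  if (length(times) == 0L) stop("forcing requires at least one sample")
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length")
  if (anyDuplicated(times)) stop("duplicate timestamps in forcing samples")
  if (is.unsorted(times, strictly = TRUE)) stop("forcing times must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("forcing values must be finite and non-negative")
  if (length(times) == 1L) {
    v <- values
    f <- function(t) rep(v, length(t))
  } else {
    f <- approxfun(times, values, rule = 2)
  }
  structure(f, times = times, values = values, class = c("forcing_fn", "function"))
}

#' @export
print.forcing_fn <- function(x, ...) {
  tt <- attr(x, "times")
  cat(sprintf("Forcing signal: %d breakpoint(s) on [%g, %g] min, range [%g, %g]\n",
              length(tt), min(tt), max(tt),
              min(attr(x, "values")), max(attr(x, "values"))))
  invisible(x)
}

# Breakpoint matrix covering [t0, t1] for deSolve's linear forcing
# interpolation (constant extrapolation realised by explicit end rows).
forcing_matrix <- function(f, t0, t1) {
  if (is.numeric(f) && length(f) == 1L)
    return(cbind(c(t0, t1), c(f, f)))
  if (!inherits(f, "forcing_fn"))
    stop("forcing must be a forcing_fn or a single number")
  tt <- attr(f, "times")
  vv <- attr(f, "values")
  keep <- tt > t0 & tt < t1
  tt2 <- c(t0, tt[keep], t1)
  vv2 <- c(f(t0), vv[keep], f(t1))
  cbind(tt2, vv2)
}
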