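#' Log-normal prior specification for the model parameters
#'
#' Independent log-normal priors on the estimated parameters (all are
#' strictly positive).  The defaults centre the rate constants on values
#' typical for minimal-model studies in type 1 diabetes and leave the
#' exercise gains weakly informed; they are configurable assumptions, not
#' canonical values.
#'
#' @param location geometric means (natural scale) for
#'   `Gp0, p1, p2, p3, e1, e2`.
#' @param log_sd standard deviations on the log scale, same order.
#' @return Object of class `emm_prior` with fields `meanlog`, `sdlog`.
#' @examples
#' emm_prior()
#' @export
emm_prior <- function(location = c(Gp0 = 35, p1 = 0.0025, p2 = 0.03,
                                   p3 = 1.5e-5, e1 = 1, e2 = 1),
                      log_sd = c(Gp0 = 0.5, p1 = 0.5, p2 = 0.5,
                                 p3 = 0.5, e1 = 1, e2 = 1)) {
  nm <- c("Gp0", "p1", "p2", "p3", "e1", "e2")
  if (!all(nm %in% names(location)) || !all(nm %in% names(log_sd)))
    stop("prior needs named entries for ", paste(nm, collapse = ", "))
  location <- location[nm]; log_sd <- log_sd[nm]
  if (any(location <= 0)) stop("prior locations must be strictly positive")
  if (any(log_sd <= 0)) stop("prior log-sd must be strictly positive")
  structure(list(meanlog = log(location), sdlog = log_sd),
            class = "emm_prior")
}

#' @export
print.emm_prior <- function(x, ...) {
  cat("Log-normal priors (geometric mean, log-sd):\n")
  for (nm in names(x$meanlog))
    cat(sprintf("  %-4s %.4g (log-sd %.2f)\n", nm, exp(x$meanlog[nm]), x$sdlog[nm]))
  invisible(x)
}

# short stable fingerprint of a prior, recorded in chain metadata
prior_hash <- function(prior) {
  s <- paste(format(c(prior$meanlog, prior$sdlog), digits = 15), collapse = ",")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}
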