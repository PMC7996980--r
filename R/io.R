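#' Read and write subject datasets as CSV
#'
#' The on-disk schema has columns `time_min, glucose_mmol_L, insulin_mU_L,
#' vo2, exercise_flag, symptoms_flag`, preceded by `#`-comment header lines
#' carrying the subject id and session metadata (start, duration, VO2
#' rest/max).  Times are absolute minutes from 00:00 of the visit day.
#' `write_dataset` followed by `read_dataset` and a second `write_dataset`
#' reproduces the file byte for byte.
#'
#' @param data a [subject_dataset()].
#' @param path CSV file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   a [subject_dataset()].
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "subject_dataset"))
  ses <- data$session
  hdr <- c(
    sprintf("# subject_id: %s", data$subject_id),
    sprintf("# session_t_start: %.15g", ses$t_start),
    sprintf("# session_duration: %.15g", ses$duration),
    sprintf("# session_vo2_rest: %.15g", ses$vo2_rest),
    sprintf("# session_vo2_max: %.15g", ses$vo2_max)
  )
  df <- data.frame(time_min = data$times, glucose_mmol_L = data$glucose,
                   insulin_mU_L = data$insulin, vo2 = data$vo2,
                   exercise_flag = data$times >= ses$t_start &
                     data$times <= ses$t_end,
                   symptoms_flag = data$symptoms)
  con <- file(path, "w")
  writeLines(hdr, con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  need_meta <- c("subject_id", "session_t_start", "session_duration",
                 "session_vo2_rest", "session_vo2_max")
  miss <- setdiff(need_meta, names(meta))
  if (length(miss))
    stop("dataset header missing metadata: ", paste(miss, collapse = ", "))
  df <- read.csv(path, comment.char = "#")
  need <- c("time_min", "glucose_mmol_L", "insulin_mU_L", "vo2",
            "exercise_flag", "symptoms_flag")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dataset schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (is.unsorted(df$time_min, strictly = TRUE))
    stop("validation error: time_min must be strictly increasing")
  t_start <- as.numeric(meta$session_t_start)
  duration <- as.numeric(meta$session_duration)
  vo2_rest <- as.numeric(meta$session_vo2_rest)
  vo2_max <- as.numeric(meta$session_vo2_max)
  session <- exercise_session(t_start, duration, vo2_rest, vo2_max,
                              forcing_fn(df$time_min, df$vo2))
  subject_dataset(meta$subject_id, df$time_min, df$glucose_mmol_L,
                  df$insulin_mU_L, df$vo2, session, df$symptoms_flag)
}

#' Persist and reload MCMC chains
#'
#' Chains are stored as CSV (one column per parameter plus `deviance`) with
#' a JSON sidecar `<path>.meta.json` recording seed, run length, variant,
#' fixed `Insb` and a prior fingerprint, so any stored chain can be
#' regenerated exactly.
#'
#' @param fit an [emm_fit()].
#' @param path CSV path for the draws.
#' @return `write_chains` returns `path` invisibly; `read_chains` returns a
#'   list with `chains`, `deviance` and `meta`.
#' @export
write_chains <- function(fit, path) {
  stopifnot(inherits(fit, "emm_fit"))
  df <- data.frame(fit$chains, deviance = fit$deviance)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  meta <- list(seed = fit$seed, n_iter = fit$n_iter, n_burn = fit$n_burn,
               variant = fit$variant, Insb = fit$Insb,
               subject_id = fit$data$subject_id,
               acc_rate = fit$acc_rate,
               prior_hash = prior_hash(fit$prior),
               package_version = as.character(utils::packageVersion("minmodex")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_chains
#' @export
read_chains <- function(path) {
  df <- read.csv(path)
  if (!("deviance" %in% names(df))) stop("chain file lacks a deviance column")
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  list(chains = as.matrix(df[setdiff(names(df), "deviance")]),
       deviance = df$deviance, meta = meta)
}

#' Persist and reload a virtual cohort
#'
#' Flat CSV with one row per subject and columns
#' `Gp0, p1, p2, p3, Insb, e1, e2, variant`.
#'
#' @param cohort list of [emm_params()].
#' @param path CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a list of
#'   [emm_params()].
#' @export
write_cohort <- function(cohort, path) {
  df <- do.call(rbind, lapply(cohort, as.data.frame))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path)
  need <- c("Gp0", "p1", "p2", "p3", "Insb", "e1", "e2", "variant")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort schema error: missing column(s) ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    emm_params(df$Gp0[i], df$p1[i], df$p2[i], df$p3[i], df$Insb[i],
               df$e1[i], df$e2[i], df$variant[i]))
}
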