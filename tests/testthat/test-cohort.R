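test_that("the default schedule reproduces the 14-point study design", {
  sch <- build_schedule()
  expect_length(sch, 14)
  expect_equal(sch[1], 930)        # 15:30 control start
  expect_equal(sum(sch <= 1080), 6) # every 30 min through exercise start
  expect_equal(sum(sch > 1080 & sch <= 1140), 6) # every 10 min during
  expect_equal(sch[sch > 1140], c(1155, 1170))   # every 15 min recovery
})

test_that("schedule segments respond to their durations", {
  expect_equal(max(build_schedule(recovery = 0)), 1140) # ends at exercise end
  sch10 <- build_schedule(exercise_dur = 10, recovery = 0)
  expect_equal(sch10[sch10 > 1080], 1090) # exactly one during-exercise sample
  expect_error(build_schedule(control_start = 1100), "before exercise")
  expect_error(build_schedule(exercise_dur = -5), "positive")
})

test_that("cohort sampling is seeded and respects the spec", {
  spec <- cohort_spec(n_subjects = 6, seed = 77)
  c1 <- sample_cohort(spec)
  c2 <- sample_cohort(spec)
  expect_identical(c1, c2)
  expect_length(c1, 6)
  for (p in c1) expect_s3_class(p, "emm_params")
  c3 <- sample_cohort(cohort_spec(n_subjects = 6, seed = 78))
  expect_false(identical(c1, c3))

  # degenerate spread pins every subject at the location values
  c0 <- sample_cohort(cohort_spec(n_subjects = 3, log_sd = 0, seed = 1))
  expect_equal(c0[[1]]$Gp0, 32.1)
  expect_equal(c0[[2]]$p3, 1.6e-5)
  expect_identical(c0[[1]], c0[[3]])
})

test_that("cohort draws concentrate on the configured geometric mean", {
  spec <- cohort_spec(n_subjects = 10000, log_sd = 0.5, seed = 123)
  cohort <- sample_cohort(spec)
  p1s <- vapply(cohort, function(p) p$p1, 0)
  gm <- exp(mean(log(p1s)))
  expect_lt(abs(gm / 0.0021 - 1), 0.02)
})

test_that("generated datasets follow the multiplicative noise model", {
  p <- ref_params()
  ses <- ref_session()
  sch <- build_schedule()
  # zero noise reproduces the trajectory exactly
  d0 <- generate_dataset(p, sch, ses, noise_cv = 0, seed = 1)
  expect_equal(d0$glucose, attr(d0, "truth"))
  # determinism
  d1 <- generate_dataset(p, sch, ses, seed = 99)
  d2 <- generate_dataset(p, sch, ses, seed = 99)
  expect_identical(d1$glucose, d2$glucose)
  expect_false(identical(d1$glucose,
                         generate_dataset(p, sch, ses, seed = 100)$glucose))
  # dataset invariants hold by construction
  expect_s3_class(d1, "subject_dataset")
  expect_length(d1$times, 14)
  expect_true(all(d1$glucose > 0))
})

test_that("replicate observations at one time point have ~2% CV", {
  p <- ref_params()
  ses <- ref_session()
  sch <- build_schedule()
  truth <- attr(generate_dataset(p, sch, ses, noise_cv = 0, seed = 1), "truth")
  k <- 10 # the mid-exercise sample
  set.seed(2024)
  reps <- truth[k] * (1 + 0.02 * rnorm(10000))
  cv <- sd(reps) / mean(reps)
  expect_lt(abs(cv - 0.02), 0.001)
  # the same holds through the generator itself on a smaller replicate set
  obs_k <- vapply(1:400, function(s)
    generate_dataset(p, sch, ses, seed = 5000 + s)$glucose[k], 0)
  expect_lt(abs(sd(obs_k) / mean(obs_k) - 0.02), 0.004)
})

test_that("constant-intensity sessions plateau at the requested fraction", {
  ses <- default_exercise_trace(0.6, 60, t_start = 1080)
  mid <- seq(1085, 1135, 5)
  pv <- pvo2max(ses$vo2_trace(mid), ses$vo2_rest, ses$vo2_max)
  expect_equal(pv, rep(0.6, length(mid)), tolerance = 1e-12)
  # plateau length respects the ramps
  ses30 <- default_exercise_trace(0.5, 30, t_start = 0)
  expect_equal(ses30$duration, 30)
  expect_equal(pvo2max(ses30$vo2_trace(15), 3.5, 40), 0.5)
  # full intensity clips at 1
  ses1 <- default_exercise_trace(1.3, 60, t_start = 0)
  expect_equal(pvo2max(ses1$vo2_trace(30), 3.5, 40), 1)
})

test_that("bout sessions return to rest between work periods", {
  ses <- bout_trace(0.5, n_bouts = 4, work = 15, rest = 5, t_start = 1080)
  expect_equal(ses$duration, 75)
  # mid-bout intensity
  expect_equal(pvo2max(ses$vo2_trace(1087), ses$vo2_rest, ses$vo2_max), 0.5)
  # mid-rest the intensity signal is back to zero
  rest_mid <- 1080 + 15 + 2.5
  expect_equal(pvo2max(ses$vo2_trace(rest_mid), ses$vo2_rest, ses$vo2_max), 0)
})

test_that("full synthetic study runs end to end in fast mode", {
  spec <- cohort_spec(n_subjects = 2, seed = 55)
  study <- generate_study(spec)
  expect_length(study$datasets, 2)
  kept <- filter_sessions(study$datasets, quiet = TRUE)
  fit <- emm_fit(kept[[1]], variant = 6, n_iter = 2000, n_burn = 1500,
                 seed = 1)
  r <- compute_dic(fit)
  expect_true(is.finite(r$DIC))
  expect_identical(r$DIC, r$D_bar + r$pD)
})
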