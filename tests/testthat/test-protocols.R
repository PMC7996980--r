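test_that("insulin submodel obeys its linear-chain closed forms", {
  cfg <- insulin_kinetics()
  # nothing in, nothing out
  f0 <- insulin_submodel(0, t_range = c(0, 300), config = cfg)
  expect_equal(max(f0(seq(0, 300, 10))), 0)
  # constant basal plateaus at u/(ke*V_I)
  f1 <- insulin_submodel(1.0, t_range = c(0, 1000), config = cfg,
                         init = c(0, 0, 0))
  plateau <- 1.0 * 1000 / 60 / (cfg$ke * cfg$V_I)
  expect_lt(abs(f1(1000) / plateau - 1), 0.01)
  # steady start holds the plateau from t = 0
  f2 <- insulin_submodel(1.0, t_range = c(0, 300), config = cfg)
  expect_equal(f2(0), plateau, tolerance = 1e-6)
  expect_lt(max(abs(f2(seq(0, 300, 10)) - plateau)) / plateau, 1e-4)
  # bolus increments scale linearly with the dose
  base <- insulin_submodel(0.8, t_range = c(0, 400), config = cfg)
  b1 <- insulin_submodel(0.8, data.frame(time = 60, units = 4),
                         t_range = c(0, 400), config = cfg)
  b2 <- insulin_submodel(0.8, data.frame(time = 60, units = 1),
                         t_range = c(0, 400), config = cfg)
  tt <- seq(0, 400, 1)
  inc1 <- b1(tt) - base(tt)
  inc2 <- b2(tt) - base(tt)
  expect_equal(max(inc2) / max(inc1), 0.25, tolerance = 1e-3)
  expect_error(insulin_submodel(0.8, data.frame(time = 60, units = -1)),
               "negative")
  expect_error(insulin_submodel(-0.5), "negative")
})

test_that("meal appearance conserves carbohydrate mass", {
  cfg <- meal_kinetics()
  m0 <- meal_submodel(0, meal_time = 480)
  expect_equal(max(m0(seq(400, 900, 10))), 0)
  m <- meal_submodel(75, meal_time = 480, config = cfg)
  tt <- seq(480, 480 + 600, 0.5)
  ra <- m(tt)
  auc <- sum((ra[-1] + ra[-length(ra)]) / 2 * diff(tt))
  total <- 75 * cfg$mmol_per_g * cfg$bioavail / cfg$V_G
  expect_lt(abs(auc / total - 1), 0.001)
  expect_equal(attr(m, "total"), total)
  # appearance is still positive when exercise starts 90 min post-meal
  expect_gt(m(480 + 90), 0.01)
  expect_true(all(ra >= 0))
})

test_that("glycemic outcomes follow band geometry", {
  const <- function(g) structure(
    data.frame(time = 0:100, G = rep(g, 101), X = 0, inc1 = 0, inc2 = 0),
    class = c("emm_trajectory", "data.frame"))
  r5 <- glycemic_outcomes(const(5), window = c(0, 100))
  expect_equal(unname(r5$per_subject[1, ]), c(100, 100, 0, 0))
  r9 <- glycemic_outcomes(const(9), window = c(0, 100))
  expect_equal(unname(r9$per_subject[1, c("4-8", "4-10")]), c(0, 100))
  # linear ramp 3 -> 5: half the window is below 4
  ramp <- structure(
    data.frame(time = c(0, 100), G = c(3, 5), X = 0, inc1 = 0, inc2 = 0),
    class = c("emm_trajectory", "data.frame"))
  rr <- glycemic_outcomes(ramp, window = c(0, 100))
  expect_equal(unname(rr$per_subject[1, "<4"]), 50)
  expect_equal(unname(rr$per_subject[1, "4-8"]), 50)
  expect_error(glycemic_outcomes(const(5), window = c(50, 50)), "non-empty")
  expect_error(glycemic_outcomes(const(5), window = c(-10, 50)), "span")
})

test_that("band nesting holds on simulated cohort outcomes", {
  cohort <- sample_cohort(cohort_spec(n_subjects = 4, seed = 31))
  res <- run_study2(cohort, "pump-stop")
  per <- res$outcomes$per_subject
  expect_true(all(per[, "4-8"] <= per[, "4-10"] + 1e-9))
  expect_true(all(per[, "<3.3"] <= per[, "<4"] + 1e-9))
  expect_true(all(per >= 0 & per <= 100))
})

test_that("protocol grid and spec validation match the study design", {
  arms <- study1_protocols()
  expect_equal(nrow(arms), 8)
  expect_equal(arms$intensity[arms$protocol == 4], 0.50)
  expect_equal(arms$bolus_reduction[arms$protocol == 4], 0.75)
  expect_equal(arms$duration[arms$protocol == 7], 30)
  expect_error(protocol_spec(bolus_reduction = 1.2), "\\[0, 1\\]")
  expect_error(protocol_spec(bolus_reduction = 0.5, pump_suspend = TRUE),
               "exactly one")
  expect_error(protocol_spec(duration = 60,
                             bouts = list(n = 4, work = 10, rest = 5)),
               "sum to the stated")
})

test_that("larger bolus reductions never lower glucose", {
  cohort <- sample_cohort(cohort_spec(n_subjects = 3, seed = 62))
  r50 <- run_study1(cohort, 3) # 50% VO2max, 60 min, 50% reduction
  r75 <- run_study1(cohort, 4) # same exercise, 75% reduction
  for (i in seq_along(cohort)) {
    g50 <- r50$trajectories[[i]]$G
    g75 <- r75$trajectories[[i]]$G
    expect_true(all(g75 >= g50 - 1e-8))
  }
  expect_true(all(r75$end_exercise_glucose >= r50$end_exercise_glucose))
})

test_that("study-2 strategies modulate insulin as specified", {
  p <- ref_params()
  res_stop <- run_study2(list(p), "pump-stop")
  res_80 <- run_study2(list(p), "80%-basal-90min")
  tr_stop <- res_stop$trajectories[[1]]
  tr_80 <- res_80$trajectories[[1]]
  t_ex <- attr(tr_stop, "t_exercise")[1]
  # before the basal change both arms are at rest
  pre <- tr_stop$time < t_ex - 90
  expect_equal(tr_stop$G[pre], tr_80$G[pre], tolerance = 1e-6)
  # the early-reduction arm enters exercise with higher glucose
  i_start <- which.min(abs(tr_80$time - t_ex))
  expect_gt(tr_80$G[i_start], tr_stop$G[i_start])
  # the intensity signal vanishes during within-session rests
  rest_mid <- t_ex + 15 + 2.5
  i_rest <- which.min(abs(tr_80$time - rest_mid))
  expect_equal(tr_80$inc1[i_rest], 0)
})

test_that("exercise effect can be disabled for attribution runs", {
  p0 <- ref_params(e1 = 0, e2 = 0)
  res <- run_study2(list(p0), "50%-basal-90min")
  tr <- res$trajectories[[1]]
  expect_true(all(tr$inc1 == 0) && all(tr$inc2 == 0))
  # glucose still rises because insulin was reduced (a negative drop)
  expect_lt(res$glucose_drop[1], 0)
})
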