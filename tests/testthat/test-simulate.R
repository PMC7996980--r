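test_that("forcing interpolation is linear, exact and constant-extrapolated", {
  f <- forcing_fn(0, 12)
  expect_equal(f(c(-50, 0, 1000)), c(12, 12, 12))
  g <- forcing_fn(c(0, 10), c(10, 20))
  expect_equal(g(5), 15)
  expect_equal(g(c(0, 10)), c(10, 20))
  expect_equal(g(c(-5, 25)), c(10, 20)) # beyond the ends
  tt <- c(0, 7, 13, 40); vv <- c(3, 9, 2, 5)
  h <- forcing_fn(tt, vv)
  expect_equal(h(tt), vv)
  expect_error(forcing_fn(numeric(0), numeric(0)), "at least one")
  expect_error(forcing_fn(c(0, 0), c(1, 2)), "duplicate")
  expect_error(forcing_fn(c(5, 1), c(1, 2)), "increasing")
})

test_that("steady state is preserved over 300 min for all six variants", {
  grid <- seq(0, 300, 5)
  for (v in 1:6) {
    p <- ref_params(variant = v)
    tr <- emm_simulate(p, insulin = p$Insb, t_grid = grid)
    G0 <- steady_state(p)[["G"]]
    expect_lt(max(abs(tr$G - G0)) / G0, 1e-6)
    expect_equal(tr$G[1], G0) # first point equals the supplied init
  }
})

test_that("zero-insulin limit matches the closed-form relaxation to Gp0", {
  p <- ref_params()
  grid <- seq(0, 300, 5)
  tr <- emm_simulate(p, insulin = 0, t_grid = grid,
                     init = c(G = p$Gp0 / 2, X = 0))
  exact <- p$Gp0 + (p$Gp0 / 2 - p$Gp0) * exp(-p$p1 * grid)
  expect_lt(max(abs(tr$G - exact) / exact), 1e-6)
})

test_that("tolerance refinement leaves the trajectory unchanged", {
  p <- ref_params()
  ses <- ref_session()
  ins <- default_insulin_profile(p$Insb, ses)
  grid <- seq(930, 1170, 5)
  a <- emm_simulate(p, ins, ses, grid, rtol = 1e-8, atol = 1e-10)
  b <- emm_simulate(p, ins, ses, grid, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(a$G - b$G) / b$G), 1e-5)
})

test_that("steady start requires insulin near basal", {
  p <- ref_params()
  expect_error(emm_simulate(p, insulin = 2 * p$Insb, t_grid = seq(0, 60, 5)),
               "within 10%")
})

test_that("counterfactual pair isolates the exercise effect", {
  grid <- seq(930, 1200, 2)
  ses <- ref_session()
  # zero gains: exercise changes nothing
  p0 <- ref_params(e1 = 0, e2 = 0)
  cp <- counterfactual_pair(p0, p0$Insb, ses, grid)
  expect_equal(cp$with_exercise$G, cp$without_exercise$G, tolerance = 1e-10)
  # session outside the grid span changes nothing
  p <- ref_params()
  far <- ref_session(t_start = 5000)
  cp2 <- counterfactual_pair(p, p$Insb, far, grid)
  expect_equal(cp2$with_exercise$G, cp2$without_exercise$G, tolerance = 1e-10)
  # active gains lower glucose pointwise from the window start on
  cp3 <- counterfactual_pair(p, p$Insb, ses, grid)
  expect_true(all(cp3$with_exercise$G <= cp3$without_exercise$G + 1e-9))
  expect_lt(min(cp3$with_exercise$G - cp3$without_exercise$G), -0.5)
})

test_that("exercise lowers glucose pointwise for every variant", {
  grid <- seq(930, 1200, 5)
  ses <- ref_session()
  for (v in 1:6) {
    p <- ref_params(variant = v)
    cp <- counterfactual_pair(p, p$Insb, ses, grid)
    expect_true(all(cp$with_exercise$G <= cp$without_exercise$G + 1e-9),
                label = sprintf("variant %d monotone", v))
  }
})

test_that("trajectory diagnostics expose the inc terms", {
  p <- ref_params(variant = 3, e1 = 1.75, e2 = 0)
  ses <- ref_session()
  grid <- c(seq(930, 1080, 30), seq(1085, 1140, 5), seq(1150, 1170, 10))
  tr <- emm_simulate(p, p$Insb, ses, grid)
  pre <- tr$time < ses$t_start
  post <- tr$time > ses$t_end
  expect_true(all(tr$inc1[pre | post] == 0))
  expect_true(all(tr$inc2 == 0)) # variant 3 has no insulin-sensitivity term
  plateau <- tr$time > ses$t_start + 2 & tr$time < ses$t_end - 2
  expect_true(all(tr$inc1[plateau] == 1.75))
})

test_that("trajectory CSV export has the documented schema", {
  p <- ref_params()
  tr <- emm_simulate(p, p$Insb, t_grid = seq(0, 60, 10))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  df <- read.csv(path)
  expect_named(df, c("time_min", "G_mmol_L", "X_per_min", "inc1", "inc2"))
  expect_equal(df$G_mmol_L, tr$G)
  unlink(path)
})
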