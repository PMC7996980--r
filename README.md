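# minmodex

Exercise-extended minimal models of glucose dynamics in type 1 diabetes:
simulation, Bayesian estimation, model selection, and in-silico protocol
replay.

## The problem

People with type 1 diabetes who exercise face a sharp rise in glucose
uptake — and with it, the risk of exercise-induced hypoglycemia.
Simulation environments used to develop artificial-pancreas control
algorithms need glucoregulatory models that capture this effect.
`minmodex` implements six variants of the Bergman Minimal Model extended
with exercise action, for researchers building or evaluating in-silico
exercise-management strategies:

$$\dot X = -p_2 X + p_3 (1 + inc_2(t))\,Ins(t), \qquad
  \dot G = -p_1 (1 + inc_1(t))\,G - X G + p_1 G_{p0}$$

with $G$ plasma glucose (mmol/L), $X$ remote insulin action, $Ins(t)$
measured plasma insulin as a forcing signal.  The increments $inc_1$ (on
glucose effectiveness, the insulin-independent route) and $inc_2$ (on
insulin sensitivity) are active only during the exercise window and are
assembled per variant from gains $e_1, e_2$, the intensity signal
$PVO_{2max}(t)$ and the normalised exercise duration $t_e(t)$ — from a
fixed step (variant 1) to intensity-plus-duration action (variant 6).

The package provides:

* a compiled ODE kernel with exercise, insulin and meal forcing
  (`emm_simulate()`, `counterfactual_pair()`);
* per-subject Bayesian estimation by adaptive random-walk Metropolis
  MCMC under a 2 %-CV Gaussian likelihood (`emm_fit()`, a classed model
  object with `summary`, `coef`, `predict`, `plot`, `residuals`,
  `simulate` methods);
* DIC model comparison across the six variants (`compute_dic()`,
  `emm_select()`);
* seeded virtual-patient cohorts emulating the 14-sample exercise-visit
  design (`cohort_spec()`, `sample_cohort()`, `generate_dataset()`);
* an in-silico protocol engine for two classic exercise-management
  studies — premeal bolus reductions and pre-exercise basal reductions —
  with time-in-range outcome reports (`run_study1()`, `run_study2()`,
  `glycemic_outcomes()`);
* CSV persistence for datasets, chains, cohorts and reports, and a thin
  command-line wrapper (`inst/cli/minmodex.R`) with `synth`, `fit`,
  `select`, `simulate`, `protocol` and `report` subcommands.

## Worked example

Generate a virtual subject on the study's sampling schedule, fit the
intensity-plus-duration variant, and inspect the fit:

```r
library(minmodex)

truth <- emm_params(Gp0 = 32.1, p1 = 0.0021, p2 = 0.031, p3 = 1.6e-5,
                    Insb = 12, e1 = 1.60, e2 = 0.778, variant = 6)
session <- default_exercise_trace(intensity = 0.6, duration = 60,
                                  t_start = 1080)   # 18:00, 60 min
data <- generate_dataset(truth, build_schedule(), session, seed = 42)

fit <- emm_fit(data, variant = 6, fast = TRUE, seed = 1)
summary(fit)
#> Posterior summary, variant 6, subject S1 (2000 draws):
#>        median       q25       q75      mean        sd     cv
#> Gp0 1.511e+01 1.374e+01 1.711e+01 1.569e+01 2.253e+00 0.1436
#> p1  3.269e-03 2.492e-03 4.241e-03 3.487e-03 1.275e-03 0.3657
#> p2  3.854e-02 2.722e-02 4.951e-02 3.935e-02 1.338e-02 0.3400
#> p3  8.664e-06 7.354e-06 1.077e-05 9.320e-06 3.150e-06 0.3380
#> e1  5.206e-01 4.169e-01 7.689e-01 5.830e-01 2.595e-01 0.4451
#> e2  1.736e+00 1.498e+00 2.098e+00 1.789e+00 3.763e-01 0.2103
#> CV range 14%-45%; acceptance 8.9%
compute_dic(fit)
#> DIC = -12.56  (D_bar = -14.60, D(theta_bar) = -16.64, pD = 2.04)
```

Every CV stays below the 100 % identifiability bar and `pD` ≈ 2 effective
parameters — far fewer than the six sampled — which is the point: from 14
observations the parameters are identified *jointly*, not individually.
This particular noise draw settles on a ridge point with lower `Gp0` and
a different `e1`/`e2` split than the generating values, while fitting the
glucose trace equally well; across 20 replicate subjects the 90 %
credible intervals cover the generating parameters in ~97 % of
parameter-by-subject cells (the acceptance suite recomputes this).

Replay a validation scenario — the bolus-reduction study's 50 %-VO₂max
arms — on a 12-subject virtual cohort:

```r
cohort <- sample_cohort(cohort_spec(n_subjects = 12, seed = 42))
r50 <- run_study1(cohort, 3)   # 60 min at 50% VO2max, 50% bolus cut
r75 <- run_study1(cohort, 4)   # same exercise, 75% bolus cut
mean(r75$end_exercise_glucose) - mean(r50$end_exercise_glucose)
#> [1] 2.968149
r75$outcomes
#> Glycemic outcomes over [570, 690] min (n = 12):
#>   Time spent between 4-8 mmol/L      26.1% (sd 28.2), median  18.3% (IQR 0.0-59.9)
#>   Time spent between 4-10 mmol/L     41.4% (sd 32.8), median  49.2% (IQR 0.0-73.5)
#>   Time spent below 4 mmol/L           0.0% (sd  0.0), median   0.0% (IQR 0.0-0.0)
#>   Time spent below 3.3 mmol/L         0.0% (sd  0.0), median   0.0% (IQR 0.0-0.0)
```

The deeper bolus cut ends exercise ~3 mmol/L higher and spends no time
below 4 mmol/L (the 50 % arm spends 11 %) — the safer-from-hypoglycemia
profile the original clinical comparison reported, at the cost of more
time above 10 mmol/L after a 75-g meal with three quarters of the bolus
withheld.

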