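---
title: "Exercise-extended minimal models of glucose dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exercise-extended minimal models of glucose dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

During aerobic exercise, people with type 1 diabetes experience a marked
acceleration of glucose uptake, through two additive routes: an
insulin-*independent* route (muscle contraction recruits GLUT4
transporters directly) and an insulin-*dependent* route (muscle becomes
more sensitive to the insulin that is present).  `minmodex` represents
both on top of the classical two-state Bergman Minimal Model:

$$\dot X(t) = -p_2\,X(t) + p_3\,(1 + inc_2(t))\,Ins(t)$$
$$\dot G(t) = -p_1\,(1 + inc_1(t))\,G(t) - X(t)\,G(t) + p_1\,G_{p0}$$

where $G$ is plasma glucose (mmol/L), $X$ is remote insulin action
(min⁻¹), $Ins(t)$ is measured plasma insulin (mU/L) treated as a known
forcing signal, $p_1$ is glucose effectiveness (min⁻¹), $p_2$ the remote
insulin time constant (min⁻¹), $p_3$ insulin sensitivity
(min⁻² per mU/L) and $G_{p0}$ the glucose level at zero plasma insulin
(mmol/L).  The multiplicative increments $inc_1$ (on glucose
effectiveness — the insulin-independent route) and $inc_2$ (on insulin
sensitivity — the insulin-dependent route) are zero outside the exercise
window and, inside it, are built from two gains $e_1, e_2 \ge 0$, the
intensity signal $PVO_{2max}(t) = (VO_2(t) - VO_{2,rest}) /
(VO_{2,max} - VO_{2,rest})$ clipped to $[0,1]$, and the normalised elapsed
time $t_e(t) = (t - t_{start})/60\,\mathrm{min}$:

| variant | $inc_1$ | $inc_2$ | hypothesis |
|---|---|---|---|
| 1 | $e_1$ | $e_2$ | fixed increase in both routes |
| 2 | $0$ | $e_1$ | insulin-independent route negligible |
| 3 | $e_1$ | $0$ | insulin-dependent route negligible |
| 4 | $e_1 PVO_{2max}$ | $e_2 PVO_{2max}$ | both scale with intensity |
| 5 | $e_1 t_e$ | $e_2 t_e$ | both scale with duration |
| 6 | $e_1 PVO_{2max}$ | $e_2(PVO_{2max} + t_e)$ | intensity, plus duration on the insulin route |

Gains are stored as dimensionless fractions (a "160 %" increase is 1.60).
After the window closes the increments return to zero immediately: no
post-exercise carry-over is modelled, because the short recovery period in
the emulated study design cannot identify one.  For the same reason the
models apply to *moderate continuous* exercise only; interval or anaerobic
exercise raises glucose through mechanisms these equations cannot
represent.

The resting state at basal insulin $Ins_b$ is
$X_0 = (p_3/p_2) Ins_b$, $G_0 = G_{p0}\,p_1 / (p_1 + X_0)$ — the unique
state annihilating both derivatives — and every simulation and likelihood
evaluation starts there.

## Numerical choices

The right-hand side is compiled C, integrated with `deSolve`'s `lsoda`.
Forcing signals (insulin, VO₂, meal appearance) are piecewise linear with
constant extrapolation beyond their samples.  Session window edges and
VO₂-trace breakpoints are inserted into the solver grid so that the
switch-on of the increments is not smeared across an adaptive step.
`emm_simulate()` uses rtol 1e-8 / atol 1e-10; the likelihood inside MCMC
uses rtol 1e-6 / atol 1e-8, which changes simulated glucose by far less
than the 2 % measurement noise while roughly halving run time.  Inside the
solver $G$ is floored at 1e-6 mmol/L so the bilinear $XG$ term stays
benign on degenerate parameter draws; mathematically $\dot G > 0$ as
$G \to 0$, so trajectories remain positive.  VO₂ traces get 1–2 min
linear on/off ramps: measured breath-by-breath data contain no
discontinuities, and the ramps spare the stiff solver an avoidable corner.

## Bayesian estimation

Each subject visit contributes 14 glucose observations on the study
schedule (every 30 min through 2.5 h of closed-loop control, every 10 min
during 60 min of exercise, every 15 min for 30 min of recovery).
Measurement error is Gaussian with a 2 % coefficient of variation, with
the standard deviation proportional to the *prediction*
($\sigma_i = 0.02\,\hat G(t_i)$) so the likelihood stays a proper density
in the parameters.  Identification is open loop: exercise is an external
input, insulin a measured forcing, and $Ins_b$ is fixed to the mean of
the pre-exercise insulin samples rather than estimated.

Priors are independent log-normals on $G_{p0}, p_1, p_2, p_3, e_1, e_2$
(geometric means 35, 0.0025, 0.03, 1.5e-5, 1, 1; log-sd 0.5 for the first
four and 1.0 for the gains).  The source study did not publish its prior
hyperparameters, only that literature values had to inform $p_1$ and
$p_2$ because the pre-exercise window is too short to identify them from
data; these defaults are therefore configurable assumptions
(`emm_prior()`), not canonical values.

Sampling is adaptive random-walk Metropolis on the log-transformed
parameters: a multivariate Gaussian proposal whose covariance is learned
from the chain history (Haario-style rank-one updates, refreshed every
100 iterations) with a global scale tuned towards 30 % acceptance.
Adaptation stops at the end of burn-in, so the kept draws come from a
fixed-kernel chain satisfying detailed balance.  The default run length
is 100,000 iterations keeping the last 20,000; the *fast* mode
(10,000 / 2,000) is used for automated test runs and gives usable — if
noisier — posteriors for these 5–6 parameter problems.  Fixed seeds make
chains bit-identical.  Variants 2 and 3 estimate a single gain; the rest
estimate both.

## Model comparison: DIC and its plug-in

Models are ranked by the deviance information criterion,
$pD = \bar D - D(\hat\theta)$ and $DIC = \bar D + pD$, pooled over
subjects by summation (deviance is additive over independent subjects;
whether the source analysis pooled this way is not stated, so summation
is adopted and documented here).  A variant whose posterior CVs exceed
100 % in any subject is flagged as failing the identifiability criterion.

The plug-in $\hat\theta$ deserves care.  These parameters are identified
*jointly*, along a curved ridge: the flat pre-exercise glucose pins the
nonlinear combination $G_{p0} p_1/(p_1 + (p_3/p_2)Ins_b)$ to within the
2 % noise while leaving each coordinate free over a wide prior range, and
the two exercise gains trade off against each other.  On such a posterior
the *component-wise* natural-scale mean — the classical plug-in — and
even the component-wise median can land far off the ridge, where the
deviance is enormous, producing large spurious negative $pD$ (we observed
$pD \approx -400$ on well-mixed chains).  `compute_dic()` therefore
defaults to the minimum-deviance kept draw as $\hat\theta$: a
likelihood-based point estimate that lies on the identified manifold by
construction, yields $pD \ge 0$, and coincides with the classical value
for approximately Gaussian posteriors (both are then the effective
parameter count).  The classical `"mean"` and the reporting point
estimate `"median"` remain available for comparison.  Both DIC identities
($DIC = \bar D + pD = D(\hat\theta) + 2pD$) hold by construction for any
plug-in.

## The synthetic cohort

No clinical dataset accompanies the source study, so every pipeline is
exercised on seeded synthetic cohorts.  A virtual subject is a log-normal
draw per parameter; the default locations are the selected model's
reported posterior medians ($G_{p0} = 32.1$, $p_1 = 0.0021$,
$p_2 = 0.031$, $p_3 = 1.6\times10^{-5}$, $e_1 = 1.60$, $e_2 = 0.778$,
variant 6) with between-subject log-sd 0.25, inside the spread the
reported interquartile ranges imply, and $Ins_b = 12$ mU/L.  Datasets
follow the 14-point schedule with a 60-min session at 60 % VO₂max and
2 % multiplicative observation noise (non-positive draws are redrawn and
counted).

The synthetic plasma-insulin profile emulates closed-loop behaviour
around exercise — basal until onset, a piecewise-linear decline to 70 %
of basal at the end of the hour, partial recovery afterwards.  The 70 %
floor is not arbitrary: the package's own subcutaneous absorption chain
shows that even a pump stopped dead at exercise onset leaves ~72 % of
basal plasma insulin 60 min later, so a faster decline would be
kinetically impossible.  What the generator does *not* emulate: real
closed-loop feedback (insulin reacting to glucose), glucagon, meal
absorption during the fitting window, sensor artefacts, or post-exercise
physiology.  Passing recovery tests on this generator therefore
demonstrates the estimator is consistent under the stated noise model on
study-shaped data — not that it reproduces any particular clinical
subject.

Two recovery properties are checked routinely, at problem sizes chosen to
keep the full suite in the tens of minutes on a single core: 90 %
credible intervals cover the generating parameters in at least 80 % of
parameter-by-subject cells over 20 subjects (fast-mode MCMC), and the
generating variant 6 attains the lowest pooled DIC in at least 2 of 3
replicate 10-subject cohorts (the design-rate version of this check is
7 of 10 cohorts; 3 is the routine-suite reduction).  A caveat the second
check surfaces honestly: under *constant-intensity* exercise, variant 4
differs from variant 6 only through the duration ramp on the insulin
route, which carries little signal when insulin is suppressed during
exercise — their pooled-DIC margin is a few units, and an occasional
variant-4 win in a replicate cohort is expected behaviour, not a defect.

## The in-silico protocol engine

Model validation replays two exercise-management experiments on a
12-subject virtual cohort.  Because the original supplementary meal and
insulin submodels are unavailable, the engine uses standard linear
stand-ins behind a replaceable interface:

* **Insulin**: two sequential subcutaneous compartments (time constant
  55 min) feeding plasma with clearance 0.138 min⁻¹ from 0.12 L/kg;
  basal rates converge to $Ins_b = u/(k_e V_I)$ and boluses scale
  linearly.  Each virtual subject's basal rate is set to sustain exactly
  its $Ins_b$.
* **Meal**: gut appearance $Ra(t) \propto t\,e^{-t/40\,\mathrm{min}}$
  with bioavailability 0.8 into 0.16 L/kg, added to the glucose equation
  as $Ra(t)/V_G$; the fitting configuration omits this term since meals
  precede the modelled window.

Study 1 is a 75-g breakfast (bolus = carbs / 10 g/U, reduced per arm) with
exercise 90 min later, over the eight intensity × duration × reduction
arms.  Study 2 is intermittent exercise (four 15-min bouts at 50 %
VO₂max, 5-min rests; the duration term keeps accumulating through
within-session rests while the intensity term falls to zero) under pump
stop at onset, 80 % basal reduction 90 min ahead, or 50 % reduction
90 min ahead; "pump stop" is basal → 0 with the depot draining naturally.
Outcomes are exact piecewise-linear occupancy percentages of the standard
glycemic bands (4–8, 4–10, <4, <3.3 mmol/L) plus the start-to-end
exercise glucose drop.  The engine reproduces both headline orderings:
deeper bolus reduction leaves higher end-exercise glucose and less time
below 4 mmol/L, and the early 80 % basal reduction shows the smallest
drop.  Only the orderings are meaningful — the original studies' numeric
outcome tables came from a different (unavailable) simulation backbone
and real patient cohorts.

## Known limitations

* Moderate continuous exercise only; no interval/anaerobic modes, no
  post-exercise carry-over, no glucagon.
* $Ins_b$ is fixed, not estimated; measurement CV is fixed at 2 %.
* Population-level (hierarchical) estimation is out of scope; subjects
  are fitted independently.
* DIC with any plug-in inherits the usual caveats under multimodality;
  `pD` from the min-deviance draw is slightly conservative (it bounds the
  classical value from below on finite chains).
* The protocol engine's meal/insulin kinetics are documented stand-ins;
  absolute time-in-range numbers from it should not be compared against
  clinical tables, only contrasts between arms.
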