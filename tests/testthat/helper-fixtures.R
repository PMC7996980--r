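# Shared fixtures: a reference subject (selected-model posterior medians
# from moderate-exercise data), the study sampling schedule, and a default
# 60-min session at 60% VO2max.

ref_params <- function(variant = 6, e1 = 1.60, e2 = 0.778, Insb = 12) {
  emm_params(Gp0 = 32.1, p1 = 0.0021, p2 = 0.031, p3 = 1.6e-5,
             Insb = Insb, e1 = e1, e2 = e2, variant = variant)
}

ref_session <- function(intensity = 0.6, duration = 60, t_start = 1080) {
  default_exercise_trace(intensity, duration, t_start = t_start)
}

ref_dataset <- function(seed = 1, params = ref_params(),
                        session = ref_session(), noise_cv = 0.02) {
  generate_dataset(params, build_schedule(), session,
                   noise_cv = noise_cv, seed = seed,
                   subject_id = sprintf("T%03d", seed))
}

# random admissible parameter draw for property-style loops
random_params <- function(variant = sample(1:6, 1)) {
  emm_params(Gp0 = exp(rnorm(1, log(32), 0.3)),
             p1 = exp(rnorm(1, log(0.0021), 0.3)),
             p2 = exp(rnorm(1, log(0.031), 0.3)),
             p3 = exp(rnorm(1, log(1.6e-5), 0.3)),
             Insb = exp(rnorm(1, log(12), 0.3)),
             e1 = exp(rnorm(1, log(1.2), 0.5)),
             e2 = exp(rnorm(1, log(0.8), 0.5)),
             variant = variant)
}
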