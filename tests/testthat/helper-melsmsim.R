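# Shared helpers: small study conditions and quick fits for unit tests.

quick_truth <- function(...) {
  melsm_truth(n_subjects = 40, mean_encounters = 5, ...)
}

spec_lmm <- function() {
  melsm_spec("y ~ age + albumin + (1|id)", "log(omega) ~ 1")
}

fit_quick <- function(data, spec, ...) {
  fit_melsm(data, spec, control = list(reltol = 1e-8), ...)
}

# Homoscedastic truth: unit residual SD everywhere (LMM world).
homoscedastic_truth <- function(n_subjects = 60, mean_encounters = 6) {
  melsm_truth(beta_scale = c(age = 0, albumin = 0, trig = 0, platelet = 0),
              sigma_omega = 0, n_subjects = n_subjects,
              mean_encounters = mean_encounters)
}
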