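# Scenario registry: the misspecification practices studied by the package.
#
# Practice 1  ignoring heteroscedasticity (MELSM vs LMM over N and M grids)
# Practice 2  misspecifying location/scale covariates or the scale RE
# Practice 3  ignoring a non-linear (sinusoidal) time trend in the location
# Practice 4  ignoring random slopes present in both submodels
# Practice 5  misspecifying the random-intercept distribution (Student t3)
#
# Within a practice every fitted model shares the same generative truth (and,
# in the runner, the same per-replication dataset), so contrasts between
# models are paired.

#' The correctly specified MELSM of the simulation study
#'
#' `y ~ age + albumin + (1|id)` for the location and
#' `log(omega) ~ age + trig + (1|id)` for the scale — the specification that
#' matches the default generative truth.
#'
#' @return A [melsm_spec()].
#' @export
spec_correct <- function() {
  melsm_spec("y ~ age + albumin + (1|id)", "log(omega) ~ age + trig + (1|id)")
}

#' Build one scenario row
#'
#' @param id Unique scenario identifier.
#' @param label Human-readable label.
#' @param truth A [melsm_truth()] describing the data-generating process.
#' @param spec The fitted [melsm_spec()].
#' @param data_id Identifier of the generative condition; scenarios sharing a
#'   `data_id` are fitted to identical datasets replication by replication.
#' @param practice Practice number (informational).
#' @param replications Default replication count.
#' @param backend Default fitting backend.
#' @param alpha Interval level.
#' @return A one-row tibble with list-columns `truth` and `spec`.
#' @export
melsm_scenario <- function(id, label, truth, spec, data_id = id,
                           practice = NA_integer_, replications = 100L,
                           backend = "mle", alpha = 0.95) {
  stopifnot(inherits(truth, "melsm_truth"), inherits(spec, "melsm_spec"))
  tibble::tibble(
    id = id, label = label, practice = as.integer(practice),
    data_id = data_id, truth = list(truth), spec = list(spec),
    replications = as.integer(replications), backend = backend, alpha = alpha
  )
}

#' Registry of built-in misspecification scenarios
#'
#' @param practices Which practices to include (subset of 1:5).
#' @param p1_n,p1_m Subject-count and encounter-count grids for Practice 1.
#' @param replications Default replication count recorded on each scenario.
#' @return A tibble of scenarios (see [melsm_scenario()]); `id` is unique.
#' @export
melsm_scenarios <- function(practices = 1:5,
                            p1_n = c(100, 300, 500, 1000),
                            p1_m = c(5, 10, 20),
                            replications = 100L) {
  correct <- spec_correct()
  lmm <- melsm_spec("y ~ age + albumin + (1|id)", "log(omega) ~ 1")
  out <- list()
  if (1 %in% practices) {
    for (n in p1_n) for (m in p1_m) {
      truth <- melsm_truth(n_subjects = n, mean_encounters = m)
      cell <- sprintf("p1_n%d_m%d", n, m)
      out <- c(out, list(
        melsm_scenario(paste0(cell, "_melsm"),
                       sprintf("Practice 1 / MELSM (N=%d, M=%d)", n, m),
                       truth, correct, data_id = cell, practice = 1,
                       replications = replications),
        melsm_scenario(paste0(cell, "_lmm"),
                       sprintf("Practice 1 / LMM (N=%d, M=%d)", n, m),
                       truth, lmm, data_id = cell, practice = 1,
                       replications = replications)
      ))
    }
  }
  if (2 %in% practices) {
    truth <- melsm_truth()
    p2 <- list(
      correct = list("Correct", correct),
      all = list("All", melsm_spec(
        "y ~ age + albumin + trig + platelet + (1|id)",
        "log(omega) ~ age + albumin + trig + platelet + (1|id)")),
      mis_y = list("Mis. y", melsm_spec(
        "y ~ albumin + (1|id)", "log(omega) ~ age + trig + (1|id)")),
      mis_omega = list("Mis. omega", melsm_spec(
        "y ~ age + albumin + (1|id)", "log(omega) ~ trig + (1|id)")),
      no_uw = list("No u_omega", melsm_spec(
        "y ~ age + albumin + (1|id)", "log(omega) ~ age + trig")),
      no_uw_mis_omega = list("No u_omega + Mis. omega", melsm_spec(
        "y ~ age + albumin + (1|id)", "log(omega) ~ trig"))
    )
    for (nm in names(p2)) {
      out <- c(out, list(
        melsm_scenario(paste0("p2_", nm),
                       paste0("Practice 2 / ", p2[[nm]][[1]]),
                       truth, p2[[nm]][[2]], data_id = "p2", practice = 2,
                       replications = replications)
      ))
    }
  }
  if (3 %in% practices) {
    truth <- melsm_truth(age_transform = "sin")
    out <- c(out, list(
      melsm_scenario("p3_correct_sin", "Practice 3 / Correct (sinus)",
                     truth,
                     melsm_spec("y ~ sin(age) + albumin + (1|id)",
                                "log(omega) ~ age + trig + (1|id)"),
                     data_id = "p3", practice = 3,
                     replications = replications),
      melsm_scenario("p3_non_sinus", "Practice 3 / Non sinus",
                     truth, correct, data_id = "p3", practice = 3,
                     replications = replications)
    ))
  }
  if (4 %in% practices) {
    truth <- melsm_truth(slope_sd_loc = 1, slope_sd_scale = 0.5)
    out <- c(out, list(
      melsm_scenario("p4_correct_slopes", "Practice 4 / Correct (slopes)",
                     truth,
                     melsm_spec("y ~ age + albumin + (1 + age|id)",
                                "log(omega) ~ age + trig + (1 + age|id)"),
                     data_id = "p4", practice = 4,
                     replications = replications),
      melsm_scenario("p4_no_uw_age", "Practice 4 / No u_omega_age",
                     truth,
                     melsm_spec("y ~ age + albumin + (1 + age|id)",
                                "log(omega) ~ age + trig + (1|id)"),
                     data_id = "p4", practice = 4,
                     replications = replications),
      melsm_scenario("p4_no_slopes", "Practice 4 / No slopes",
                     truth, correct, data_id = "p4", practice = 4,
                     replications = replications)
    ))
  }
  if (5 %in% practices) {
    truth <- melsm_truth(re_distribution = "student_t", re_df = 3)
    out <- c(out, list(
      melsm_scenario("p5_student", "Practice 5 / Student",
                     truth,
                     melsm_spec("y ~ age + albumin + (1|id)",
                                "log(omega) ~ age + trig + (1|id)",
                                re_distribution = "student_t", re_df = 3),
                     data_id = "p5", practice = 5,
                     replications = replications),
      melsm_scenario("p5_gaussian", "Practice 5 / Gaussian",
                     truth, correct, data_id = "p5", practice = 5,
                     replications = replications)
    ))
  }
  dplyr::bind_rows(out)
}
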