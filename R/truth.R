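# The generative parameterisation of the simulation study.

#' Baseline covariate covariance of the PBC study population
#'
#' Covariance matrix of the four standardised baseline covariates (age,
#' albumin, triglycerides, platelets) observed in the Mayo Clinic primary
#' biliary cholangitis trial data; embedded as constants so no external
#' dataset is needed.
#'
#' @return A symmetric positive-definite 4x4 matrix with dimnames
#'   `(age, albumin, trig, platelet)`.
#' @export
pbc_covariate_cov <- function() {
  v <- c( 1.02, -0.23,  0.02, -0.14,
         -0.23,  0.90, -0.10,  0.18,
          0.02, -0.10,  1.00,  0.10,
         -0.14,  0.18,  0.10,  0.89)
  nm <- c("age", "albumin", "trig", "platelet")
  matrix(v, 4, 4, dimnames = list(nm, nm))
}

#' Define the data-generating truth for a simulation scenario
#'
#' The default settings reproduce the study conditions used throughout the
#' package: `N = 200` subjects, on average `M = 15` encounters each
#' (`J_i ~ U{1, 2M - 1}`), baseline covariates from `MVN(0, Sigma)` with the
#' PBC covariance, age increasing by 1 per encounter while the other
#' covariates stay fixed, location fixed effects `(0.5, 0.5, 0, 0)` on
#' (age, albumin, trig, platelet), log-scale fixed effects `(0.8, 0, 0.8, 0)`,
#' and independent Gaussian random intercepts with `sigma_y = 1`,
#' `sigma_omega = 0.5`, `rho = 0`. There are no fixed intercepts in the truth
#' (both are 0).
#'
#' @param beta_loc,beta_scale Named length-4 coefficient vectors over
#'   `(age, albumin, trig, platelet)` for the location and log-scale.
#' @param sigma_y,sigma_omega SD of the location and scale random intercepts.
#'   Under `re_distribution = "student_t"` these are the *scale* parameters of
#'   the t distribution (its SD is `sigma * sqrt(df / (df - 2))`).
#' @param rho Correlation of the two random intercepts (Gaussian only).
#' @param slope_sd_loc,slope_sd_scale Optional SDs of independent Gaussian
#'   random slopes on age in the location resp. scale submodel (`NULL` for
#'   none; the random-slope scenario uses 1 and 0.5).
#' @param re_distribution `"gaussian"` or `"student_t"` for the random
#'   intercepts.
#' @param re_df Degrees of freedom of the Student intercepts (>= 3).
#' @param age_transform `"identity"`, or `"sin"` for the non-linear time
#'   trend `beta_age * sin(age)` in the location model.
#' @param age_step Per-encounter increment of age on the standardised
#'   scale: `age_{i,j} = age_{i,0} + j * age_step`. The default 0.1 is one
#'   calendar year between regular visits expressed in SD units of the PBC
#'   baseline age (SD about 10 years).
#' @param n_subjects Number of subjects N.
#' @param mean_encounters Average number of encounters M per subject.
#' @param covariate_cov Baseline covariate covariance matrix.
#' @return A list of class `melsm_truth`.
#' @export
melsm_truth <- function(beta_loc = c(age = 0.5, albumin = 0.5, trig = 0, platelet = 0),
                        beta_scale = c(age = 0.8, albumin = 0, trig = 0.8, platelet = 0),
                        sigma_y = 1, sigma_omega = 0.5, rho = 0,
                        slope_sd_loc = NULL, slope_sd_scale = NULL,
                        re_distribution = c("gaussian", "student_t"), re_df = 3,
                        age_transform = c("identity", "sin"),
                        age_step = 0.1,
                        n_subjects = 200, mean_encounters = 15,
                        covariate_cov = pbc_covariate_cov()) {
  re_distribution <- match.arg(re_distribution)
  age_transform <- match.arg(age_transform)
  stopifnot(is.numeric(age_step), length(age_step) == 1, age_step > 0)
  covs <- c("age", "albumin", "trig", "platelet")
  beta_loc <- unlist(beta_loc)[covs]
  beta_scale <- unlist(beta_scale)[covs]
  stopifnot(!anyNA(beta_loc), !anyNA(beta_scale),
            sigma_y >= 0, sigma_omega >= 0, abs(rho) <= 1,
            n_subjects >= 1, mean_encounters >= 1)
  if (!is.null(slope_sd_loc)) stopifnot(slope_sd_loc >= 0)
  if (!is.null(slope_sd_scale)) stopifnot(slope_sd_scale >= 0)
  if (re_distribution == "student_t") {
    stopifnot(re_df >= 3)
    if (rho != 0) abort("Student random intercepts are drawn independently; rho must be 0")
  }
  structure(
    list(beta_loc = beta_loc, beta_scale = beta_scale,
         sigma_y = sigma_y, sigma_omega = sigma_omega, rho = rho,
         slope_sd_loc = slope_sd_loc, slope_sd_scale = slope_sd_scale,
         re_distribution = re_distribution,
         re_df = if (re_distribution == "student_t") re_df else NULL,
         age_transform = age_transform,
         age_step = age_step,
         n_subjects = as.integer(n_subjects),
         mean_encounters = as.integer(mean_encounters),
         covariate_cov = covariate_cov),
    class = "melsm_truth"
  )
}

#' @export
print.melsm_truth <- function(x, ...) {
  cat("<melsm_truth>\n")
  cat(sprintf("  N = %d subjects, M = %d mean encounters\n",
              x$n_subjects, x$mean_encounters))
  cat("  beta_loc:  ", paste(sprintf("%s=%g", names(x$beta_loc), x$beta_loc),
                             collapse = ", "), "\n")
  cat("  beta_scale:", paste(sprintf("%s=%g", names(x$beta_scale), x$beta_scale),
                             collapse = ", "), "\n")
  cat(sprintf("  sigma_y = %g, sigma_omega = %g, rho = %g (%s)\n",
              x$sigma_y, x$sigma_omega, x$rho, x$re_distribution))
  if (!is.null(x$slope_sd_loc) || !is.null(x$slope_sd_scale)) {
    cat(sprintf("  random slopes on age: loc SD = %s, scale SD = %s\n",
                x$slope_sd_loc %||% "none", x$slope_sd_scale %||% "none"))
  }
  if (x$age_transform == "sin") cat("  location uses sin(age)\n")
  invisible(x)
}

# Named vector of true parameter values for every parameter a fitted spec
# estimates (fixed intercepts are 0 in the truth; coefficients absent from the
# generative process are 0; sin(age) carries the age coefficient).
truth_parameters <- function(truth, spec) {
  stopifnot(inherits(truth, "melsm_truth"), inherits(spec, "melsm_spec"))
  val <- c()
  fixed_truth <- function(sub, beta) {
    out <- c()
    if (sub$intercept) out <- c("(Intercept)" = 0)
    if (nrow(sub$fixed_terms)) {
      labels <- term_labels(sub$fixed_terms)
      v <- unname(beta[sub$fixed_terms$covariate])
      v[is.na(v)] <- 0
      out <- c(out, setNames(v, labels))
    }
    out
  }
  loc <- fixed_truth(spec$location, truth$beta_loc)
  sca <- fixed_truth(spec$scale, truth$beta_scale)
  val <- c(setNames(loc, paste0("loc_", names(loc))),
           setNames(sca, paste0("scale_", names(sca))))
  rand_truth <- function(random, side) {
    out <- c()
    if (is.null(random)) return(out)
    if (random$intercept) {
      out <- c(out, setNames(if (side == "loc") truth$sigma_y else truth$sigma_omega,
                             sprintf("sd_%s_(Intercept)", side)))
    }
    if (!is.null(random$slope)) {
      sd_true <- if (side == "loc") truth$slope_sd_loc else truth$slope_sd_scale
      out <- c(out, setNames(sd_true %||% 0,
                             sprintf("sd_%s_%s", side, random$slope)))
    }
    out
  }
  val <- c(val, rand_truth(spec$location$random, "loc"),
           rand_truth(spec$scale$random, "scale"))
  if (spec$correlated) val <- c(val, cor_loc_scale = truth$rho)
  val
}
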