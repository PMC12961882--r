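# Longitudinal data generator: baseline covariates, encounter process,
# random effects, heteroscedastic outcomes.

#' Draw baseline covariates for a synthetic population
#'
#' Subjects are drawn from a zero-mean multivariate normal with the given
#' covariance. Standard-normal deviates are consumed in row-major order
#' (subject by subject), so with a fixed seed the first subjects' covariates
#' do not depend on `n_subjects`.
#'
#' @param n_subjects Number of subjects.
#' @param cov Covariance matrix (defaults to [pbc_covariate_cov()]).
#' @param seed Integer seed for this stage.
#' @return A tibble with columns `id` and one column per covariate.
#' @export
draw_baseline_covariates <- function(n_subjects, cov = pbc_covariate_cov(),
                                     seed = 1L) {
  stopifnot(n_subjects >= 1, is.matrix(cov), nrow(cov) == ncol(cov))
  if (max(abs(cov - t(cov))) > 1e-8) abort("covariance matrix must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    abort(sprintf("covariance matrix is not positive definite: smallest eigenvalue %.3g <= 0",
                  min(ev)))
  }
  p <- ncol(cov)
  z <- with_seed(seed, matrix(rnorm(n_subjects * p), ncol = p, byrow = TRUE))
  x <- z %*% chol(cov)
  colnames(x) <- colnames(cov) %||% paste0("x", seq_len(p))
  dplyr::bind_cols(tibble::tibble(id = seq_len(n_subjects)),
                   tibble::as_tibble(x))
}

#' Draw per-subject encounter counts
#'
#' Encounter counts follow the discrete uniform `J_i ~ U{1, 2M - 1}`, a
#' regular visiting schedule uninformative of the outcome, with mean `M`.
#'
#' @param n_subjects Number of subjects.
#' @param m Average number of encounters M (>= 1).
#' @param seed Integer seed for this stage.
#' @return An integer vector of length `n_subjects` with values in
#'   `{1, ..., 2M - 1}`.
#' @export
draw_encounter_counts <- function(n_subjects, m = 15, seed = 1L) {
  stopifnot(n_subjects >= 1)
  if (m < 1) abort("mean encounter count m must be at least 1")
  with_seed(seed, sample.int(2L * as.integer(m) - 1L, n_subjects, replace = TRUE))
}

#' Expand baseline covariates into encounter rows
#'
#' Subject `i` contributes `J_i` rows with encounter index `j = 0, ...,
#' J_i - 1` (the baseline visit is `j = 0`). Age is the only time-varying
#' covariate, advancing by `age_step` (standardised-scale units) per
#' encounter: `age_{i,j} = age_{i,0} + j * age_step`; all other covariates
#' are carried forward unchanged.
#'
#' @param baseline Tibble from [draw_baseline_covariates()].
#' @param counts Integer vector of encounter counts aligned with `baseline`.
#' @param age_step Standardised-scale age increment per encounter.
#' @return A long tibble with columns `id`, `j`, and the covariates.
#' @export
expand_longitudinal <- function(baseline, counts, age_step = 0.1) {
  stopifnot(is.data.frame(baseline), nrow(baseline) == length(counts),
            all(counts >= 1))
  idx <- rep.int(seq_len(nrow(baseline)), counts)
  out <- baseline[idx, , drop = FALSE]
  out$j <- unlist(lapply(counts, function(k) seq_len(k) - 1L), use.names = FALSE)
  out$age <- out$age + out$j * age_step
  dplyr::relocate(tibble::as_tibble(out), "id", "j")
}

#' Draw subject-level random effects
#'
#' Random intercepts for location and scale come from the bivariate normal
#' with SDs `(sigma_y, sigma_omega)` and correlation `rho`, or (under the
#' Student option) independently from t distributions with `re_df` degrees of
#' freedom scaled by the same sigmas. Random slopes on age, when present, are
#' independent Gaussians with their stated SDs.
#'
#' @param truth A [melsm_truth()].
#' @param seed Integer seed for this stage.
#' @return A tibble with one row per subject: `id`, `u_loc_intercept`,
#'   `u_scale_intercept`, and `u_loc_slope` / `u_scale_slope` when the truth
#'   includes slopes.
#' @export
draw_random_effects <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "melsm_truth"))
  n <- truth$n_subjects
  with_seed(seed, {
    if (truth$re_distribution == "student_t") {
      u_loc <- truth$sigma_y * rt(n, df = truth$re_df)
      u_scale <- truth$sigma_omega * rt(n, df = truth$re_df)
    } else {
      z <- matrix(rnorm(2 * n), ncol = 2, byrow = TRUE)
      s2 <- matrix(c(truth$sigma_y^2,
                     truth$rho * truth$sigma_y * truth$sigma_omega,
                     truth$rho * truth$sigma_y * truth$sigma_omega,
                     truth$sigma_omega^2), 2, 2)
      u <- z %*% chol_psd(s2)
      u_loc <- u[, 1]
      u_scale <- u[, 2]
    }
    out <- tibble::tibble(id = seq_len(n),
                          u_loc_intercept = u_loc,
                          u_scale_intercept = u_scale)
    if (!is.null(truth$slope_sd_loc)) {
      out$u_loc_slope <- rnorm(n, 0, truth$slope_sd_loc)
    }
    if (!is.null(truth$slope_sd_scale)) {
      out$u_scale_slope <- rnorm(n, 0, truth$slope_sd_scale)
    }
    out
  })
}

# Cholesky factor tolerant of zero-variance rows (sigma = 0 scenarios).
chol_psd <- function(s) {
  ev <- eigen(s, symmetric = TRUE)
  v <- pmax(ev$values, 0)
  t(ev$vectors %*% (t(ev$vectors) * sqrt(v)))
}

#' Residual standard deviation from the scale submodel
#'
#' `omega = exp(eta)` where `eta` is the scale linear predictor (fixed part
#' plus random-effect contribution). The predictor is clipped to
#' `[-30, 30]` before exponentiation as an overflow guard; clipping is
#' reported with a warning and never triggers under the default truths.
#'
#' @param X_scale Numeric matrix of scale covariate rows (or a vector for a
#'   single row).
#' @param beta_scale Coefficient vector conformable with `X_scale`.
#' @param u Random-effect contribution to the predictor, per row (default 0).
#' @return The strictly positive vector of residual SDs `omega`.
#' @export
compute_scale <- function(X_scale, beta_scale, u = 0) {
  if (!is.matrix(X_scale)) X_scale <- matrix(X_scale, nrow = 1)
  eta <- drop(X_scale %*% beta_scale) + u
  if (any(abs(eta) > 30)) {
    warning(sprintf("scale linear predictor clipped to [-30, 30] for %d row(s)",
                    sum(abs(eta) > 30)))
    eta <- pmin(pmax(eta, -30), 30)
  }
  exp(eta)
}

#' Generate outcomes for expanded covariate rows
#'
#' Applies the location and scale equations of the generative model:
#' `y_ij = beta_y . x_ij + u_loc (+ u_loc_slope * age) + eps_ij` with
#' `eps_ij ~ N(0, omega_ij^2)` and
#' `omega_ij = exp(beta_w . x_ij + u_scale (+ u_scale_slope * age))`.
#' Under `age_transform = "sin"` the location (and only the location) uses
#' `sin(age)` in place of age.
#'
#' @param rows Long covariate tibble from [expand_longitudinal()].
#' @param random_effects Tibble from [draw_random_effects()].
#' @param truth The [melsm_truth()].
#' @param seed Integer seed for the measurement noise.
#' @return `rows` with columns `y` and `.omega` (the true residual SD)
#'   appended.
#' @export
generate_outcomes <- function(rows, random_effects, truth, seed = 1L) {
  stopifnot(inherits(truth, "melsm_truth"),
            all(rows$id %in% random_effects$id))
  re <- random_effects[match(rows$id, random_effects$id), ]
  covs <- names(truth$beta_loc)
  X <- as.matrix(rows[covs])
  X_loc <- X
  if (truth$age_transform == "sin") X_loc[, "age"] <- sin(X_loc[, "age"])
  eta_loc <- drop(X_loc %*% truth$beta_loc) + re$u_loc_intercept
  if ("u_loc_slope" %in% names(re)) {
    eta_loc <- eta_loc + re$u_loc_slope * rows$age
  }
  u_scale <- re$u_scale_intercept
  if ("u_scale_slope" %in% names(re)) {
    u_scale <- u_scale + re$u_scale_slope * rows$age
  }
  omega <- compute_scale(X, truth$beta_scale, u_scale)
  out <- rows
  out$y <- eta_loc + with_seed(seed, rnorm(nrow(rows), 0, omega))
  out$.omega <- omega
  out
}

#' Generate a complete longitudinal dataset
#'
#' Composes the four generator stages — baseline covariates, encounter
#' counts, random effects, outcomes — under a single master seed that is
#' split deterministically into one sub-seed per stage via [derive_seed()].
#'
#' @param truth A [melsm_truth()].
#' @param seed Master integer seed.
#' @return A long tibble (`id`, `j`, `age`, `albumin`, `trig`, `platelet`,
#'   `y`, `.omega`) with the per-subject random effects attached as attribute
#'   `"random_effects"` and the truth as attribute `"truth"`.
#' @export
simulate_melsm <- function(truth = melsm_truth(), seed = 1L) {
  stopifnot(inherits(truth, "melsm_truth"))
  baseline <- draw_baseline_covariates(truth$n_subjects, truth$covariate_cov,
                                       derive_seed(seed, "baseline"))
  counts <- draw_encounter_counts(truth$n_subjects, truth$mean_encounters,
                                  derive_seed(seed, "counts"))
  rows <- expand_longitudinal(baseline, counts, truth$age_step)
  re <- draw_random_effects(truth, derive_seed(seed, "random_effects"))
  out <- generate_outcomes(rows, re, truth, derive_seed(seed, "outcomes"))
  attr(out, "random_effects") <- re
  attr(out, "truth") <- truth
  out
}

#' Write / read a simulated dataset as plain CSV
#'
#' The observable table is written to `path` with header
#' `id,j,age,albumin,trig,platelet,y`. The hidden generative truth — the
#' per-subject random effects and the per-row true residual SD — goes to a
#' sidecar `<path minus .csv>-truth.csv` (columns `id,j,omega` joined with
#' the random-effect columns), intended for evaluation only.
#'
#' @param data A dataset from [simulate_melsm()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_melsm_dataset <- function(data, path) {
  obs <- data[intersect(c("id", "j", "age", "albumin", "trig", "platelet", "y"),
                        names(data))]
  utils::write.csv(obs, path, row.names = FALSE)
  re <- attr(data, "random_effects")
  if (!is.null(re) || ".omega" %in% names(data)) {
    hidden <- tibble::tibble(id = data$id, j = data$j, omega = data$.omega)
    if (!is.null(re)) hidden <- dplyr::left_join(hidden, re, by = "id")
    utils::write.csv(hidden, sidecar_path(path), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_melsm_dataset
#' @export
read_melsm_dataset <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  sidecar <- sidecar_path(path)
  if (file.exists(sidecar)) {
    hidden <- tibble::as_tibble(utils::read.csv(sidecar))
    out$.omega <- hidden$omega[match(paste(out$id, out$j),
                                     paste(hidden$id, hidden$j))]
    re_cols <- setdiff(names(hidden), c("j", "omega"))
    attr(out, "random_effects") <- dplyr::distinct(hidden[re_cols])
  }
  out
}

sidecar_path <- function(path) sub("(\\.csv)?$", "-truth.csv", path)
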