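# Prior specification for the Bayesian backend.
#
# The concrete defaults mirror the conventional weakly-informative choices of
# mainstream Bayesian mixed-model software: improper flat priors on fixed
# effects, half-Student-t(3, 0, 2.5) on every random-effect SD, and LKJ(1)
# (uniform) on random-effect correlation matrices.

#' Specify priors for MELSM parameters
#'
#' @param sd_df,sd_scale Degrees of freedom and scale of the half-Student-t
#'   prior on each random-effect SD.
#' @param lkj_eta Shape of the LKJ prior on the random-intercept correlation
#'   (`1` is uniform).
#' @return A list of class `melsm_priors`.
#' @export
melsm_priors <- function(sd_df = 3, sd_scale = 2.5, lkj_eta = 1) {
  stopifnot(sd_df > 0, sd_scale > 0, lkj_eta > 0)
  structure(list(fixed = "flat", sd_df = sd_df, sd_scale = sd_scale,
                 lkj_eta = lkj_eta),
            class = "melsm_priors")
}

half_t_log_density <- function(x, df, scale) {
  ifelse(x < 0, -Inf, log(2) + dt(x / scale, df = df, log = TRUE) - log(scale))
}

# LKJ density of a 2x2 correlation matrix as a function of rho.
lkj2_log_density <- function(rho, eta) {
  (eta - 1) * log1p(-rho^2) - (2 * eta - 1) * log(2) - lbeta(eta, eta)
}

#' Log prior density of a MELSM parameter vector
#'
#' Flat blocks (the fixed effects) contribute 0; each random-effect SD
#' contributes a half-Student-t log-density and an estimated correlation an
#' LKJ log-density. Densities are evaluated on the natural scale (no
#' sampling-transform Jacobians; the posterior sampler adds those itself).
#'
#' @param params Named natural-scale parameter vector (see
#'   [parameter_names()]).
#' @param spec A [melsm_spec()] identifying which names are SDs/correlations.
#' @param priors A [melsm_priors()].
#' @return A single number (may be `-Inf` for inadmissible values).
#' @export
melsm_log_prior <- function(params, spec, priors = melsm_priors()) {
  stopifnot(inherits(priors, "melsm_priors"))
  params <- unlist(params)
  nms <- parameter_names(spec)
  missing <- setdiff(nms, names(params))
  if (length(missing)) {
    abort(paste0("missing parameter values: ", paste(missing, collapse = ", ")))
  }
  lp <- 0
  for (nm in nms[startsWith(nms, "sd_")]) {
    lp <- lp + half_t_log_density(params[[nm]], priors$sd_df, priors$sd_scale)
  }
  if ("cor_loc_scale" %in% nms) {
    lp <- lp + lkj2_log_density(params[["cor_loc_scale"]], priors$lkj_eta)
  }
  unname(lp)
}
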