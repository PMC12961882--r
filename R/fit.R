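# User-facing fitting interface and the melsm_fit result class.

new_melsm_fit <- function(summary, backend, spec, alpha, theta = NULL,
                          vcov = NULL, draws = NULL, loglik = NA_real_,
                          converged = NA, diagnostics = list(),
                          n_obs = NA_integer_, n_subjects = NA_integer_,
                          time = NA_real_) {
  structure(
    list(summary = summary, backend = backend, spec = spec, alpha = alpha,
         theta = theta, vcov = vcov, draws = draws, loglik = loglik,
         converged = converged, diagnostics = diagnostics,
         n_obs = n_obs, n_subjects = n_subjects, time = time),
    class = "melsm_fit"
  )
}

#' Fit a mixed-effects location-scale model
#'
#' Estimates a MELSM (or its LMM special case) from a long-format dataset.
#' Two backends implement the same model: `"mle"` maximises the adaptive
#' Gauss-Hermite marginal likelihood (fast; Wald intervals from the inverse
#' observed information), `"mcmc"` draws from the posterior under
#' [melsm_priors()] with an adaptive Metropolis sampler and summarises the
#' draws by posterior means, SDs, and equal-tailed quantile intervals.
#'
#' @param data Long-format data frame with `id`, the covariates named in
#'   `spec`, and outcome `y`.
#' @param spec A [melsm_spec()] (or anything [melsm_spec()] accepts via its
#'   formula strings).
#' @param backend `"mle"` or `"mcmc"`.
#' @param alpha Interval level for the reported bounds (default 0.95).
#' @param quad_points Gauss-Hermite points per random-effect dimension.
#' @param method Integration route passed to the likelihood engine
#'   (`"auto"`, `"collapsed"`, `"joint"`).
#' @param start Optional named natural-scale starting values.
#' @param fixed Optional named natural-scale values held fixed.
#' @param priors,chains,total,warmup,seed,mle MCMC settings (see
#'   [sample_posterior()]); ignored by the MLE backend.
#' @param control MLE optimiser control list passed to [stats::optim()].
#' @return A `melsm_fit` object. Use [tidy()] for the per-parameter summary
#'   (term, estimate, std.error, conf.low, conf.high), [glance()] for
#'   one-row model information, and [fit_summary()] for the serialisable
#'   summary table with stable column names.
#' @export
fit_melsm <- function(data, spec, backend = c("mle", "mcmc"), alpha = 0.95,
                      quad_points = 9, method = "auto", start = NULL,
                      fixed = NULL, priors = melsm_priors(), chains = 2,
                      total = 2000, warmup = 1000, seed = 1L, mle = NULL,
                      control = list()) {
  backend <- match.arg(backend)
  if (!inherits(spec, "melsm_spec")) abort("spec must be a melsm_spec")
  if (backend == "mle") {
    fit_melsm_mle(data, spec, alpha = alpha, quad_points = quad_points,
                  method = method, start = start, fixed = fixed,
                  control = control)
  } else {
    t0 <- proc.time()[["elapsed"]]
    draws <- sample_posterior(data, spec, priors = priors, chains = chains,
                              total = total, warmup = warmup, seed = seed,
                              quad_points = quad_points, method = method,
                              start = start, fixed = fixed, mle = mle)
    summary <- summarize_fit(draws, alpha = alpha)
    new_melsm_fit(
      summary = summary, backend = "mcmc", spec = spec, alpha = alpha,
      draws = draws, converged = summary$converged[1],
      diagnostics = list(accept_rate = draws$accept_rate,
                         max_rhat = suppressWarnings(max(summary$rhat,
                                                         na.rm = TRUE)),
                         quad_points = quad_points),
      n_obs = draws$n_obs, n_subjects = draws$n_subjects,
      time = proc.time()[["elapsed"]] - t0
    )
  }
}

#' Serialisable per-parameter summary of a fit
#'
#' @param fit A `melsm_fit`.
#' @return A tibble with stable columns `parameter`, `estimate`, `se`,
#'   `lower`, `upper`, `rhat`, `ess`, `converged`.
#' @export
fit_summary <- function(fit) {
  stopifnot(inherits(fit, "melsm_fit"))
  fit$summary
}

#' @method tidy melsm_fit
#' @export
tidy.melsm_fit <- function(x, ...) {
  dplyr::transmute(x$summary,
                   term = .data$parameter,
                   estimate = .data$estimate,
                   std.error = .data$se,
                   conf.low = .data$lower,
                   conf.high = .data$upper)
}

#' @method glance melsm_fit
#' @export
glance.melsm_fit <- function(x, ...) {
  tibble::tibble(
    backend = x$backend,
    logLik = x$loglik,
    nobs = x$n_obs,
    n_subjects = x$n_subjects,
    n_parameters = nrow(x$summary),
    converged = x$converged,
    alpha = x$alpha,
    elapsed = x$time
  )
}

#' @export
print.melsm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<melsm_fit> backend = %s, %d obs / %d subjects%s\n",
              x$backend, x$n_obs, x$n_subjects,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  cat(paste0("  ", format(x$spec)), sep = "\n")
  df <- as.data.frame(x$summary[c("parameter", "estimate", "se",
                                  "lower", "upper")])
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @method autoplot melsm_fit
#' @export
autoplot.melsm_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      x = "estimate",
      y = NULL,
      title = sprintf("MELSM parameter estimates (%d%% intervals, %s)",
                      round(object$alpha * 100), object$backend)
    )
}
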