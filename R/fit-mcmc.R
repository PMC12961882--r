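# Bayesian backend: adaptive random-walk Metropolis on the unconstrained
# marginalised parameter space (random effects are integrated out by AGQ, so
# the chain samples the ParameterVector only). During warmup the proposal is
# a scaled multivariate normal whose covariance starts from the inverse
# observed information at the MLE, with Robbins-Monro tuning of the global
# scale towards a 0.234 acceptance rate and one empirical-covariance update
# mid-warmup; adaptation is frozen after warmup.

#' Draw from the posterior of a MELSM
#'
#' The target density is the AGQ marginal log-likelihood plus the log prior
#' ([melsm_priors()]: flat on fixed effects, half-Student-t on SDs, LKJ on a
#' correlation) with the change-of-variable Jacobians for the log-SD and
#' atanh-correlation sampling scales. Defaults mirror a conventional
#' two-chain run: 2000 iterations per chain of which the first 1000 are
#' discarded as burn-in, leaving 2 x 1000 retained draws.
#'
#' @inheritParams melsm_marginal_loglik
#' @param priors A [melsm_priors()].
#' @param chains Number of chains.
#' @param total Total iterations per chain (including warmup).
#' @param warmup Burn-in iterations discarded per chain.
#' @param seed Integer seed; chains use deterministic sub-seeds.
#' @param start Optional named natural-scale start values; by default chains
#'   start from a short maximum-likelihood fit, jittered per chain.
#' @param fixed Optional named natural-scale values held fixed (not sampled).
#' @param mle Optional precomputed MLE `melsm_fit` for the same data and
#'   spec, reused for the chain start and proposal covariance.
#' @return A `melsm_draws` object: unconstrained draws (retained iterations
#'   stacked over chains), chain and iteration labels, parameter names, and
#'   acceptance diagnostics.
#' @export
sample_posterior <- function(data, spec, priors = melsm_priors(), chains = 2,
                             total = 2000, warmup = 1000, seed = 1L,
                             quad_points = 9, method = "auto", start = NULL,
                             fixed = NULL, mle = NULL) {
  stopifnot(chains >= 1, total > warmup, warmup >= 0)
  eng <- new_engine(data, spec)
  if (eng$N < 2 && (eng$d_y + eng$d_w) > 0) {
    abort("random-effect models need at least 2 subjects")
  }
  if (is.null(mle)) {
    mle <- tryCatch(
      fit_melsm_mle(data, spec, quad_points = quad_points, method = method,
                    start = start, fixed = fixed),
      error = function(e) NULL
    )
  } else {
    stopifnot(inherits(mle, "melsm_fit"), identical(mle$backend, "mle"))
  }
  p <- length(eng$par_names)
  if (!is.null(mle)) {
    theta_init <- mle$theta
    vc <- mle$vcov
    ok <- all(is.finite(diag(vc)))
  } else {
    theta_init <- if (is.null(start)) start_theta(eng) else pack_params(start, eng)
    ok <- FALSE
  }
  free <- seq_len(p)
  if (!is.null(fixed)) {
    free <- setdiff(free, match(names(fixed), eng$par_names))
  }
  pf <- length(free)
  prop_cov <- if (!is.null(mle) && ok) {
    mle$vcov[free, free, drop = FALSE] + diag(1e-8, pf)
  } else {
    diag(0.01, pf)
  }
  log_post <- function(theta) {
    ll <- as.numeric(engine_loglik(theta, eng, quad_points, method))
    nat <- natural_params(theta, eng)
    lp <- melsm_log_prior(nat, spec, priors)
    # Jacobians of the sampling transforms
    lp <- lp + sum(theta[eng$idx$sd])
    if (length(eng$idx$rho)) {
      lp <- lp + log1p(-tanh(theta[eng$idx$rho])^2)
    }
    ll + lp
  }
  n_keep <- total - warmup
  draws <- matrix(NA_real_, chains * n_keep, p,
                  dimnames = list(NULL, eng$par_names))
  chain_id <- rep(seq_len(chains), each = n_keep)
  iteration <- rep(seq_len(n_keep), chains)
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    with_seed(derive_seed(seed, "mcmc-chain", ch), {
      theta <- theta_init
      theta[free] <- theta[free] + rnorm(pf, 0, 0.02 * (ch - 1))
      lp <- log_post(theta)
      if (!is.finite(lp)) {
        theta <- theta_init
        lp <- log_post(theta)
      }
      R <- chol(prop_cov)
      log_scale <- log(2.38 / sqrt(max(pf, 1)))
      n_acc <- 0
      warm_hist <- matrix(NA_real_, warmup, pf)
      for (it in seq_len(total)) {
        prop <- theta
        prop[free] <- theta[free] +
          exp(log_scale) * drop(rnorm(pf) %*% R)
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
          theta <- prop
          lp <- lp_prop
          acc <- 1
        } else {
          acc <- 0
        }
        if (it <= warmup) {
          warm_hist[it, ] <- theta[free]
          log_scale <- log_scale + (acc - 0.234) / sqrt(it)
          if (it == max(200, floor(warmup / 2)) && it >= 50) {
            emp <- stats::cov(warm_hist[seq_len(it), , drop = FALSE])
            if (all(is.finite(emp))) {
              R <- tryCatch(chol(emp + diag(1e-8, pf)), error = function(e) R)
            }
          }
        } else {
          if (acc == 1) n_acc <- n_acc + 1
          draws[(ch - 1) * n_keep + (it - warmup), ] <- theta
        }
      }
      accept[ch] <- n_acc / n_keep
    })
  }
  structure(
    list(draws = draws, chain = chain_id, iteration = iteration,
         par_names = eng$par_names, free = free,
         chains = chains, total = total, warmup = warmup,
         accept_rate = accept, eng_idx = eng$idx,
         n_obs = eng$n, n_subjects = eng$N),
    class = "melsm_draws"
  )
}

#' @export
print.melsm_draws <- function(x, ...) {
  cat(sprintf("<melsm_draws> %d chains x %d retained draws, %d parameters\n",
              x$chains, x$total - x$warmup, length(x$par_names)))
  cat(sprintf("  acceptance rate: %s\n",
              paste(sprintf("%.2f", x$accept_rate), collapse = ", ")))
  invisible(x)
}

# Split-Rhat (chains split in half) for one parameter.
split_rhat <- function(x, chain) {
  halves <- split(x, paste(chain, ave(seq_along(x), chain, FUN = function(i) {
    rep(1:2, each = ceiling(length(i) / 2), length.out = length(i))
  })))
  n <- min(lengths(halves))
  if (n < 2) return(NA_real_)
  halves <- lapply(halves, function(h) h[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size via Geyer's initial positive sequence on the
# chain-averaged autocorrelations.
ess_basic <- function(x, chain) {
  chains <- split(x, chain)
  n <- min(lengths(chains))
  if (n < 4) return(NA_real_)
  chains <- lapply(chains, function(c1) c1[seq_len(n)])
  m <- length(chains)
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  if (W <= 0) return(m * n)
  max_lag <- min(n - 1, 400)
  acov <- sapply(chains, function(c1) {
    a <- stats::acf(c1, lag.max = max_lag, plot = FALSE, type = "covariance",
                    demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)
  means <- vapply(chains, mean, numeric(1))
  var_plus <- (n - 1) / n * W + if (m > 1) var(means) else 0
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  # sum consecutive pairs while positive
  tau <- 1
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(m * n / tau, 1)
}

#' Summarise posterior draws into a fit summary
#'
#' Draws are mapped to the natural scale draw-wise (SDs by `exp`, a
#' correlation by `tanh`) before summarising: the point estimate is the
#' posterior mean, the standard error the posterior SD, and the interval the
#' equal-tailed sample quantiles at levels `(1 -/+ alpha) / 2`. Split-Rhat
#' and effective sample size are attached per parameter.
#'
#' @param draws A `melsm_draws` object from [sample_posterior()].
#' @param alpha Interval level (default 0.95).
#' @return A tibble with columns `parameter`, `estimate`, `se`, `lower`,
#'   `upper`, `rhat`, `ess`, `converged` (split-Rhat below 1.05 for all
#'   sampled parameters).
#' @export
summarize_fit <- function(draws, alpha = 0.95) {
  stopifnot(inherits(draws, "melsm_draws"), nrow(draws$draws) > 0)
  nat <- draws$draws
  nat[, draws$eng_idx$sd] <- exp(nat[, draws$eng_idx$sd, drop = FALSE])
  if (length(draws$eng_idx$rho)) {
    nat[, draws$eng_idx$rho] <- tanh(nat[, draws$eng_idx$rho])
  }
  probs <- c((1 - alpha) / 2, (1 + alpha) / 2)
  rhat <- ess <- rep(NA_real_, ncol(nat))
  for (j in seq_len(ncol(nat))) {
    if (j %in% draws$free && draws$chains >= 1) {
      rhat[j] <- split_rhat(nat[, j], draws$chain)
      ess[j] <- ess_basic(nat[, j], draws$chain)
    }
  }
  conv <- all(is.na(rhat) | rhat < 1.05)
  tibble::tibble(
    parameter = draws$par_names,
    estimate = unname(colMeans(nat)),
    se = unname(apply(nat, 2, sd)),
    lower = unname(apply(nat, 2, quantile, probs[1], names = FALSE)),
    upper = unname(apply(nat, 2, quantile, probs[2], names = FALSE)),
    rhat = rhat,
    ess = ess,
    converged = conv
  )
}
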