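# Maximum-likelihood backend: BFGS on the unconstrained parameters of the
# AGQ marginal log-likelihood, standard errors from the inverse observed
# information (finite differences of the Fisher-identity score), Wald
# intervals formed on the unconstrained scale and mapped back (so SD
# intervals stay positive and correlation intervals stay in (-1, 1)).

start_theta <- function(eng) {
  # The generative process can produce residual SDs spanning many orders of
  # magnitude across encounters, so an unweighted OLS start is useless.
  # Alternate a weighted location fit with a log-|residual| scale regression
  # (IRLS): E log|N(0, s)| = log s - 0.6351814.
  X <- eng$des$X_loc
  Xw <- eng$des$X_scale
  y <- eng$des$y
  wls <- function(X, y, w) {
    b <- tryCatch(qr.coef(qr(X * sqrt(w)), y * sqrt(w)),
                  error = function(e) rep(0, ncol(X)))
    b[is.na(b)] <- 0
    b
  }
  b_w <- rep(0, eng$p_w)
  b_y <- rep(0, eng$p_y)
  for (it in 1:4) {
    w <- exp(pmin(pmax(-2 * drop(Xw %*% b_w), -60), 60))
    b_y <- wls(X, y, w)
    e <- y - drop(X %*% b_y)
    # floor |residual| relative to its typical size so rows where the fit
    # happens to interpolate cannot drag the log-scale regression down
    floor_e <- 1e-3 * stats::median(abs(e)) + 1e-12
    le <- log(pmax(abs(e), floor_e)) + 0.6351814
    b_w <- wls(Xw, le, rep(1, length(y)))
  }
  e <- y - drop(X %*% b_y)
  # the log-|residual| regression targets the mean log SD; shift the
  # intercept so the fitted scale matches the residual root-mean-square
  # instead (much closer to the ML optimum when scale misspecification
  # leaves residual SDs spanning orders of magnitude)
  if (eng$p_w > 0) {
    lres2 <- 2 * (log(pmax(abs(e), 1e-8)) - drop(Xw %*% b_w))
    shift <- 0.5 * (max(lres2) + log(mean(exp(lres2 - max(lres2)))))
    int_col <- which(colnames(eng$des$X_scale) == "(Intercept)")
    if (length(int_col) == 1) b_w[int_col] <- b_w[int_col] + shift
  }
  w <- exp(pmin(pmax(-2 * drop(Xw %*% b_w), -60), 60))
  sds <- numeric(0)
  if (eng$d_y > 0) {
    # SD of precision-weighted subject means of the residuals
    mbar <- rowsum(e * w, eng$sub)[, 1] / pmax(rowsum(w, eng$sub)[, 1], 1e-12)
    s0 <- min(max(sd(mbar), 0.2), 10)
    sds <- c(sds, s0, if (eng$d_y > 1) max(s0 / 2, 0.2))
  }
  if (eng$d_w > 0) {
    lres <- le - drop(Xw %*% b_w)
    s0 <- min(max(sd(rowsum(lres, eng$sub)[, 1] / eng$J), 0.2), 5)
    sds <- c(sds, s0, if (eng$d_w > 1) max(s0 / 2, 0.15))
  }
  c(b_y, b_w, if (length(sds)) log(sds), if (length(eng$idx$rho)) 0)
}

# Observed information of the negative log-likelihood by forward differences
# of the score (p + 1 score evaluations; the O(h) bias at h = 1e-4 is far
# below the statistical uncertainty the matrix quantifies).
observed_information <- function(theta, eng, quad_points, method, h = 1e-4) {
  p <- length(theta)
  Hn <- matrix(NA_real_, p, p)
  g0 <- attr(engine_loglik(theta, eng, quad_points, method,
                           want_grad = TRUE), "gradient")
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h
    gp <- attr(engine_loglik(theta + e, eng, quad_points, method,
                             want_grad = TRUE), "gradient")
    Hn[, j] <- -(gp - g0) / h
  }
  (Hn + t(Hn)) / 2
}

# Numeric Hessian of a scalar function by central second differences (used
# where the analytic score path is not available).
fd_hessian <- function(fun, x, h = 1e-3) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fun(x)
  fp <- fm <- numeric(p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h
    fp[j] <- fun(x + e)
    fm[j] <- fun(x - e)
    H[j, j] <- (fp[j] - 2 * f0 + fm[j]) / h^2
  }
  if (p > 1) {
    for (a in 1:(p - 1)) for (b in (a + 1):p) {
      ea <- numeric(p); ea[a] <- h
      eb <- numeric(p); eb[b] <- h
      H[a, b] <- H[b, a] <-
        (fun(x + ea + eb) - fun(x + ea - eb) -
           fun(x - ea + eb) + fun(x - ea - eb)) / (4 * h^2)
    }
  }
  H
}

fit_melsm_mle <- function(data, spec, alpha = 0.95, quad_points = 9,
                          method = "auto", start = NULL, fixed = NULL,
                          control = list()) {
  eng <- new_engine(data, spec)
  if (eng$N < 2 && (eng$d_y + eng$d_w) > 0) {
    abort("random-effect models need at least 2 subjects")
  }
  if (is.null(start) && any(eng$dist == "student_t")) {
    # warm-start Student fits from the Gaussian-effects solution (its fitted
    # SDs divided by sqrt(df / (df - 2)) approximate the t scales); the
    # Student likelihood has a spurious large-scale mode that cold starts
    # can fall into
    gspec <- spec
    for (side in c("location", "scale")) {
      if (!is.null(gspec[[side]]$random)) {
        gspec[[side]]$random$distribution <- "gaussian"
        gspec[[side]]$random$df <- NULL
      }
    }
    gfit <- tryCatch(
      fit_melsm_mle(data, gspec, alpha = alpha, quad_points = quad_points,
                    method = method, control = control),
    error = function(e) NULL)
    if (!is.null(gfit)) {
      start <- setNames(gfit$summary$estimate, gfit$summary$parameter)
      is_sd <- startsWith(names(start), "sd_")
      df0 <- eng$df[is.finite(eng$df)][1]
      start[is_sd] <- start[is_sd] / sqrt(df0 / (df0 - 2))
    }
  }
  theta0 <- if (is.null(start)) start_theta(eng) else pack_params(start, eng)
  p <- length(theta0)
  free <- seq_len(p)
  theta_fix <- theta0
  if (!is.null(fixed)) {
    fix_idx <- match(names(fixed), eng$par_names)
    if (anyNA(fix_idx)) abort("unknown parameter in 'fixed'")
    tv <- unlist(fixed)
    is_sd <- fix_idx %in% eng$idx$sd
    tv[is_sd] <- log(tv[is_sd])
    is_rho <- fix_idx %in% eng$idx$rho
    tv[is_rho] <- atanh(tv[is_rho])
    theta_fix[fix_idx] <- tv
    free <- setdiff(free, fix_idx)
  }
  expand <- function(th_free) {
    th <- theta_fix
    th[free] <- th_free
    th
  }
  # a Gaussian log-density is bounded by the clipped log-SD, so the total
  # log-likelihood cannot genuinely exceed ~30 per observation; anything
  # larger is floating-point cancellation in a pathological region
  ll_cap <- 31 * eng$n + 1e4
  negll <- function(th_free) {
    if (any(!is.finite(th_free))) return(1e10)
    v <- -as.numeric(engine_loglik(expand(th_free), eng, quad_points, method))
    if (!is.finite(v) || v < -ll_cap) v <- 1e10
    v
  }
  neggr <- function(th_free) {
    if (any(!is.finite(th_free))) return(numeric(length(th_free)))
    g <- attr(engine_loglik(expand(th_free), eng, quad_points, method,
                            want_grad = TRUE), "gradient")
    g[!is.finite(g)] <- 0
    -g[free]
  }
  # the Fisher-identity score is exact for Gaussian random effects, but under
  # Student effects single-encounter subjects expose it to catastrophic
  # floating-point cancellation at extreme quadrature nodes; those fits use
  # finite-difference derivatives of the (stable) likelihood value instead,
  # with a shorter refinement budget since they start from the Gaussian
  # solution
  use_score <- !any(eng$dist == "student_t")
  ctl <- modifyList(
    if (use_score) list(maxit = 400, reltol = 1e-9) else
      list(maxit = 120, reltol = 1e-8),
    control)
  t0 <- proc.time()[["elapsed"]]
  with_frozen_grid <- function(code) {
    eng$cache$freeze <- TRUE
    eng$cache$frozen_nm <- NULL
    eng$cache$frozen_sf <- NULL
    on.exit({
      eng$cache$freeze <- FALSE
      eng$cache$frozen_nm <- NULL
      eng$cache$frozen_sf <- NULL
    })
    force(code)
  }
  curvature <- function(opt) {
    info <- if (use_score) {
      observed_information(expand(opt$par), eng, quad_points,
                           method)[free, free, drop = FALSE]
    } else {
      with_frozen_grid({
        negll(opt$par) # compute and freeze the grid at the optimum
        fd_hessian(negll, opt$par)
      })
    }
    vc <- tryCatch(solve(info), error = function(e) NULL)
    ok <- !is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)
    list(vcov = vc, ok = ok)
  }
  neggr_fd <- function(th_free) {
    with_frozen_grid({
      negll(th_free)
      h <- 1e-4
      vapply(seq_along(th_free), function(j) {
        e <- numeric(length(th_free)); e[j] <- h
        (negll(th_free + e) - negll(th_free - e)) / (2 * h)
      }, numeric(1))
    })
  }
  gr_fun <- if (use_score) neggr else neggr_fd
  opt <- optim(theta0[free], negll, gr_fun, method = "BFGS", control = ctl)
  curv <- curvature(opt)
  # rescue with a gradient-free simplex pass (then BFGS polish) when BFGS
  # stalled, ran away, or stopped at a point without positive-definite
  # curvature. A boundary optimum (an SD driven to ~0) legitimately has a
  # singular information matrix; rescuing cannot fix that, so such fits are
  # just flagged.
  sd_free <- intersect(eng$idx$sd, free)
  at_boundary <- length(sd_free) &&
    any(expand(opt$par)[sd_free] < log(1e-4))
  if (opt$convergence != 0 || !is.finite(opt$value) ||
      max(abs(opt$par)) > 1e3 || (!curv$ok && !at_boundary)) {
    nm <- optim(theta0[free], negll, method = "Nelder-Mead",
                control = list(maxit = 500))
    opt2 <- optim(nm$par, negll, gr_fun, method = "BFGS", control = ctl)
    if (is.finite(opt2$value) && opt2$value <= opt$value) {
      opt <- opt2
      curv <- curvature(opt)
    }
  }
  theta_hat <- expand(opt$par)
  vcov_free <- curv$vcov
  hess_ok <- curv$ok
  vcov <- matrix(NA_real_, p, p, dimnames = list(eng$par_names, eng$par_names))
  if (hess_ok) vcov[free, free] <- vcov_free
  se_theta <- sqrt(pmax(diag(vcov), 0))
  converged <- opt$convergence == 0 && hess_ok
  z <- qnorm((1 + alpha) / 2)
  est_nat <- natural_params(theta_hat, eng)
  lower_t <- theta_hat - z * se_theta
  upper_t <- theta_hat + z * se_theta
  nat_of <- function(th) natural_params(th, eng)
  lower <- nat_of(lower_t)
  upper <- nat_of(upper_t)
  se_nat <- se_theta
  se_nat[eng$idx$sd] <- est_nat[eng$idx$sd] * se_theta[eng$idx$sd]
  if (length(eng$idx$rho)) {
    se_nat[eng$idx$rho] <- (1 - est_nat[eng$idx$rho]^2) * se_theta[eng$idx$rho]
  }
  summary <- tibble::tibble(
    parameter = eng$par_names,
    estimate = unname(est_nat),
    se = unname(se_nat),
    lower = unname(lower),
    upper = unname(upper),
    rhat = NA_real_,
    ess = NA_real_,
    converged = converged
  )
  new_melsm_fit(
    summary = summary, backend = "mle", spec = spec, alpha = alpha,
    theta = setNames(theta_hat, eng$par_names), vcov = vcov,
    loglik = -opt$value, converged = converged,
    diagnostics = list(optim_convergence = opt$convergence,
                       optim_message = opt$message,
                       hessian_pd = hess_ok,
                       counts = opt$counts,
                       fixed = fixed,
                       quad_points = quad_points,
                       method = if (identical(method, "auto")) {
                         if (eng$collapsed_ok) "collapsed" else "joint"
                       } else method),
    n_obs = eng$n, n_subjects = eng$N,
    time = proc.time()[["elapsed"]] - t0
  )
}
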