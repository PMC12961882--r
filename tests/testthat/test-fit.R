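# Fitting backends: MLE oracles, interval construction, posterior sampling.

test_that("a noiseless fixed-effects model is interpolated exactly", {
  base <- draw_baseline_covariates(30, seed = 2)
  rows <- expand_longitudinal(base, rep(4L, 30))
  # scale pinned far below the signal, no random effects
  y <- 0.3 + 0.5 * rows$age - 0.2 * rows$albumin
  d <- dplyr::mutate(rows, y = y + rnorm(nrow(rows), 0, 1e-6))
  spec <- melsm_spec("y ~ age + albumin", "log(omega) ~ 1")
  f <- fit_quick(d, spec)
  est <- setNames(f$summary$estimate, f$summary$parameter)
  expect_equal(unname(est[c("loc_(Intercept)", "loc_age", "loc_albumin")]),
               c(0.3, 0.5, -0.2), tolerance = 1e-4)
  expect_lt(est["scale_(Intercept)"], -10)
})

test_that("the LMM special case matches lme4", {
  skip_if_not_installed("lme4")
  tr <- homoscedastic_truth(n_subjects = 60, mean_encounters = 6)
  d <- simulate_melsm(tr, seed = 14)
  f <- fit_quick(d, spec_lmm())
  ref <- lme4::lmer(y ~ age + albumin + (1 | id), data = d, REML = FALSE)
  est <- setNames(f$summary$estimate, f$summary$parameter)
  expect_equal(unname(est[c("loc_(Intercept)", "loc_age", "loc_albumin")]),
               unname(lme4::fixef(ref)), tolerance = 1e-3)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(unname(est["sd_loc_(Intercept)"]),
               vc$sdcor[vc$grp == "id"], tolerance = 1e-3)
  expect_equal(unname(exp(est["scale_(Intercept)"])),
               vc$sdcor[vc$grp == "Residual"], tolerance = 1e-3)
  expect_equal(f$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-5)
})

test_that("the fixed-effects-only scale model matches glmmTMB", {
  skip_if_not_installed("glmmTMB")
  tr <- melsm_truth(sigma_omega = 0, n_subjects = 60, mean_encounters = 6)
  d <- simulate_melsm(tr, seed = 25)
  spec <- melsm_spec("y ~ age + albumin + (1|id)", "log(omega) ~ age + trig")
  f <- fit_quick(d, spec)
  ref <- suppressWarnings(glmmTMB::glmmTMB(
    y ~ age + albumin + (1 | id), dispformula = ~ age + trig, data = d,
    REML = FALSE))
  est <- setNames(f$summary$estimate, f$summary$parameter)
  expect_equal(unname(est[c("loc_(Intercept)", "loc_age", "loc_albumin")]),
               unname(glmmTMB::fixef(ref)$cond), tolerance = 2e-3)
  # glmmTMB parameterises the dispersion model on log(sd) with the same link
  expect_equal(unname(est[c("scale_(Intercept)", "scale_age", "scale_trig")]),
               unname(glmmTMB::fixef(ref)$disp), tolerance = 2e-3)
})

test_that("SD-scale parameters carry delta-method errors and positive bounds", {
  tr <- quick_truth()
  d <- simulate_melsm(tr, seed = 5)
  f <- fit_quick(d, spec_correct())
  s <- fit_summary(f)
  expect_true(all(s$lower <= s$upper))
  sd_rows <- startsWith(s$parameter, "sd_")
  expect_true(all(s$lower[sd_rows] > 0))
  # delta method: se(sd) = sd * se(log sd); recover se(log sd) from the
  # unconstrained covariance and compare
  se_log <- sqrt(diag(f$vcov))[s$parameter[sd_rows]]
  expect_equal(s$se[sd_rows], s$estimate[sd_rows] * unname(se_log),
               tolerance = 1e-10)
  # Wald interval mapped through exp stays consistent
  z <- qnorm(0.975)
  expect_equal(s$lower[sd_rows],
               s$estimate[sd_rows] * exp(-z * se_log), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("fit_melsm validates inputs and flags failures", {
  tr <- quick_truth()
  d <- simulate_melsm(tr, seed = 5)
  expect_error(fit_melsm(d, "not a spec"), "melsm_spec")
  expect_error(fit_melsm(d[d$id == 1, ], spec_correct()), "2 subjects")
})

test_that("posterior sampling reproduces a conjugate normal posterior", {
  omega0 <- 1.3
  n <- 40
  set.seed(8)
  y <- rnorm(n, 2, omega0)
  d <- tibble::tibble(id = rep(1:2, each = n / 2), age = 0, albumin = 0,
                      trig = 0, platelet = 0, y = y)
  spec <- melsm_spec("y ~ 1", "log(omega) ~ 1")
  draws <- sample_posterior(d, spec, chains = 2, total = 4000, warmup = 1000,
                            seed = 31,
                            fixed = c("scale_(Intercept)" = log(omega0)))
  s <- summarize_fit(draws)
  mu_row <- s[s$parameter == "loc_(Intercept)", ]
  # flat prior: posterior is N(ybar, omega0^2 / n)
  mcse <- mu_row$se / sqrt(max(mu_row$ess, 10))
  expect_equal(mu_row$estimate, mean(y), tolerance = max(5 * mcse, 5e-3))
  expect_equal(mu_row$se, omega0 / sqrt(n), tolerance = 0.25 * omega0 / sqrt(n))
  # fixed parameter does not move
  sc <- s[s$parameter == "scale_(Intercept)", ]
  expect_equal(sc$estimate, log(omega0), tolerance = 1e-12)
  expect_equal(sc$se, 0, tolerance = 1e-12)
})

test_that("posterior defaults retain 2 x 1000 draws and are reproducible", {
  tr <- melsm_truth(n_subjects = 25, mean_encounters = 4)
  d <- simulate_melsm(tr, seed = 3)
  spec <- spec_lmm()
  draws <- sample_posterior(d, spec, seed = 7)
  expect_equal(nrow(draws$draws), 2000)
  expect_equal(unname(table(draws$chain)), c(1000L, 1000L),
               ignore_attr = TRUE)
  draws2 <- sample_posterior(d, spec, seed = 7)
  expect_identical(draws$draws, draws2$draws)
  draws3 <- sample_posterior(d, spec, seed = 8)
  expect_false(identical(draws$draws, draws3$draws))
})

test_that("summarize_fit uses natural-scale means and sorting quantiles", {
  # hand-built draws object: constant draws collapse to a point
  const <- structure(list(
    draws = matrix(log(2), 50, 1, dimnames = list(NULL, "sd_loc_(Intercept)")),
    chain = rep(1:2, each = 25), iteration = rep(1:25, 2),
    par_names = "sd_loc_(Intercept)", free = 1L, chains = 2,
    total = 35, warmup = 10, accept_rate = c(0.2, 0.2),
    eng_idx = list(sd = 1L, rho = integer()), n_obs = 1, n_subjects = 1
  ), class = "melsm_draws")
  s <- summarize_fit(const)
  expect_equal(s$estimate, 2)
  expect_equal(s$lower, 2)
  expect_equal(s$upper, 2)
  expect_equal(s$se, 0)

  set.seed(10)
  x <- rnorm(400)
  rd <- const
  rd$draws <- matrix(x, 400, 1, dimnames = list(NULL, "loc_age"))
  rd$chain <- rep(1:2, each = 200)
  rd$iteration <- rep(1:200, 2)
  rd$par_names <- "loc_age"
  rd$eng_idx <- list(sd = integer(), rho = integer())
  s2 <- summarize_fit(rd, alpha = 0.95)
  xs <- sort(x)
  expect_equal(s2$estimate, mean(x))
  expect_equal(s2$lower, unname(quantile(xs, 0.025)))
  expect_equal(s2$upper, unname(quantile(xs, 0.975)))
  # natural-scale back-transform happens draw-wise
  rd_sd <- rd
  rd_sd$par_names <- "sd_loc_(Intercept)"
  colnames(rd_sd$draws) <- "sd_loc_(Intercept)"
  rd_sd$eng_idx <- list(sd = 1L, rho = integer())
  s3 <- summarize_fit(rd_sd)
  expect_equal(s3$estimate, mean(exp(x)))
})

test_that("tidy and glance expose broom-style summaries", {
  tr <- quick_truth()
  d <- simulate_melsm(tr, seed = 5)
  f <- fit_quick(d, spec_lmm())
  td <- tidy(f)
  expect_equal(names(td),
               c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_equal(nrow(td), 5)
  g <- glance(f)
  expect_equal(g$nobs, nrow(d))
  expect_equal(g$n_subjects, 40)
  expect_true(is.finite(g$logLik))
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})
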