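# Synthetic-data generator: distributional checks, determinism, conservation.

test_that("baseline covariates reproduce the population covariance", {
  base <- draw_baseline_covariates(200000, seed = 101)
  S <- stats::cov(as.matrix(base[c("age", "albumin", "trig", "platelet")]))
  target <- pbc_covariate_cov()
  # MC standard error of a covariance entry is about
  # sqrt((s_ii s_jj + s_ij^2) / n)
  mcse <- sqrt((outer(diag(target), diag(target)) + target^2) / 200000)
  expect_true(all(abs(S - target) < 3 * mcse))

  indep <- draw_baseline_covariates(100000, cov = diag(4), seed = 5)
  S0 <- stats::cov(as.matrix(indep[-1]))
  expect_true(all(abs(S0[upper.tri(S0)]) < 0.02))
})

test_that("baseline draws are reproducible and N-stable for early subjects", {
  a <- draw_baseline_covariates(50, seed = 7)
  b <- draw_baseline_covariates(50, seed = 7)
  expect_identical(a, b)
  big <- draw_baseline_covariates(500, seed = 7)
  expect_equal(as.data.frame(big[1:50, ]), as.data.frame(a))
})

test_that("non positive definite covariances are rejected", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(draw_baseline_covariates(10, cov = bad), "eigenvalue")
  asym <- pbc_covariate_cov(); asym[1, 2] <- 0
  expect_error(draw_baseline_covariates(10, cov = asym), "symmetric")
})

test_that("encounter counts follow the discrete uniform on {1, ..., 2M-1}", {
  j <- draw_encounter_counts(50000, m = 15, seed = 3)
  expect_true(all(j >= 1 & j <= 29))
  expect_lt(abs(mean(j) - 15), 3 * sd(j) / sqrt(50000))

  expect_true(all(draw_encounter_counts(100, m = 1, seed = 1) == 1))
  expect_error(draw_encounter_counts(10, m = 0.5), "at least 1")

  # chi-square goodness of fit against uniform{1..9} at M = 5
  j5 <- draw_encounter_counts(50000, m = 5, seed = 9)
  gof <- stats::chisq.test(table(factor(j5, levels = 1:9)))
  expect_gt(gof$p.value, 1e-4)
})

test_that("longitudinal expansion advances age and copies covariates", {
  base <- draw_baseline_covariates(3, seed = 2)
  counts <- c(3L, 1L, 2L)
  rows <- expand_longitudinal(base, counts, age_step = 1)
  expect_equal(nrow(rows), sum(counts))
  expect_equal(rows$age[rows$id == 1], base$age[1] + 0:2)
  expect_equal(rows$j[rows$id == 1], 0:2)
  expect_equal(rows$albumin[rows$id == 1], rep(base$albumin[1], 3))
  expect_equal(as.data.frame(rows[rows$id == 2, names(base)]),
               as.data.frame(base[2, ]))

  # default annual increments on the standardised scale
  rows01 <- expand_longitudinal(base, counts)
  expect_equal(rows01$age[rows01$id == 1], base$age[1] + 0.1 * 0:2)
})

test_that("random effects match their stated distributions", {
  tr <- melsm_truth(n_subjects = 50000)
  re <- draw_random_effects(tr, seed = 31)
  expect_equal(nrow(re), 50000)
  expect_lt(abs(sd(re$u_loc_intercept) - 1), 0.02)
  expect_lt(abs(sd(re$u_scale_intercept) - 0.5), 0.01)
  expect_lt(abs(cor(re$u_loc_intercept, re$u_scale_intercept)), 0.02)

  tr_rho <- melsm_truth(rho = 0.6, n_subjects = 50000)
  re_rho <- draw_random_effects(tr_rho, seed = 31)
  expect_lt(abs(cor(re_rho$u_loc_intercept, re_rho$u_scale_intercept) - 0.6),
            0.02)

  tr0 <- melsm_truth(sigma_y = 0, sigma_omega = 0, n_subjects = 100)
  re0 <- draw_random_effects(tr0, seed = 1)
  expect_true(all(re0$u_loc_intercept == 0))
  expect_true(all(re0$u_scale_intercept == 0))

  tr_sl <- melsm_truth(slope_sd_loc = 1, slope_sd_scale = 0.5,
                       n_subjects = 50000)
  re_sl <- draw_random_effects(tr_sl, seed = 4)
  expect_lt(abs(sd(re_sl$u_loc_slope) - 1), 0.02)
  expect_lt(abs(sd(re_sl$u_scale_slope) - 0.5), 0.01)
})

test_that("Student intercepts use sigma as the t scale parameter", {
  tr <- melsm_truth(re_distribution = "student_t", re_df = 3,
                    n_subjects = 200000)
  re <- draw_random_effects(tr, seed = 12)
  # SD of a t3 with scale s is s * sqrt(3); the sample SD of a t3 converges
  # slowly (infinite fourth moment), hence the generous band
  expect_lt(abs(sd(re$u_loc_intercept) - sqrt(3)), 0.35)
  # interquartile range is a robust check of the scale parameter itself:
  # IQR(t3 scale s) = 2 s qt(0.75, 3)
  expect_lt(abs(stats::IQR(re$u_loc_intercept) - 2 * qt(0.75, 3)), 0.03)
  expect_lt(abs(stats::IQR(re$u_scale_intercept) - 0.5 * 2 * qt(0.75, 3)), 0.02)
})

test_that("compute_scale exponentiates the linear predictor", {
  expect_equal(compute_scale(c(0, 0), c(0, 0)), 1)
  expect_equal(compute_scale(c(1, 0), c(0.8, 0)), exp(0.8), tolerance = 1e-12)
  expect_equal(exp(0.8), 2.2255, tolerance = 1e-4)
  base <- compute_scale(c(1, 2), c(0.3, 0.1))
  expect_equal(compute_scale(c(1, 2), c(0.3, 0.1), u = log(2)), 2 * base)
  expect_warning(compute_scale(matrix(40), 1), "clipped")
})

test_that("outcome noise matches the scale model within strata", {
  tr <- melsm_truth(n_subjects = 3000)
  d <- simulate_melsm(tr, seed = 77)
  re <- attr(d, "random_effects")
  eta <- 0.5 * d$age + 0.5 * d$albumin +
    re$u_loc_intercept[match(d$id, re$id)]
  resid <- d$y - eta
  # residual variance within narrow bands of true omega tracks omega^2
  bands <- cut(log(d$.omega), breaks = stats::quantile(log(d$.omega),
                                                       seq(0, 1, 0.25)),
               include.lowest = TRUE)
  for (b in levels(bands)) {
    idx <- bands == b
    expect_lt(abs(var(resid[idx]) / mean(d$.omega[idx]^2) - 1), 0.2)
  }
})

test_that("location coefficients are recoverable from generated data", {
  tr <- melsm_truth(n_subjects = 5000)
  d <- simulate_melsm(tr, seed = 13)
  # weighted least squares with the true residual SDs; subject random
  # intercepts remain in the error, so compare against 3 empirical SEs
  w <- 1 / (d$.omega^2 + 1)
  fit <- stats::lm(y ~ age + albumin + trig + platelet, data = d, weights = w)
  est <- coef(fit)[c("age", "albumin")]
  se <- sqrt(diag(stats::vcov(fit)))[c("age", "albumin")]
  expect_true(all(abs(est - c(0.5, 0.5)) < 3 * pmax(se, 0.02)))
})

test_that("the composed generator is deterministic and complete", {
  tr <- melsm_truth(slope_sd_loc = 1, slope_sd_scale = 0.5,
                    re_distribution = "student_t",
                    age_transform = "sin", n_subjects = 30)
  d1 <- simulate_melsm(tr, seed = 5)
  d2 <- simulate_melsm(tr, seed = 5)
  expect_identical(d1, d2)
  expect_true(all(c("id", "j", "age", "albumin", "trig", "platelet", "y",
                    ".omega") %in% names(d1)))
  re <- attr(d1, "random_effects")
  expect_true(all(c("u_loc_intercept", "u_scale_intercept", "u_loc_slope",
                    "u_scale_slope") %in% names(re)))
  expect_equal(nrow(re), 30)

  d3 <- simulate_melsm(melsm_truth(n_subjects = 200, mean_encounters = 15),
                       seed = 5)
  expect_equal(dplyr::n_distinct(d3$id), 200)
  expect_true(nrow(d3) > 200 * 10 && nrow(d3) < 200 * 20)
  expect_equal(nrow(d3), sum(table(d3$id)))
})

test_that("datasets round-trip through CSV with their hidden truth", {
  tr <- quick_truth()
  d <- simulate_melsm(tr, seed = 3)
  path <- file.path(tempdir(), "melsm-test.csv")
  write_melsm_dataset(d, path)
  back <- read_melsm_dataset(path)
  expect_equal(back$y, d$y, tolerance = 1e-12)
  expect_equal(back$.omega, d$.omega, tolerance = 1e-12)
  re <- attr(back, "random_effects")
  expect_equal(re$u_loc_intercept,
               attr(d, "random_effects")$u_loc_intercept, tolerance = 1e-12)
  unlink(c(path, sub("\\.csv$", "-truth.csv", path)))
})
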