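# Likelihood engine: conditional density, marginalisation oracles, priors.

test_that("conditional log-likelihood matches the density-sum oracle", {
  # standard normal at zero
  d1 <- tibble::tibble(id = 1, age = 0, albumin = 0, trig = 0, platelet = 0,
                       y = 0)
  spec <- spec_correct()
  pars <- c("loc_(Intercept)" = 0, loc_age = 0, loc_albumin = 0,
            "scale_(Intercept)" = 0, scale_age = 0, scale_trig = 0,
            "sd_loc_(Intercept)" = 1, "sd_scale_(Intercept)" = 0.5)
  re0 <- tibble::tibble(id = 1, u_loc_intercept = 0, u_scale_intercept = 0)
  expect_equal(melsm_conditional_loglik(d1, spec, pars, re0),
               -0.5 * log(2 * pi), tolerance = 1e-9)
  expect_equal(-0.5 * log(2 * pi), -0.918939, tolerance = 1e-6)

  # random 10-row instance against an independent per-row sum
  set.seed(42)
  tr <- quick_truth()
  d <- simulate_melsm(tr, seed = 8)[1:10, ]
  re <- attr(simulate_melsm(tr, seed = 8), "random_effects")
  pars2 <- pars + rnorm(length(pars), 0, 0.1)
  names(pars2) <- names(pars)
  pars2[7:8] <- abs(pars2[7:8])
  mu <- pars2["loc_(Intercept)"] + pars2["loc_age"] * d$age +
    pars2["loc_albumin"] * d$albumin +
    re$u_loc_intercept[match(d$id, re$id)]
  sdv <- exp(pars2["scale_(Intercept)"] + pars2["scale_age"] * d$age +
               pars2["scale_trig"] * d$trig +
               re$u_scale_intercept[match(d$id, re$id)])
  oracle <- sum(dnorm(d$y, mu, sdv, log = TRUE))
  expect_equal(melsm_conditional_loglik(d, spec, pars2, re), oracle,
               tolerance = 1e-10)

  # adding ln 2 to the scale intercept at y = mean lowers each term by ln 2
  d0 <- d; d0$y <- as.numeric(mu)
  base <- melsm_conditional_loglik(d0, spec, pars2, re)
  pars3 <- pars2; pars3["scale_(Intercept)"] <- pars3["scale_(Intercept)"] + log(2)
  expect_equal(melsm_conditional_loglik(d0, spec, pars3, re),
               base - nrow(d0) * log(2), tolerance = 1e-9)
})

test_that("vanishing random-effect SDs collapse the marginal to u = 0", {
  tr <- quick_truth()
  d <- simulate_melsm(tr, seed = 21)
  spec <- spec_correct()
  pars <- truth_parameters(tr, spec)
  pars["sd_loc_(Intercept)"] <- 1e-8
  pars["sd_scale_(Intercept)"] <- 1e-8
  re0 <- tibble::tibble(id = unique(d$id), u_loc_intercept = 0,
                        u_scale_intercept = 0)
  expect_equal(melsm_marginal_loglik(d, spec, pars),
               melsm_conditional_loglik(d, spec, pars, re0),
               tolerance = 1e-5)
})

test_that("marginal likelihood matches the closed-form LMM density", {
  # location random intercept, constant residual SD: the marginal of each
  # subject is MVN with covariance sigma^2 11' + omega^2 I
  tr <- homoscedastic_truth(n_subjects = 25, mean_encounters = 6)
  d <- simulate_melsm(tr, seed = 33)
  spec <- spec_lmm()
  pars <- c("loc_(Intercept)" = 0.1, loc_age = 0.45, loc_albumin = 0.6,
            "scale_(Intercept)" = log(1.2), "sd_loc_(Intercept)" = 0.8)
  got <- melsm_marginal_loglik(d, spec, pars)
  oracle <- 0
  for (i in unique(d$id)) {
    di <- d[d$id == i, ]
    r <- di$y - (0.1 + 0.45 * di$age + 0.6 * di$albumin)
    V <- 0.8^2 + diag(1.2^2, nrow(di))
    oracle <- oracle - 0.5 * (nrow(di) * log(2 * pi) +
                                determinant(V)$modulus[1] +
                                drop(t(r) %*% solve(V, r)))
  }
  expect_equal(got, oracle, tolerance = 1e-6 * abs(oracle))
})

test_that("marginal likelihood matches plain Monte-Carlo integration", {
  # 2-D random effects (both intercepts), 3 observations
  tr <- melsm_truth(n_subjects = 1, mean_encounters = 2)
  base <- draw_baseline_covariates(1, seed = 4)
  rows <- expand_longitudinal(base, 3L)
  re <- tibble::tibble(id = 1, u_loc_intercept = 0.4, u_scale_intercept = -0.2)
  d <- generate_outcomes(rows, re, tr, seed = 6)
  spec <- spec_correct()
  pars <- truth_parameters(tr, spec)
  got <- melsm_marginal_loglik(d, spec, pars)

  set.seed(99)
  M <- 1e6
  u <- rnorm(M, 0, 1)
  v <- rnorm(M, 0, 0.5)
  eta <- 0.5 * d$age + 0.5 * d$albumin
  lsd <- 0.8 * d$age + 0.8 * d$trig
  ll <- numeric(M)
  for (j in 1:3) {
    ll <- ll + dnorm(d$y[j], eta[j] + u, exp(lsd[j] + v), log = TRUE)
  }
  m <- max(ll)
  mc <- m + log(mean(exp(ll - m)))
  w <- exp(ll - m)
  mcse <- sd(w) / (mean(w) * sqrt(M)) # relative SE of the mean
  expect_lt(mcse, 2e-3)
  expect_equal(got, mc, tolerance = max(5e-3, 4 * mcse) * abs(mc))
})

test_that("collapsed and joint integration routes agree", {
  tr <- melsm_truth(n_subjects = 20, mean_encounters = 8)
  d <- simulate_melsm(tr, seed = 55)
  spec <- spec_correct()
  pars <- truth_parameters(tr, spec)
  a <- melsm_marginal_loglik(d, spec, pars, method = "collapsed",
                             quad_points = 15)
  b <- melsm_marginal_loglik(d, spec, pars, method = "joint",
                             quad_points = 15)
  expect_equal(a, b, tolerance = 2e-3 * abs(a) / 20)
})

test_that("doubling the quadrature points leaves the marginal unchanged", {
  d <- simulate_melsm(melsm_truth(), seed = 3)
  spec <- spec_correct()
  pars <- truth_parameters(attr(d, "truth"), spec)
  a <- melsm_marginal_loglik(d, spec, pars, quad_points = 9)
  b <- melsm_marginal_loglik(d, spec, pars, quad_points = 18)
  expect_lt(abs(a - b), 1e-6 * abs(a))
})

test_that("marginal likelihood is additive and relabelling-invariant", {
  tr <- quick_truth()
  d <- simulate_melsm(tr, seed = 71)
  spec <- spec_correct()
  pars <- truth_parameters(tr, spec)
  half1 <- d[d$id <= 20, ]
  half2 <- d[d$id > 20, ]
  expect_equal(melsm_marginal_loglik(d, spec, pars),
               melsm_marginal_loglik(half1, spec, pars) +
                 melsm_marginal_loglik(half2, spec, pars),
               tolerance = 1e-8)

  single <- d[d$id == 1, ]
  bys <- attr(melsm_marginal_loglik(d, spec, pars, by_subject = TRUE),
              "by_subject")
  expect_equal(melsm_marginal_loglik(single, spec, pars), unname(bys[1]),
               tolerance = 1e-8)

  relab <- d
  relab$id <- max(d$id) + 1 - d$id
  relab <- relab[order(relab$id, relab$j), ]
  expect_equal(melsm_marginal_loglik(relab, spec, pars),
               melsm_marginal_loglik(d, spec, pars), tolerance = 1e-8)
})

test_that("the Fisher-identity score matches finite differences", {
  tr <- quick_truth()
  d <- simulate_melsm(tr, seed = 17)
  spec <- spec_correct()
  eng <- melsmsim:::new_engine(d, spec)
  theta <- melsmsim:::pack_params(truth_parameters(tr, spec), eng) + 0.05
  got <- attr(melsmsim:::engine_loglik(theta, eng, 9, "collapsed",
                                       want_grad = TRUE), "gradient")
  fd <- vapply(seq_along(theta), function(j) {
    e <- numeric(length(theta)); e[j] <- 1e-5
    (as.numeric(melsmsim:::engine_loglik(theta + e, eng, 9, "collapsed")) -
       as.numeric(melsmsim:::engine_loglik(theta - e, eng, 9, "collapsed"))) /
      2e-5
  }, numeric(1))
  expect_true(all(abs(got - fd) < 0.02 * (abs(fd) + 1)))
})

test_that("log priors follow the stated blocks", {
  spec <- spec_correct()
  pars <- truth_parameters(melsm_truth(), spec)
  # only the two SD blocks contribute; fixed effects are flat
  expected <- sum(log(2) + dt(c(1, 0.5) / 2.5, df = 3, log = TRUE) - log(2.5))
  expect_equal(melsm_log_prior(pars, spec), expected, tolerance = 1e-10)

  # boundary SD = 0 stays finite (half-t density at zero)
  pars0 <- pars
  pars0["sd_loc_(Intercept)"] <- 0
  expect_true(is.finite(melsm_log_prior(pars0, spec)))
  at0 <- log(2) + dt(0, 3, log = TRUE) - log(2.5)
  expect_equal(melsm_log_prior(pars0, spec) -
                 (log(2) + dt(0.5 / 2.5, 3, log = TRUE) - log(2.5)),
               at0, tolerance = 1e-10)

  # LKJ(1) is flat in the correlation
  spec_c <- melsm_spec("y ~ age + albumin + (1|id)",
                       "log(omega) ~ age + trig + (1|id)", correlated = TRUE)
  pc <- c(truth_parameters(melsm_truth(), spec_correct()), cor_loc_scale = 0.3)
  pc2 <- pc; pc2["cor_loc_scale"] <- -0.8
  expect_equal(melsm_log_prior(pc, spec_c), melsm_log_prior(pc2, spec_c),
               tolerance = 1e-12)
})
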