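# melsmsim

Simulation and estimation tools for studying **mixed-effects
location-scale models (MELSM)** under variance heterogeneity and model
misspecification.

Longitudinal analyses usually reach for the linear mixed model (LMM),
which assumes a constant residual SD. When the residual SD itself varies —
with covariates and between subjects — the MELSM models it explicitly:

    y_ij      = x_ij' beta_y  + z_ij' u_i  + e_ij,   e_ij ~ N(0, omega_ij^2)
    omega_ij  = exp( x_ij' beta_w + z_ij' v_i )

Both the *location* (mean) and the *scale* (log residual SD) carry fixed
effects and subject-level random effects; the LMM is the special case
`log(omega) ~ 1` with no scale random effects. This package answers, by
simulation, the questions practitioners actually face: what goes wrong if
heteroscedasticity is ignored, and how does misspecifying one submodel
(covariates, functional form, random-effect structure or distribution)
contaminate the other?

It provides, as first-class tested components:

* a **synthetic-data generator** for heteroscedastic longitudinal cohorts
  (PBC-patterned baseline covariates, uniform encounter counts, annual
  age progression, Gaussian or Student-t random intercepts, optional
  random slopes and a sinusoidal time trend);
* an **estimation engine** built from the model's marginal likelihood via
  adaptive Gauss-Hermite quadrature — a fast maximum-likelihood backend
  with Fisher-identity gradients and Wald intervals, and an adaptive
  Metropolis posterior-sampling backend with weakly-informative default
  priors and split-Rhat/ESS diagnostics;
* an **evaluation layer** computing bias, interval coverage, interval
  width, the sampling SD of estimates and the mean reported SE across
  replications, with non-converged fits excluded and counted;
* a **scenario registry and replication runner** covering the five
  misspecification practices (LMM vs MELSM over sample-size grids;
  covariate misspecification in either submodel; missing non-linearity;
  missing random slopes; Student vs Gaussian random intercepts), with
  paired datasets across fitted models within a practice.

## A worked example

```r
library(melsmsim)

truth <- melsm_truth()            # N = 200 subjects, M = 15 mean encounters
data  <- simulate_melsm(truth, seed = 1)
fit   <- fit_melsm(data, spec_correct())
tidy(fit)
#> # A tibble: 8 × 5
#>   term                 estimate std.error conf.low conf.high
#>   <chr>                   <dbl>     <dbl>    <dbl>     <dbl>
#> 1 loc_(Intercept)       -0.103     0.0799  -0.259     0.0536
#> 2 loc_age                0.480     0.0119   0.457     0.503
#> 3 loc_albumin            0.354     0.0866   0.184     0.524
#> 4 scale_(Intercept)      0.0219    0.0410  -0.0586    0.102
#> 5 scale_age              0.782     0.0190   0.745     0.820
#> 6 scale_trig             0.869     0.0367   0.797     0.941
#> 7 sd_loc_(Intercept)     0.932     0.0624   0.817     1.06
#> 8 sd_scale_(Intercept)   0.483     0.0296   0.428     0.544
```

The generative values here were `loc_age = loc_albumin = 0.5`,
`scale_age = scale_trig = 0.8`, random-intercept SDs 1 and 0.5, and zero
intercepts: a single fit recovers each of them within its interval. A
paired replication study contrasts models on identical datasets:

```r
scen <- dplyr::bind_rows(
  melsm_scenario("melsm", "Correct MELSM", truth, spec_correct(),
                 data_id = "demo"),
  melsm_scenario("lmm", "LMM", truth,
                 melsm_spec("y ~ age + albumin + (1|id)", "log(omega) ~ 1"),
                 data_id = "demo")
)
study <- run_study(scen, replications = 20, master_seed = 1)
dplyr::filter(study$metrics, parameter == "loc_age") |>
  dplyr::select(scenario, truth, bias, coverage, estimate_sd, mean_se)
#> # A tibble: 2 × 6
#>   scenario truth     bias coverage estimate_sd mean_se
#>   <chr>    <dbl>    <dbl>    <dbl>       <dbl>   <dbl>
#> 1 lmm        0.5 -0.0393        80      0.255   0.193
#> 2 melsm      0.5 -0.00161      100      0.0119  0.0179
```

Read: fitted to the *same* twenty heteroscedastic datasets, the correctly
specified MELSM is unbiased with a reported SE on the order of the true
sampling SD and intervals that always covered here, while the LMM's
location-age interval covers the truth only 80% of the time — its reported
SE (0.19) understates the true sampling variability (0.26), and the gap
widens with more replications (coverage is about 68% at 100 replications).
`autoplot(study)` draws the corresponding boxplot-with-coverage figure;
`export_report(study)` returns it as a table.

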