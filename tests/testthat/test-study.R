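# Scenario registry and the replication runner.

test_that("the registry lists the documented scenarios", {
  scen <- melsm_scenarios()
  expect_false(anyDuplicated(scen$id) > 0)

  p2 <- scen[scen$practice == 2, ]
  expect_equal(nrow(p2), 6)
  expect_setequal(p2$id, c("p2_correct", "p2_all", "p2_mis_y", "p2_mis_omega",
                           "p2_no_uw", "p2_no_uw_mis_omega"))

  # Practice 1: two fitted models per (N, M) grid cell
  p1 <- scen[scen$practice == 1, ]
  expect_equal(nrow(p1), 2 * 4 * 3)
  lmm <- p1$spec[[which(p1$id == "p1_n100_m5_lmm")]]
  expect_equal(nrow(lmm$scale$fixed_terms), 0)
  expect_null(lmm$scale$random)

  expect_equal(nrow(scen[scen$practice == 3, ]), 2)
  expect_equal(nrow(scen[scen$practice == 4, ]), 3)
  expect_equal(nrow(scen[scen$practice == 5, ]), 2)

  # generative truths are self-describing
  p5 <- scen$truth[[which(scen$id == "p5_student")]]
  expect_equal(p5$re_distribution, "student_t")
  expect_equal(p5$re_df, 3)
  p4 <- scen$truth[[which(scen$id == "p4_correct_slopes")]]
  expect_equal(p4$slope_sd_loc, 1)
  expect_equal(p4$slope_sd_scale, 0.5)
  p3 <- scen$truth[[which(scen$id == "p3_correct_sin")]]
  expect_equal(p3$age_transform, "sin")
})

test_that("replications are deterministic and paired within a practice", {
  scen <- dplyr::bind_rows(
    melsm_scenario("a", "model A", quick_truth(), spec_correct(),
                   data_id = "shared"),
    melsm_scenario("b", "model B", quick_truth(), spec_correct(),
                   data_id = "shared"),
    melsm_scenario("c", "model C", quick_truth(), spec_correct(),
                   data_id = "other")
  )
  r1 <- run_replication(scen[1, ], 3, master_seed = 9)
  r1b <- run_replication(scen[1, ], 3, master_seed = 9)
  # elapsed wall time is informational
  expect_identical(dplyr::select(r1, -"elapsed"),
                   dplyr::select(r1b, -"elapsed"))

  # same data_id -> identical dataset -> identical estimates under the same
  # spec; different data_id -> different dataset
  r2 <- run_replication(scen[2, ], 3, master_seed = 9)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-10)
  r3 <- run_replication(scen[3, ], 3, master_seed = 9)
  expect_false(isTRUE(all.equal(r1$estimate, r3$estimate)))
})

test_that("records carry exactly the parameters of the fitted spec", {
  scen <- melsm_scenario("lmm", "LMM", quick_truth(), spec_lmm())
  r <- run_replication(scen, 1, master_seed = 4)
  expect_setequal(r$parameter,
                  c("loc_(Intercept)", "loc_age", "loc_albumin",
                    "scale_(Intercept)", "sd_loc_(Intercept)"))
  expect_false("sd_scale_(Intercept)" %in% r$parameter)
  # truths: zero intercepts, table coefficients, RE SD
  expect_equal(r$truth[r$parameter == "loc_age"], 0.5)
  expect_equal(r$truth[r$parameter == "loc_(Intercept)"], 0)
  expect_equal(r$truth[r$parameter == "sd_loc_(Intercept)"], 1)
})

test_that("run_study aggregates, reruns identically, and writes outputs", {
  scen <- dplyr::bind_rows(
    melsm_scenario("m1", "correct", quick_truth(), spec_correct(),
                   data_id = "d"),
    melsm_scenario("m2", "lmm", quick_truth(), spec_lmm(), data_id = "d")
  )
  out_dir <- file.path(tempdir(), "melsm-study-test")
  st <- run_study(scen, replications = 3, master_seed = 21, out_dir = out_dir)
  expect_equal(dplyr::n_distinct(st$records$rep), 3)
  expect_true(all(c("bias", "coverage", "estimate_sd", "mean_se",
                    "width_mean") %in% names(st$metrics)))
  expect_true(file.exists(file.path(out_dir, "metrics.csv")))
  expect_true(file.exists(file.path(out_dir, "records-m1.csv")))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))

  st2 <- run_study(scen, replications = 3, master_seed = 21)
  expect_equal(dplyr::select(st$records, -"elapsed"),
               dplyr::select(st2$records, -"elapsed"))
  expect_equal(st$metrics, st2$metrics)

  empty <- run_study(scen[0, ], replications = 3, master_seed = 21)
  expect_equal(nrow(empty$records), 0)

  rep_tab <- export_report(st)
  expect_true(all(c("ymin", "q1", "median", "q3", "ymax", "coverage")
                  %in% names(rep_tab)))
  est <- st$records$estimate[st$records$scenario == "m1" &
                               st$records$parameter == "loc_age" &
                               st$records$converged]
  row <- rep_tab[rep_tab$scenario == "m1" & rep_tab$parameter == "loc_age", ]
  expect_equal(row$median, stats::median(est))
  expect_equal(row$q1, unname(quantile(est, 0.25)))

  p <- autoplot(st)
  expect_s3_class(p, "ggplot")
  unlink(out_dir, recursive = TRUE)
})

test_that("estimation error shrinks as the population grows", {
  # echoes the sample-size practice: the sampling SD of the location age
  # effect falls as N increases (reduced-scale grid)
  rmse <- c()
  for (n in c(40, 160, 640)) {
    scen <- melsm_scenario(paste0("n", n), "correct",
                           melsm_truth(n_subjects = n, mean_encounters = 5),
                           spec_correct())
    st <- run_study(scen, replications = 14, master_seed = 5,
                    control = list(reltol = 1e-8))
    est <- st$records$estimate[st$records$parameter == "loc_age" &
                                 st$records$converged]
    rmse <- c(rmse, sqrt(mean((est - 0.5)^2)))
  }
  expect_true(all(diff(rmse) < 0))
})
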