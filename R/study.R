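# Replication loop: one scenario x replication -> one fitted record;
# a study = scenarios x replications -> records + metric table.

#' Run a single replication of a scenario
#'
#' Derives the replication's seed from `(master_seed, data_id, index)`,
#' generates a fresh dataset from the scenario's truth, fits the scenario's
#' specification, and returns the per-parameter record. Because the seed
#' depends on the scenario's `data_id` (not its `id`), every fitted model
#' within a practice sees the *same* dataset at a given replication index —
#' model contrasts are paired.
#'
#' @param scenario A one-row scenario tibble (see [melsm_scenario()]).
#' @param index Replication index (1, 2, ...).
#' @param master_seed Master seed of the study.
#' @param backend Optional backend override (`"mle"` or `"mcmc"`).
#' @param quad_points Gauss-Hermite points per random-effect dimension.
#' @param ... Further arguments passed to [fit_melsm()].
#' @return A tibble with one row per estimated parameter: `scenario`, `rep`,
#'   `backend`, `parameter`, `truth`, `estimate`, `se`, `lower`, `upper`,
#'   `rhat`, `ess`, `converged`, `elapsed`.
#' @export
run_replication <- function(scenario, index, master_seed = 1L, backend = NULL,
                            quad_points = 9, ...) {
  stopifnot(is.data.frame(scenario), nrow(scenario) == 1)
  truth <- scenario$truth[[1]]
  spec <- scenario$spec[[1]]
  backend <- backend %||% scenario$backend
  seed <- derive_seed(master_seed, paste0("data-", scenario$data_id), index)
  data <- simulate_melsm(truth, seed)
  fit <- tryCatch(
    fit_melsm(data, spec, backend = backend, alpha = scenario$alpha,
              quad_points = quad_points,
              seed = derive_seed(master_seed, paste0("fit-", scenario$id), index),
              ...),
    error = function(e) e
  )
  truths <- truth_parameters(truth, spec)
  if (inherits(fit, "error")) {
    return(tibble::tibble(
      scenario = scenario$id, rep = as.integer(index), backend = backend,
      parameter = names(truths), truth = unname(truths),
      estimate = NA_real_, se = NA_real_, lower = NA_real_, upper = NA_real_,
      rhat = NA_real_, ess = NA_real_, converged = FALSE,
      elapsed = NA_real_
    ))
  }
  summary <- fit_summary(fit)
  dplyr::bind_cols(
    tibble::tibble(scenario = scenario$id, rep = as.integer(index),
                   backend = backend)[rep(1, nrow(summary)), ],
    tibble::tibble(parameter = summary$parameter,
                   truth = unname(truths[summary$parameter])),
    summary[c("estimate", "se", "lower", "upper", "rhat", "ess", "converged")],
    tibble::tibble(elapsed = fit$time)
  )
}

#' Run a replication study over a set of scenarios
#'
#' @param scenarios Scenario tibble ([melsm_scenarios()] or hand-built rows).
#' @param replications Replication count (overrides the per-scenario
#'   default when given).
#' @param master_seed Master seed; every dataset and fit seed derives from it.
#' @param backend Optional backend override applied to all scenarios.
#' @param quad_points Gauss-Hermite points per random-effect dimension.
#' @param out_dir Optional output directory: writes a `manifest.json`,
#'   per-scenario record CSVs, and the metric table as CSV (and JSON when
#'   jsonlite is available).
#' @param progress Print per-scenario progress lines to stderr?
#' @param ... Passed on to [run_replication()] / [fit_melsm()].
#' @return A `melsm_study`: list with `records` (long tibble), `metrics`
#'   (the aggregate table of [aggregate_metrics()]), `scenarios`, and
#'   `config`.
#' @export
run_study <- function(scenarios, replications = NULL, master_seed = 1L,
                      backend = NULL, quad_points = 9, out_dir = NULL,
                      progress = FALSE, ...) {
  stopifnot(is.data.frame(scenarios))
  if (anyDuplicated(scenarios$id)) abort("scenario ids must be unique")
  records <- purrr::map_dfr(seq_len(nrow(scenarios)), function(si) {
    scen <- scenarios[si, ]
    reps <- replications %||% scen$replications
    if (progress) {
      message(sprintf("[%s] %d replications ...", scen$id, reps))
    }
    purrr::map_dfr(seq_len(reps), function(r) {
      run_replication(scen, r, master_seed = master_seed, backend = backend,
                      quad_points = quad_points, ...)
    })
  })
  metrics <- if (nrow(records)) aggregate_metrics(records) else tibble::tibble()
  result <- structure(
    list(records = records, metrics = metrics, scenarios = scenarios,
         config = list(master_seed = master_seed,
                       replications = replications,
                       backend = backend, quad_points = quad_points,
                       package_version = as.character(
                         utils::packageVersion("melsmsim")))),
    class = "melsm_study"
  )
  if (!is.null(out_dir)) write_study(result, out_dir)
  result
}

write_study <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      c(result$config,
        list(scenario_ids = result$scenarios$id,
             formulas = lapply(result$scenarios$spec, format))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  for (id in unique(result$records$scenario)) {
    utils::write.csv(result$records[result$records$scenario == id, ],
                     file.path(out_dir, paste0("records-", id, ".csv")),
                     row.names = FALSE)
  }
  if (nrow(result$metrics)) {
    utils::write.csv(result$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(result$metrics, file.path(out_dir, "metrics.json"),
                           dataframe = "rows", digits = NA)
    }
  }
  invisible(out_dir)
}

#' @export
print.melsm_study <- function(x, ...) {
  cat(sprintf("<melsm_study> %d scenarios, %d replication records\n",
              nrow(x$scenarios), dplyr::n_distinct(x$records[c("scenario", "rep")])))
  excl <- x$records |>
    dplyr::distinct(.data$scenario, .data$rep, .data$converged) |>
    dplyr::summarise(excluded = sum(!.data$converged), .by = "scenario")
  if (any(excl$excluded > 0)) {
    cat("  non-converged replications excluded from metrics:\n")
    for (i in which(excl$excluded > 0)) {
      cat(sprintf("    %s: %d\n", excl$scenario[i], excl$excluded[i]))
    }
  }
  invisible(x)
}

#' Tabular report of a study: boxplot summaries plus coverage
#'
#' For each (scenario, parameter) the five-number summary of the point
#' estimates across converged replications (whiskers at the most extreme
#' points within 1.5 IQR of the quartiles, as drawn by a standard boxplot)
#' with the empirical coverage attached — the numeric content of the usual
#' boxplot-with-coverage figures.
#'
#' @param result A `melsm_study` from [run_study()].
#' @return A tibble with columns `scenario`, `parameter`, `truth`, `ymin`,
#'   `q1`, `median`, `q3`, `ymax`, `coverage`, `n_converged`.
#' @export
export_report <- function(result) {
  stopifnot(inherits(result, "melsm_study"))
  conv <- dplyr::filter(result$records, .data$converged)
  box <- dplyr::summarise(
    dplyr::group_by(conv, .data$scenario, .data$parameter),
    truth = .data$truth[1],
    ymin = box_whisker(.data$estimate, lower = TRUE),
    q1 = quantile(.data$estimate, 0.25, names = FALSE),
    median = quantile(.data$estimate, 0.5, names = FALSE),
    q3 = quantile(.data$estimate, 0.75, names = FALSE),
    ymax = box_whisker(.data$estimate, lower = FALSE),
    coverage = 100 * mean(.data$lower < .data$truth &
                            .data$truth < .data$upper),
    n_converged = dplyr::n(),
    .groups = "drop"
  )
  box
}

box_whisker <- function(x, lower) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  if (lower) min(x[x >= q[1] - 1.5 * iqr]) else max(x[x <= q[2] + 1.5 * iqr])
}

#' Boxplot figure of estimates by scenario
#'
#' @param object A `melsm_study`.
#' @param parameter Which parameter to display (default the location age
#'   effect).
#' @param ... Unused.
#' @return A ggplot object: boxplots of the replication estimates per
#'   scenario, the true value as a vertical reference line, and coverage
#'   annotated at the right margin.
#' @method autoplot melsm_study
#' @export
autoplot.melsm_study <- function(object, parameter = "loc_age", ...) {
  df <- dplyr::filter(object$records, .data$converged,
                      .data$parameter == !!parameter)
  if (nrow(df) == 0) abort(sprintf("no records for parameter '%s'", parameter))
  cov <- coverage(df)
  truth <- df$truth[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$scenario)) +
    ggplot2::geom_vline(xintercept = truth, colour = "red") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_text(data = cov,
                       ggplot2::aes(x = max(df$estimate),
                                    label = sprintf("%.0f%%", .data$coverage)),
                       hjust = -0.2, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(.05, .15))) +
    ggplot2::labs(x = sprintf("estimate of %s (truth %.3g)", parameter, truth),
                  y = NULL)
}
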