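# Replication-study estimands: coverage, bias, interval width, the sampling
# SD of the estimates, and the average reported SE. All metrics are computed
# over converged replications only; the number excluded is carried alongside.

# Records are long tibbles with one row per (scenario, replication,
# parameter): columns `parameter`, `estimate`, `se`, `lower`, `upper`,
# `converged`, optionally `scenario` and `rep`, and `truth` (either as a
# column or supplied separately).

resolve_truth <- function(records, truths) {
  if (!is.null(truths)) {
    if (!is.data.frame(truths)) {
      truths <- tibble::tibble(parameter = names(truths),
                               truth = unname(unlist(truths)))
    }
    records$truth <- NULL
    records <- dplyr::left_join(records, truths, by = "parameter")
  }
  if (!"truth" %in% names(records)) {
    abort("no truth values: supply `truths` or a `truth` column")
  }
  records
}

metric_groups <- function(records) {
  dplyr::group_by(records,
                  dplyr::across(dplyr::any_of(c("scenario", "parameter"))))
}

#' Empirical coverage of interval estimates
#'
#' The percentage of converged replications whose interval strictly contains
#' the true parameter value, `100 * mean(lower < truth & truth < upper)`.
#' Parameters with no converged replication are reported as missing.
#'
#' @param records Long replication records (see Details in
#'   [aggregate_metrics()]).
#' @param truths Optional named vector or tibble (`parameter`, `truth`) of
#'   true values; may be omitted when `records` carries a `truth` column.
#' @return A tibble with one row per (scenario,) parameter: `coverage` in
#'   percent and `n_converged`.
#' @export
coverage <- function(records, truths = NULL) {
  records <- resolve_truth(records, truths)
  dplyr::summarise(
    metric_groups(dplyr::filter(records, .data$converged)),
    coverage = 100 * mean(.data$lower < .data$truth &
                            .data$truth < .data$upper),
    n_converged = dplyr::n(),
    .groups = "drop"
  )
}

#' Bias of the point estimates
#'
#' `mean(estimate) - truth` over converged replications.
#'
#' @inheritParams coverage
#' @return A tibble with columns `truth`, `mean_estimate`, `bias`,
#'   `n_converged` per (scenario,) parameter.
#' @export
bias <- function(records, truths = NULL) {
  records <- resolve_truth(records, truths)
  dplyr::summarise(
    metric_groups(dplyr::filter(records, .data$converged)),
    truth = .data$truth[1],
    mean_estimate = mean(.data$estimate),
    bias = mean(.data$estimate) - .data$truth[1],
    n_converged = dplyr::n(),
    .groups = "drop"
  )
}

#' Mean estimated interval width
#'
#' `mean(upper - lower)` over converged replications.
#'
#' @inheritParams coverage
#' @export
interval_width <- function(records) {
  dplyr::summarise(
    metric_groups(dplyr::filter(records, .data$converged)),
    width_mean = mean(.data$upper - .data$lower),
    n_converged = dplyr::n(),
    .groups = "drop"
  )
}

#' Sampling standard deviation of the estimates
#'
#' The n-1 sample SD of the point estimates across converged replications —
#' the Monte-Carlo truth against which reported standard errors can be
#' calibrated.
#'
#' @inheritParams coverage
#' @export
estimate_sd <- function(records) {
  dplyr::summarise(
    metric_groups(dplyr::filter(records, .data$converged)),
    estimate_sd = sd(.data$estimate),
    n_converged = dplyr::n(),
    .groups = "drop"
  )
}

#' Average reported standard error
#'
#' `mean(se)` over converged replications; under correct specification this
#' should match [estimate_sd()].
#'
#' @inheritParams coverage
#' @export
mean_se <- function(records) {
  dplyr::summarise(
    metric_groups(dplyr::filter(records, .data$converged)),
    mean_se = mean(.data$se),
    n_converged = dplyr::n(),
    .groups = "drop"
  )
}

#' Aggregate all replication metrics into one table
#'
#' One row per (scenario, parameter) with the truth, mean estimate, bias,
#' coverage (percent), mean interval width, sampling SD of the estimates,
#' average reported SE, and the converged / total replication counts.
#' Parameters that a fitted specification does not estimate are simply
#' absent. Metrics use converged replications only; `n_total - n_converged`
#' is the exclusion count.
#'
#' @inheritParams coverage
#' @return The metric tibble described above.
#' @export
aggregate_metrics <- function(records, truths = NULL) {
  records <- resolve_truth(records, truths)
  totals <- dplyr::summarise(metric_groups(records),
                             n_total = dplyr::n(), .groups = "drop")
  conv <- dplyr::filter(records, .data$converged)
  if (nrow(conv) == 0) {
    return(dplyr::mutate(totals, truth = NA_real_, mean_estimate = NA_real_,
                         bias = NA_real_, coverage = NA_real_,
                         width_mean = NA_real_, estimate_sd = NA_real_,
                         mean_se = NA_real_, n_converged = 0L))
  }
  out <- dplyr::summarise(
    metric_groups(conv),
    truth = .data$truth[1],
    mean_estimate = mean(.data$estimate),
    bias = mean(.data$estimate) - .data$truth[1],
    coverage = 100 * mean(.data$lower < .data$truth &
                            .data$truth < .data$upper),
    width_mean = mean(.data$upper - .data$lower),
    estimate_sd = sd(.data$estimate),
    mean_se = mean(.data$se),
    n_converged = dplyr::n(),
    .groups = "drop"
  )
  dplyr::left_join(totals, out,
                   by = intersect(c("scenario", "parameter"), names(totals)))
}
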