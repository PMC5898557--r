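check_trials <- function(results) {
  if (length(results) == 0) abort("`results` must contain at least one trial.")
  if (inherits(results, "fa_trial")) results <- list(results)
  ok <- vapply(results, inherits, logical(1), what = "fa_trial")
  if (!all(ok)) abort("`results` must be a list of `fa_trial` objects.")
  results
}

#' Expected proportion of failures (EPF)
#'
#' Mean over simulated trials of the fraction of enrolled patients with a
#' failure (non-response) outcome at termination. The per-trial average
#' (unweighted across trials) is the primary definition; `pooled = TRUE`
#' instead pools patients across trials.
#'
#' @param results List of `fa_trial` objects.
#' @param pooled Pool patients across trials instead of averaging per-trial
#'   proportions. Default `FALSE`.
#' @return Scalar in \[0, 1\].
#' @export
epf <- function(results, pooled = FALSE) {
  results <- check_trials(results)
  fail <- vapply(results, function(r) r$total_failures, numeric(1))
  enr <- vapply(results, function(r) r$total_enrolled, numeric(1))
  if (any(enr == 0)) abort("every trial must have at least one enrolled patient.")
  if (pooled) sum(fail) / sum(enr) else mean(fail / enr)
}

#' Expected sample size (ESS) at termination
#'
#' Mean total enrolment at trial termination over simulated trials.
#'
#' @param results List of `fa_trial` objects.
#' @return Scalar.
#' @export
ess <- function(results) {
  results <- check_trials(results)
  mean(vapply(results, function(r) r$total_enrolled, numeric(1)))
}

same_schedule <- function(results) {
  s0 <- results[[1]]$schedule
  same <- vapply(results, function(r) {
    identical(r$schedule$look_targets, s0$look_targets)
  }, logical(1))
  if (!all(same)) abort("all trials must share one look schedule.")
  s0
}

#' Cumulative termination distribution over information fractions
#'
#' Fraction of trials terminated at or before each analysis look; look `k`
#' corresponds to an information fraction of `k / (n_looks + 1)` of the
#' maximum sample size (20%, 40%, ... for the default four interim looks).
#' Non-decreasing with final value 1 (every trial ends by the final look).
#'
#' @param results List of `fa_trial` objects sharing one schedule.
#' @return A tibble with `look`, `information_fraction`,
#'   `cumulative_probability`.
#' @export
termination_ecdf <- function(results) {
  results <- check_trials(results)
  s <- same_schedule(results)
  K <- length(s$look_targets)
  term <- vapply(results, function(r) r$termination_look, numeric(1))
  tibble(
    look = seq_len(K),
    information_fraction = seq_len(K) / K,
    cumulative_probability = vapply(seq_len(K),
                                    function(k) mean(term <= k), numeric(1))
  )
}

#' Root mean squared error of interim estimates
#'
#' Pools the per-look posterior-mean estimates over all simulated trials and
#' all realized looks, and returns the square root of the mean squared
#' deviation from the true value:
#' \deqn{\mathrm{RMSE}_T = \sqrt{\tfrac{1}{\sum_m K_m}\sum_{m}\sum_{k=1}^{K_m}
#'   (\hat\theta^{(mk)}_T - \theta_T)^2}.}
#' Early-stopped trials contribute only their realized looks (`fixed_K =
#' TRUE` instead repeats a trial's last estimate through the full schedule,
#' so every trial contributes the same number of terms).
#'
#' @param results List of `fa_trial` objects.
#' @param truth An `fa_truth` giving the true values.
#' @param parameter One of `"theta_A"`, `"theta_B"`, `"theta_AB"`, `"f"`.
#' @param fixed_K Use a fixed number of terms per trial (default `FALSE`).
#' @return Scalar RMSE (log-odds units).
#' @export
rmse <- function(results, truth, parameter = "theta_AB", fixed_K = FALSE) {
  results <- check_trials(results)
  stopifnot(inherits(truth, "fa_truth"))
  parameter <- match.arg(parameter, c("theta_A", "theta_B", "theta_AB", "f"))
  col <- c(theta_A = "mean_theta_A", theta_B = "mean_theta_B",
           theta_AB = "mean_theta_AB", f = "mean_f")[[parameter]]
  true_val <- truth[[parameter]]
  K_max <- length(results[[1]]$schedule$look_targets)
  errs <- unlist(lapply(results, function(r) {
    est <- r$looks[[col]]
    if (any(is.na(est))) {
      abort(sprintf("parameter `%s` is not estimated by the %s model.",
                    parameter, r$spec$kind))
    }
    e <- est - true_val
    if (fixed_K && length(e) < K_max) {
      e <- c(e, rep(e[length(e)], K_max - length(e)))
    }
    e
  }))
  sqrt(mean(errs^2))
}

#' Aggregate operating characteristics over simulated trials
#'
#' One-row summary of a batch of simulated trials from a single
#' scenario-model cell: EPF, ESS, the termination distribution, and RMSEs of
#' the three effect parameters.
#'
#' @param results List of `fa_trial` objects (one scenario, one model).
#' @param truth An `fa_truth`; defaults to the trials' scenario truth.
#' @param model Label for the model column; defaults to the model kind.
#' @param scenario Label for the scenario column.
#' @return A one-row tibble with columns `model`, `scenario`, `M`, `epf`,
#'   `epf_pooled`, `ess`, `early_stop_fraction`, `first_look_stop_fraction`,
#'   `rmse_theta_A`, `rmse_theta_B`, `rmse_theta_AB`, and `ecdf` (list-column
#'   holding the [termination_ecdf()] tibble).
#' @export
summarize_trials <- function(results, truth = NULL, model = NULL,
                             scenario = NA_character_) {
  results <- check_trials(results)
  if (is.null(truth)) truth <- scenario_truth(results[[1]]$scenario)
  if (is.null(model)) model <- results[[1]]$spec$kind
  ec <- termination_ecdf(results)
  term <- vapply(results, function(r) r$termination_look, numeric(1))
  K <- length(results[[1]]$schedule$look_targets)
  tibble(
    model = model, scenario = scenario, M = length(results),
    epf = epf(results), epf_pooled = epf(results, pooled = TRUE),
    ess = ess(results),
    early_stop_fraction = mean(term < K),
    first_look_stop_fraction = mean(term == 1),
    rmse_theta_A = rmse(results, truth, "theta_A"),
    rmse_theta_B = rmse(results, truth, "theta_B"),
    rmse_theta_AB = rmse(results, truth, "theta_AB"),
    ecdf = list(ec)
  )
}

#' Compare models against a baseline
#'
#' Relative reductions in EPF and ESS of each model against a baseline model
#' (the conventional analysis by default), plus RMSE differences, within one
#' scenario: `reduction = (metric_baseline - metric_model) / metric_baseline`.
#'
#' @param summaries Tibble of rows from [summarize_trials()] sharing one
#'   scenario and `M`.
#' @param baseline Model label used as the reference (default
#'   `"conventional"`).
#' @return `summaries` with added columns `epf_rel_reduction`,
#'   `ess_rel_reduction`, and `rmse_theta_AB_diff` (model minus baseline).
#' @export
compare_models <- function(summaries, baseline = "conventional") {
  stopifnot(is.data.frame(summaries))
  if (dplyr::n_distinct(summaries$scenario) > 1 ||
      dplyr::n_distinct(summaries$M) > 1) {
    abort("`summaries` must share one scenario and one M.")
  }
  base <- dplyr::filter(summaries, .data$model == baseline)
  if (nrow(base) != 1) {
    abort(sprintf("exactly one row must have model == \"%s\".", baseline))
  }
  dplyr::mutate(
    summaries,
    epf_rel_reduction = (base$epf - .data$epf) / base$epf,
    ess_rel_reduction = (base$ess - .data$ess) / base$ess,
    rmse_theta_AB_diff = .data$rmse_theta_AB - base$rmse_theta_AB
  )
}

#' Plot cumulative termination probability by information fraction
#'
#' @param summaries Tibble of rows from [summarize_trials()] (the `ecdf`
#'   list-column is unnested for plotting).
#' @return A ggplot of cumulative termination probability against
#'   information fraction, one line per model.
#' @export
plot_termination_ecdf <- function(summaries) {
  d <- summaries |>
    dplyr::select("model", "scenario", "ecdf") |>
    tidyr::unnest("ecdf")
  ggplot2::ggplot(d, ggplot2::aes(.data$information_fraction,
                                  .data$cumulative_probability,
                                  colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "information fraction", y = "Pr(terminated)",
                  colour = "model")
}
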