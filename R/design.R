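#' Fixed-design per-arm sample size for two proportions
#'
#' Normal-approximation sample size for detecting the difference between two
#' failure probabilities with a two-sided test, using the pooled variance
#' under the null and unpooled variances under the alternative:
#' \deqn{n = \frac{\left(z_{1-\alpha/2}\sqrt{2\bar p(1-\bar p)} +
#'   z_{1-\beta}\sqrt{p_1(1-p_1)+p_2(1-p_2)}\right)^2}{(p_1-p_2)^2},
#'   \quad \bar p = (p_1+p_2)/2,}
#' rounded to the nearest integer. In the three-arm combination design, `p1`
#' is the failure probability of the better single agent and `p2` that of the
#' combination; the resulting per-arm `n` anchors the interim-look schedule.
#'
#' @param p1,p2 Failure probabilities in (0, 1), `p1 != p2`.
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.80).
#' @return Integer per-arm sample size.
#' @examples
#' required_n_per_arm(0.35, 0.26415)  # f = 1 combination vs better agent
#' @export
required_n_per_arm <- function(p1, p2, alpha = 0.05, power = 0.80) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1,
            alpha > 0, alpha < 1, power > 0, power < 1)
  if (p1 == p2) abort("`p1` and `p2` must differ (otherwise n is infinite).")
  z_a <- qnorm(1 - alpha / 2)
  z_b <- qnorm(power)
  pbar <- (p1 + p2) / 2
  num <- (z_a * sqrt(2 * pbar * (1 - pbar)) +
            z_b * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2
  as.integer(round(num / (p1 - p2)^2))
}

#' Design-assumed additivity for weak-additivity scenarios
#'
#' When the simulated fractional additivity is absent or weak, the trial is
#' deliberately sized under an optimistic assumption: the design value of `f`
#' is the true value plus an upward bias of 0.5. Data are still simulated at
#' the true `f`; only the sample-size anchor uses the biased value.
#'
#' @param f_true True fractional additivity.
#' @return `f_true + 0.5`.
#' @examples
#' design_effect_for_weak_scenarios(0)     # 0.5
#' design_effect_for_weak_scenarios(0.25)  # 0.75
#' @export
design_effect_for_weak_scenarios <- function(f_true) f_true + 0.5

#' Failure probabilities entering the design calculation
#'
#' `p1` is the failure probability of the better single agent (the smaller
#' failure probability); `p2` is the combination's failure probability implied
#' by the scenario's design additivity (`design_f`, usually the true `f`).
#'
#' @param config An `fa_scenario`.
#' @return Named numeric vector `c(p1 = , p2 = )`.
#' @export
design_failure_probs <- function(config) {
  stopifnot(inherits(config, "fa_scenario"))
  theta_A <- logit(1 - config$p_fail_A)
  theta_B <- logit(1 - config$p_fail_B)
  theta_AB <- combination_log_odds(theta_A, theta_B, config$design_f)
  c(p1 = min(config$p_fail_A, config$p_fail_B), p2 = 1 - expit(theta_AB))
}

#' Per-arm sample-size table for a set of scenarios
#'
#' @param scenarios A list of `fa_scenario` objects (or a single one).
#' @return A tibble with one row per scenario: `p_fail_A`, `p_fail_B`,
#'   `f_true`, `design_f`, `p1`, `p2`, `n_per_arm`, `n_total` (three arms).
#' @examples
#' scs <- list(
#'   scenario_config(0.35, 0.40, f_true = 1),
#'   scenario_config(0.40, 0.40, f_true = 1)
#' )
#' scenario_design_table(scs)
#' @export
scenario_design_table <- function(scenarios) {
  if (inherits(scenarios, "fa_scenario")) scenarios <- list(scenarios)
  purrr::map_dfr(scenarios, function(sc) {
    p <- design_failure_probs(sc)
    n <- required_n_per_arm(p[["p1"]], p[["p2"]], sc$alpha, sc$power)
    tibble(p_fail_A = sc$p_fail_A, p_fail_B = sc$p_fail_B,
           f_true = sc$f_true, design_f = sc$design_f,
           p1 = p[["p1"]], p2 = p[["p2"]],
           n_per_arm = n, n_total = 3L * n)
  })
}

#' Interim-look schedule
#'
#' The trial's maximum size is three times the fixed-design per-arm
#' requirement, and the `n_looks` interim analyses are spaced equally in
#' accrued patients between first enrolment and that maximum: look `k`
#' targets `round(k / (n_looks + 1) * total)` cumulative patients, with the
#' final (non-interim) analysis exactly at the maximum.
#'
#' @param n_per_arm_required Fixed-design per-arm sample size.
#' @param n_looks Number of interim looks (default 4, giving 5 analysis
#'   points including the final one).
#' @return An object of class `fa_schedule`: list with `total_max_n` and
#'   `look_targets` (length `n_looks + 1`, strictly increasing, last entry
#'   `total_max_n`).
#' @examples
#' build_schedule(452)  # targets 271, 542, 814, 1085, 1356
#' @export
build_schedule <- function(n_per_arm_required, n_looks = 4) {
  stopifnot(n_per_arm_required >= 1, n_looks >= 1,
            n_per_arm_required >= n_looks + 1)
  total <- 3L * as.integer(n_per_arm_required)
  k <- seq_len(n_looks)
  targets <- c(as.integer(round(k / (n_looks + 1) * total)), total)
  if (any(diff(targets) <= 0)) abort("look targets must be strictly increasing.")
  structure(list(total_max_n = total, look_targets = targets),
            class = "fa_schedule")
}

#' @export
print.fa_schedule <- function(x, ...) {
  cat("<fa_schedule> max", x$total_max_n, "patients; looks at",
      paste(x$look_targets, collapse = ", "), "\n")
  invisible(x)
}

schedule_for_scenario <- function(config) {
  p <- design_failure_probs(config)
  build_schedule(required_n_per_arm(p[["p1"]], p[["p2"]], config$alpha, config$power),
                 config$n_looks)
}
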