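#' Log-odds and inverse log-odds transforms
#'
#' `logit()` maps a probability to its log-odds; `expit()` is the inverse.
#' These are thin, domain-checked wrappers around [stats::qlogis()] and
#' [stats::plogis()], the scale on which all treatment effects in this package
#' live.
#'
#' @param p Probability, strictly inside (0, 1). Vectorised.
#' @param x Log-odds, any finite real. Vectorised.
#' @return `logit()` returns log-odds; `expit()` returns probabilities in
#'   (0, 1).
#' @examples
#' logit(0.65)
#' expit(logit(0.65))
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly inside (0, 1).")
  }
  qlogis(p)
}

#' @rdname logit
#' @export
expit <- function(x) plogis(x)

#' Combination-treatment effect under fractional additivity
#'
#' The effect (log-odds of response) of the combination of two treatments is
#' modelled as the better single agent's effect plus a fraction `f` of the
#' weaker agent's:
#' \deqn{\theta_{A\&B} = \max(\theta_A, \theta_B) + f \cdot \min(\theta_A, \theta_B).}
#' `f = 0` collapses to the better single agent, `f = 1` is full additivity
#' (the sum of the two effects). The mapping is symmetric in its two theta
#' arguments.
#'
#' @param theta_a,theta_b Log-odds of response for the two single agents.
#'   Vectorised.
#' @param f Fractional-additivity coefficient (typically in \[0, 1\], but any
#'   real is accepted; the prior used in inference is unbounded).
#' @return Log-odds of response for the combination arm.
#' @examples
#' combination_log_odds(logit(0.65), logit(0.60), f = 1)
#' combination_log_odds(logit(0.65), logit(0.60), f = 0)
#' @export
combination_log_odds <- function(theta_a, theta_b, f) {
  if (any(!is.finite(theta_a)) || any(!is.finite(theta_b)) || any(!is.finite(f))) {
    abort("`theta_a`, `theta_b` and `f` must be finite.")
  }
  pmax(theta_a, theta_b) + f * pmin(theta_a, theta_b)
}

#' Scenario configuration for a three-arm combination trial
#'
#' Bundles everything that defines one simulation scenario: the true failure
#' probabilities of the two single agents, the true fractional additivity, the
#' prognostic-imbalance variance, the prior on `f` used by the fractional
#' analysis model, the fixed-design parameters that size the trial, and the
#' adaptation thresholds.
#'
#' Failure convention: `p_fail_A` and `p_fail_B` are probabilities of treatment
#' FAILURE (non-response); effects are modelled as log-odds of RESPONSE, so
#' `theta_A = logit(1 - p_fail_A)`.
#'
#' @param p_fail_A,p_fail_B Failure probabilities of single agents A and B, in
#'   (0, 1).
#' @param f_true True fractional additivity used to simulate the combination
#'   arm.
#' @param sigma2 Variance of the per-patient prognostic offset added on the
#'   log-odds scale (>= 0). Default 0.16.
#' @param prior_mean_f Prior mean for `f` under the fractional analysis model.
#'   Defaults to `f_true` (an unbiased prior).
#' @param prior_var_f Prior variance for `f` (> 0). Default 0.16.
#' @param alpha Two-sided type-I error of the anchoring fixed design. Default
#'   0.05.
#' @param power Target power of the anchoring fixed design. Default 0.80.
#' @param n_looks Number of interim looks before the final analysis. Default 4.
#' @param stop_prob Early-termination threshold: stop when some arm's posterior
#'   probability of being best strictly exceeds this. Default 0.95.
#' @param drop_sqrt_prob Arm-dropping threshold on the square root of the
#'   probability of being best. Default 0.01.
#' @param allocation_mode `"adaptive"` (square-root-probability response-
#'   adaptive randomization) or `"fixed_111"` (constant 1:1:1, no dropping;
#'   early stopping still applies).
#' @param design_f Fractional additivity assumed when sizing the trial.
#'   Defaults to `f_true`; set higher for deliberately optimistic designs
#'   (see [design_effect_for_weak_scenarios()]).
#' @return An object of class `fa_scenario` (a named list).
#' @seealso [scenario_truth()], [run_trial()], [read_scenario()]
#' @examples
#' sc <- scenario_config(p_fail_A = 0.35, p_fail_B = 0.40, f_true = 0.75)
#' scenario_truth(sc)
#' @export
scenario_config <- function(p_fail_A, p_fail_B, f_true,
                            sigma2 = 0.16,
                            prior_mean_f = f_true,
                            prior_var_f = 0.16,
                            alpha = 0.05,
                            power = 0.80,
                            n_looks = 4,
                            stop_prob = 0.95,
                            drop_sqrt_prob = 0.01,
                            allocation_mode = c("adaptive", "fixed_111"),
                            design_f = f_true) {
  allocation_mode <- match.arg(allocation_mode)
  stopifnot(
    is.numeric(p_fail_A), p_fail_A > 0, p_fail_A < 1,
    is.numeric(p_fail_B), p_fail_B > 0, p_fail_B < 1,
    is.numeric(f_true), is.finite(f_true),
    sigma2 >= 0, prior_var_f > 0,
    alpha > 0, alpha < 1, power > 0, power < 1,
    n_looks >= 1, n_looks == as.integer(n_looks),
    stop_prob > 0, stop_prob < 1,
    drop_sqrt_prob > 0, drop_sqrt_prob < 1
  )
  structure(
    list(
      p_fail_A = p_fail_A, p_fail_B = p_fail_B, f_true = f_true,
      sigma2 = sigma2, prior_mean_f = prior_mean_f,
      prior_var_f = prior_var_f, alpha = alpha, power = power,
      n_looks = as.integer(n_looks), stop_prob = stop_prob,
      drop_sqrt_prob = drop_sqrt_prob, allocation_mode = allocation_mode,
      design_f = design_f
    ),
    class = "fa_scenario"
  )
}

#' @export
print.fa_scenario <- function(x, ...) {
  cat("<fa_scenario>\n")
  cat(sprintf("  failure probs:  A %.3f, B %.3f; true f = %.2f, sigma2 = %.2f\n",
              x$p_fail_A, x$p_fail_B, x$f_true, x$sigma2))
  cat(sprintf("  prior on f:     N(%.2f, var %.2f)\n", x$prior_mean_f, x$prior_var_f))
  cat(sprintf("  design:         alpha %.2f, power %.2f, design f %.2f, %d interim looks\n",
              x$alpha, x$power, x$design_f, x$n_looks))
  cat(sprintf("  adaptation:     stop if p_best > %.2f, drop if sqrt(p_best) < %.2g, mode %s\n",
              x$stop_prob, x$drop_sqrt_prob, x$allocation_mode))
  invisible(x)
}

#' Ground-truth effects implied by a scenario
#'
#' Converts a scenario's failure probabilities and fractional additivity to
#' the true log-odds (of response) used by the simulator, deriving the
#' combination arm via [combination_log_odds()].
#'
#' @param config An `fa_scenario` from [scenario_config()].
#' @return An object of class `fa_truth`: a list with `theta_A`, `theta_B`,
#'   `theta_AB`, `f`, and `sigma2`.
#' @export
scenario_truth <- function(config) {
  stopifnot(inherits(config, "fa_scenario"))
  theta_A <- logit(1 - config$p_fail_A)
  theta_B <- logit(1 - config$p_fail_B)
  structure(
    list(
      theta_A = theta_A,
      theta_B = theta_B,
      theta_AB = combination_log_odds(theta_A, theta_B, config$f_true),
      f = config$f_true,
      sigma2 = config$sigma2
    ),
    class = "fa_truth"
  )
}

#' @export
print.fa_truth <- function(x, ...) {
  cat("<fa_truth>\n")
  cat(sprintf("  theta_A  = %.4f  (failure %.4f)\n", x$theta_A, 1 - expit(x$theta_A)))
  cat(sprintf("  theta_B  = %.4f  (failure %.4f)\n", x$theta_B, 1 - expit(x$theta_B)))
  cat(sprintf("  theta_AB = %.4f  (failure %.4f), f = %.2f, sigma2 = %.2f\n",
              x$theta_AB, 1 - expit(x$theta_AB), x$f, x$sigma2))
  invisible(x)
}

#' Read or write a scenario configuration file
#'
#' Scenarios serialise as a flat key-value YAML file with keys `p_fail_A`,
#' `p_fail_B`, `f_true`, `sigma2`, `prior_mean_f`, `prior_var_f`, `alpha`,
#' `power`, `n_looks`, `stop_prob`, `drop_sqrt_prob`, `allocation_mode`
#' (and optionally `design_f`).
#'
#' @param path File path.
#' @param config An `fa_scenario`.
#' @return `read_scenario()` returns an `fa_scenario`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(scenario_config, vals)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "fa_scenario"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
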