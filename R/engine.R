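#' Square-root probability-of-superiority allocation
#'
#' Updates allocation proportions to the ratio of the square roots of the
#' posterior probabilities of being best (the square root damps adaptation
#' relative to raw probabilities). Dropped arms receive zero.
#'
#' @param probs One-row tibble from [prob_best()].
#' @param active_arms Character vector of arms still enrolling (subset of
#'   `c("A", "B", "AB")`).
#' @return Named numeric allocation vector over A, B, AB, summing to 1.
#' @examples
#' update_allocation(tibble::tibble(
#'   p_A_best = 0.04, p_B_best = 0.32, p_AB_best = 0.64))
#' @export
update_allocation <- function(probs, active_arms = ARMS) {
  p <- c(A = probs$p_A_best, B = probs$p_B_best, AB = probs$p_AB_best)
  stopifnot(all(active_arms %in% ARMS), length(active_arms) >= 1)
  w <- setNames(numeric(3), ARMS)
  w[active_arms] <- sqrt(p[active_arms])
  if (sum(w) == 0) abort("all active arms have zero probability of being best.")
  w / sum(w)
}

#' Drop inferior arms
#'
#' An arm is dropped from enrolment when the square root of its posterior
#' probability of being best falls below `drop_sqrt_prob` (equivalently, the
#' probability itself falls below `drop_sqrt_prob^2`). Dropped arms never
#' re-enter enrolment, but their accumulated data stay in every subsequent
#' posterior and superiority comparison. The currently most probable arm is
#' never dropped.
#'
#' @inheritParams update_allocation
#' @param drop_sqrt_prob Threshold on `sqrt(p_best)` (default 0.01).
#' @return Updated character vector of active arms (never empty).
#' @export
apply_drop_rule <- function(probs, active_arms = ARMS, drop_sqrt_prob = 0.01) {
  stopifnot(drop_sqrt_prob > 0, drop_sqrt_prob < 1)
  p <- c(A = probs$p_A_best, B = probs$p_B_best, AB = probs$p_AB_best)
  keep <- active_arms[sqrt(p[active_arms]) >= drop_sqrt_prob]
  # the most probable active arm is never dropped
  if (length(keep) == 0) keep <- active_arms[which.max(p[active_arms])]
  keep
}

#' Early-stopping rule
#'
#' The trial stops for superiority when some arm's posterior probability of
#' being best strictly exceeds `stop_prob`.
#'
#' @inheritParams update_allocation
#' @param stop_prob Stopping threshold (default 0.95); strict inequality.
#' @return A list with `stop` (logical) and `winner` (arm label or `NA`).
#' @export
check_stop <- function(probs, stop_prob = 0.95) {
  p <- c(A = probs$p_A_best, B = probs$p_B_best, AB = probs$p_AB_best)
  if (max(p) > stop_prob) {
    list(stop = TRUE, winner = ARMS[which.max(p)])
  } else {
    list(stop = FALSE, winner = NA_character_)
  }
}

#' Run one response-adaptive randomized trial
#'
#' Simulates a full three-arm trial under the scenario's truth, analysed at
#' each look with the given model. Enrolment starts 1:1:1; at each interim
#' look the posterior is fitted to the accumulated counts and, in order, the
#' look is recorded, the stopping rule is checked, inferior arms are dropped,
#' and the allocation is updated from the square-root probabilities. At the
#' final look estimates are recorded without further enrolment; the arm with
#' the highest probability of being best is recorded as the (non-binding)
#' final winner. With `allocation_mode = "fixed_111"` the allocation stays
#' 1:1:1 and no arms are dropped, but early stopping still applies.
#'
#' The whole trial (enrolment, outcomes, sampler) consumes a single RNG
#' stream seeded at entry, so one seed fully determines the result.
#'
#' @param scenario An `fa_scenario`.
#' @param spec An `fa_model`.
#' @param schedule An `fa_schedule`; defaults to the scenario's fixed-design
#'   schedule via [build_schedule()].
#' @param seed Integer seed.
#' @param n_draws,warmup,thin Passed to [sample_posterior()].
#' @return An object of class `fa_trial`; see [tidy.fa_trial()] for the
#'   per-look records and [glance.fa_trial()] for the one-row summary.
#' @examples
#' \donttest{
#' sc <- scenario_config(0.35, 0.40, f_true = 1)
#' tr <- run_trial(sc, model_spec("fractional", prior_mean_f = 1), seed = 1)
#' glance(tr)
#' }
#' @export
run_trial <- function(scenario, spec, schedule = NULL, seed = 1,
                      n_draws = 4000, warmup = 1000, thin = 5) {
  stopifnot(inherits(scenario, "fa_scenario"), inherits(spec, "fa_model"))
  if (is.null(schedule)) schedule <- schedule_for_scenario(scenario)
  stopifnot(inherits(schedule, "fa_schedule"))
  set.seed(seed)

  truth <- scenario_truth(scenario)
  counts <- arm_counts()
  allocation <- setNames(rep(1 / 3, 3), ARMS)
  active <- ARMS
  fixed <- scenario$allocation_mode == "fixed_111"
  targets <- schedule$look_targets
  n_looks_total <- length(targets)

  looks <- vector("list", n_looks_total)
  termination_look <- n_looks_total
  termination_reason <- "max_n_reached"
  winner <- NA_character_
  sampler_flags <- 0L

  for (k in seq_len(n_looks_total)) {
    n_new <- targets[k] - sum(counts$n_enrolled)
    batch <- simulate_batch(n_new, allocation, truth, counts)
    counts <- batch$counts

    fit <- sample_posterior(spec, counts, n_draws = n_draws,
                            warmup = warmup, thin = thin)
    if (!isTRUE(fit$diagnostics$converged)) sampler_flags <- sampler_flags + 1L
    probs <- prob_best(fit)
    means <- colMeans(fit$draws, na.rm = TRUE)
    final <- k == n_looks_total
    dec <- check_stop(probs, scenario$stop_prob)

    cv <- as_counts_vectors(counts)
    looks[[k]] <- list(
      look = k, target = targets[k],
      n_A = cv$n[["A"]], y_A = cv$y[["A"]],
      n_B = cv$n[["B"]], y_B = cv$y[["B"]],
      n_AB = cv$n[["AB"]], y_AB = cv$y[["AB"]],
      alloc_A = allocation[["A"]], alloc_B = allocation[["B"]],
      alloc_AB = allocation[["AB"]],
      p_A_best = probs$p_A_best, p_B_best = probs$p_B_best,
      p_AB_best = probs$p_AB_best,
      mean_theta_A = means[["theta_A"]], mean_theta_B = means[["theta_B"]],
      mean_theta_AB = means[["theta_AB"]],
      mean_f = if (spec$kind == "fractional") means[["f"]] else NA_real_,
      active = paste(active, collapse = ","),
      sampler_converged = fit$diagnostics$converged,
      decision = if (final) "final" else if (dec$stop) "stop" else "continue"
    )

    if (final) {
      p <- c(probs$p_A_best, probs$p_B_best, probs$p_AB_best)
      winner <- ARMS[which.max(p)]
      break
    }
    if (dec$stop) {
      termination_look <- k
      termination_reason <- "early_superiority"
      winner <- dec$winner
      break
    }
    if (!fixed) {
      active <- apply_drop_rule(probs, active, scenario$drop_sqrt_prob)
      allocation <- update_allocation(probs, active)
    }
  }

  looks_tbl <- dplyr::bind_rows(lapply(looks[!vapply(looks, is.null, logical(1))],
                                       as_tibble))
  total_enrolled <- sum(counts$n_enrolled)
  total_failures <- total_enrolled - sum(counts$n_responses)

  structure(
    list(
      looks = looks_tbl,
      termination_look = termination_look,
      termination_reason = termination_reason,
      winner = winner,
      total_enrolled = total_enrolled,
      total_failures = total_failures,
      sampler_flags = sampler_flags,
      scenario = scenario, spec = spec, schedule = schedule, seed = seed
    ),
    class = "fa_trial"
  )
}

#' @export
print.fa_trial <- function(x, ...) {
  cat("<fa_trial>", x$spec$kind, "model;",
      sprintf("terminated at look %d (%s), winner %s\n",
              x$termination_look, x$termination_reason, x$winner))
  cat(sprintf("  enrolled %d of max %d; %d failures (%.3f)\n",
              x$total_enrolled, x$schedule$total_max_n, x$total_failures,
              x$total_failures / x$total_enrolled))
  invisible(x)
}

#' Tidy a simulated trial: one row per analysis look
#'
#' Columns: cumulative per-arm counts (`n_*`, `y_*`), the allocation in force
#' while enrolling up to that look (`alloc_*`), posterior probabilities of
#' being best (`p_*_best`), posterior means, the active-arm set, and the
#' decision taken.
#'
#' @param x An `fa_trial`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fa_trial <- function(x, ...) x$looks

#' One-row summary of a simulated trial
#'
#' @param x An `fa_trial`.
#' @param ... Unused.
#' @return A tibble with the termination look and reason, winner, total
#'   enrolment, failures, and failure proportion.
#' @export
glance.fa_trial <- function(x, ...) {
  tibble(
    model = x$spec$kind,
    termination_look = x$termination_look,
    termination_reason = x$termination_reason,
    winner = x$winner,
    total_enrolled = x$total_enrolled,
    total_failures = x$total_failures,
    failure_proportion = x$total_failures / x$total_enrolled,
    sampler_flags = x$sampler_flags,
    seed = x$seed
  )
}

#' Plot the posterior-superiority trajectory of one trial
#'
#' Probabilities that each arm is best, by interim look, with the stopping
#' threshold drawn as a dashed line.
#'
#' @param object An `fa_trial`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fa_trial <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::select("look", "p_A_best", "p_B_best", "p_AB_best") |>
    tidyr::pivot_longer(-"look", names_to = "arm", values_to = "p_best") |>
    dplyr::mutate(arm = sub("^p_(.*)_best$", "\\1", .data$arm))
  ggplot2::ggplot(d, ggplot2::aes(.data$look, .data$p_best, colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$scenario$stop_prob,
                        linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "interim look", y = "Pr(arm is best)",
                  colour = "arm",
                  title = sprintf("%s model, terminated at look %d",
                                  object$spec$kind, object$termination_look))
}
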