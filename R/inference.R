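#' Analysis-model specification
#'
#' The three competing analysis models for a three-arm combination trial:
#'
#' * `"fractional"` — logistic model with the combination effect linked to the
#'   single agents through [combination_log_odds()]; the fractional-additivity
#'   coefficient `f` gets a weakly informative normal prior (variance 0.16 by
#'   default), the free thetas get diffuse normal priors.
#' * `"conventional"` — the combination arm is treated as an unrelated third
#'   treatment with its own independent effect parameter.
#' * `"full_additivity"` — the combination effect is constrained to the sum of
#'   the single-agent effects (the `f = 1` degenerate case).
#'
#' @param kind Model kind; see above.
#' @param prior_mean_f Prior mean for `f` (fractional model only; required
#'   there).
#' @param prior_var_f Prior variance for `f` (> 0). Default 0.16.
#' @param prior_sd_theta Prior standard deviation of each free theta
#'   parameter; diffuse by default (10) so it is effectively flat over
#'   plausible log-odds yet proper at zero-data looks.
#' @return An object of class `fa_model`.
#' @examples
#' model_spec("fractional", prior_mean_f = 0.75)
#' model_spec("conventional")
#' @export
model_spec <- function(kind = c("fractional", "conventional", "full_additivity"),
                       prior_mean_f = NULL,
                       prior_var_f = 0.16,
                       prior_sd_theta = 10) {
  kind <- match.arg(kind)
  stopifnot(prior_var_f > 0, prior_sd_theta > 0)
  if (kind == "fractional") {
    if (is.null(prior_mean_f) || !is.finite(prior_mean_f)) {
      abort("the fractional model requires a finite `prior_mean_f`.")
    }
  } else {
    if (!is.null(prior_mean_f)) {
      abort(sprintf("`prior_mean_f` has no meaning for the %s model.", kind))
    }
    prior_mean_f <- NA_real_
  }
  structure(
    list(kind = kind, prior_mean_f = prior_mean_f,
         prior_var_f = prior_var_f, prior_sd_theta = prior_sd_theta),
    class = "fa_model"
  )
}

#' @export
print.fa_model <- function(x, ...) {
  cat("<fa_model>", x$kind, "\n")
  if (x$kind == "fractional") {
    cat(sprintf("  f ~ N(%.3f, var %.3f)\n", x$prior_mean_f, x$prior_var_f))
  }
  cat(sprintf("  free thetas ~ N(0, sd %.1f)\n", x$prior_sd_theta))
  invisible(x)
}

model_dim <- function(spec) if (spec$kind == "full_additivity") 2L else 3L

model_kind_code <- function(spec) {
  switch(spec$kind, fractional = 1L, conventional = 2L, full_additivity = 3L)
}

#' Log posterior density on binomial sufficient statistics
#'
#' Log prior plus log binomial likelihood for one analysis model. Arm X with
#' `n` enrolled and `y` responses contributes
#' `y * log(expit(theta_X)) + (n - y) * log(1 - expit(theta_X))`, with the
#' combination arm's theta given by the model's linkage. Normal log-prior
#' densities include their normalising constants; the binomial coefficient is
#' omitted (constant in the parameters).
#'
#' @param spec An `fa_model`.
#' @param params Numeric parameter vector: `(theta_A, theta_B, f)` for
#'   fractional, `(theta_A, theta_B, theta_AB)` for conventional,
#'   `(theta_A, theta_B)` for full additivity.
#' @param counts Counts tibble as from [arm_counts()].
#' @return Scalar log density (unnormalised posterior).
#' @export
log_posterior <- function(spec, params, counts) {
  stopifnot(inherits(spec, "fa_model"))
  if (length(params) != model_dim(spec)) {
    abort(sprintf("`params` must have length %d for the %s model.",
                  model_dim(spec), spec$kind))
  }
  cv <- as_counts_vectors(counts)
  theta_A <- params[1]; theta_B <- params[2]
  lp <- dnorm(theta_A, 0, spec$prior_sd_theta, log = TRUE) +
    dnorm(theta_B, 0, spec$prior_sd_theta, log = TRUE)
  theta_AB <- switch(
    spec$kind,
    fractional = {
      f <- params[3]
      lp <- lp + dnorm(f, spec$prior_mean_f, sqrt(spec$prior_var_f), log = TRUE)
      combination_log_odds(theta_A, theta_B, f)
    },
    conventional = {
      lp <- lp + dnorm(params[3], 0, spec$prior_sd_theta, log = TRUE)
      params[3]
    },
    full_additivity = theta_A + theta_B
  )
  th <- c(theta_A, theta_B, theta_AB)
  loglik <- sum(cv$y * th - cv$n * log1p(exp(-abs(th))) -
                  cv$n * pmax(th, 0))
  lp + loglik
}

empirical_logit <- function(y, n) qlogis((y + 0.5) / (n + 1))

empirical_logit_se <- function(y, n) sqrt(1 / (y + 0.5) + 1 / (n - y + 0.5))

#' Draw from the posterior of an analysis model
#'
#' Samples the 2-3 free parameters with an adaptive random-walk Metropolis
#' sampler operating on the binomial sufficient statistics (implemented in
#' C++; fast enough for thousands of interim-look fits). Step sizes are
#' initialised from empirical-logit standard errors and tuned during warmup.
#' Thinning keeps autocorrelation low so that Monte-Carlo error on the
#' probabilities of superiority is well below the adaptation thresholds.
#'
#' @param spec An `fa_model`.
#' @param counts Counts tibble as from [arm_counts()].
#' @param n_draws Number of retained draws (default 4000).
#' @param warmup Warmup (adaptation) iterations, discarded (default 1000).
#' @param thin Keep every `thin`-th post-warmup iteration (default 5).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   consumed (used inside [run_trial()], which seeds once per trial).
#' @return An object of class `fa_draws`: a list with `draws` (tibble with
#'   columns `theta_A`, `theta_B`, `theta_AB`, `f`; `f` is `NA` except under
#'   the fractional model), `spec`, and `diagnostics` (acceptance rate,
#'   split-half convergence statistic per parameter, `converged` flag).
#'   Non-convergence is flagged, never silent.
#' @export
sample_posterior <- function(spec, counts, n_draws = 4000, warmup = 1000,
                             thin = 5, seed = NULL) {
  stopifnot(inherits(spec, "fa_model"), n_draws >= 2, warmup >= 0, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  cv <- as_counts_vectors(counts)
  n <- cv$n; y <- cv$y

  el <- empirical_logit(y, n)
  se <- empirical_logit_se(y, n)
  # zero-data arms: fall back to the prior's scale
  el[n == 0] <- 0
  se <- pmin(se, spec$prior_sd_theta)

  kind <- model_kind_code(spec)
  if (spec$kind == "fractional") {
    init <- c(el[1], el[2], spec$prior_mean_f)
    step <- c(se[1], se[2], min(sqrt(spec$prior_var_f), 2))
  } else if (spec$kind == "conventional") {
    init <- c(el[1], el[2], el[3])
    step <- c(se[1], se[2], se[3])
  } else {
    init <- c(el[1], el[2])
    step <- c(se[1], se[2])
  }
  step <- step * 2.4 / sqrt(length(step))

  fit <- rwm_sample(kind, n, y,
                    ifelse(is.na(spec$prior_mean_f), 0, spec$prior_mean_f),
                    spec$prior_var_f, spec$prior_sd_theta,
                    init, step, as.integer(warmup), as.integer(n_draws),
                    as.integer(thin))
  m <- fit$draws
  theta_A <- m[, 1]; theta_B <- m[, 2]
  if (spec$kind == "fractional") {
    f <- m[, 3]
    theta_AB <- combination_log_odds(theta_A, theta_B, f)
  } else if (spec$kind == "conventional") {
    f <- rep(NA_real_, nrow(m))
    theta_AB <- m[, 3]
  } else {
    f <- rep(NA_real_, nrow(m))
    theta_AB <- theta_A + theta_B
  }
  draws <- tibble(theta_A = theta_A, theta_B = theta_B,
                  theta_AB = theta_AB, f = f)

  free <- m
  half <- nrow(free) %/% 2
  split_stat <- vapply(seq_len(ncol(free)), function(j) {
    a <- free[seq_len(half), j]; b <- free[(half + 1):nrow(free), j]
    pooled <- stats::sd(free[, j])
    if (pooled == 0) return(1)
    1 + abs(mean(a) - mean(b)) / pooled
  }, numeric(1))
  diagnostics <- list(
    n_draws = nrow(draws),
    acceptance_rate = fit$acceptance_rate,
    split_stat = split_stat,
    converged = all(split_stat < 1.2) &&
      fit$acceptance_rate > 0.05 && fit$acceptance_rate < 0.8
  )
  structure(list(draws = draws, spec = spec, diagnostics = diagnostics),
            class = "fa_draws")
}

#' @export
print.fa_draws <- function(x, ...) {
  cat("<fa_draws>", x$spec$kind, "model,", x$diagnostics$n_draws, "draws;",
      sprintf("acceptance %.2f%s\n", x$diagnostics$acceptance_rate,
              if (isTRUE(x$diagnostics$converged)) "" else " [convergence flagged]"))
  print(posterior_summary(x))
  invisible(x)
}

#' @describeIn sample_posterior Tidy the draws: one row per posterior draw.
#' @param x An `fa_draws` object.
#' @param ... Unused.
#' @export
tidy.fa_draws <- function(x, ...) x$draws

#' @describeIn sample_posterior One-row diagnostics summary.
#' @export
glance.fa_draws <- function(x, ...) {
  tibble(kind = x$spec$kind,
         n_draws = x$diagnostics$n_draws,
         acceptance_rate = x$diagnostics$acceptance_rate,
         max_split_stat = max(x$diagnostics$split_stat),
         converged = x$diagnostics$converged)
}

#' Posterior means and central credible intervals
#'
#' @param draws An `fa_draws` object (or bare draws tibble).
#' @param level Credible level (default 0.95).
#' @return A tibble with columns `parameter`, `mean`, `lower`, `upper`.
#' @export
posterior_summary <- function(draws, level = 0.95) {
  d <- if (inherits(draws, "fa_draws")) draws$draws else as_tibble(draws)
  if (nrow(d) == 0) abort("`draws` is empty.")
  a <- (1 - level) / 2
  purrr::map_dfr(names(d), function(p) {
    v <- d[[p]]
    if (all(is.na(v))) return(NULL)
    tibble(parameter = p, mean = mean(v),
           lower = unname(quantile(v, a)), upper = unname(quantile(v, 1 - a)))
  })
}

#' Posterior probabilities of being the best arm
#'
#' The probability that each arm's response log-odds strictly exceeds both
#' other arms', estimated as the fraction of posterior draws in which it does.
#' All three arms always enter the comparison, including arms dropped from
#' enrolment (their accumulated data remain in the posterior). Exact ties
#' within a draw are broken uniformly at random (measure zero for continuous
#' samplers).
#'
#' @param draws An `fa_draws` object or a tibble/data frame with columns
#'   `theta_A`, `theta_B`, `theta_AB`.
#' @return A one-row tibble with columns `p_A_best`, `p_B_best`, `p_AB_best`,
#'   summing to 1 within `1 / n_draws`.
#' @export
prob_best <- function(draws) {
  d <- if (inherits(draws, "fa_draws")) draws$draws else as_tibble(draws)
  if (nrow(d) == 0) abort("`draws` is empty.")
  m <- cbind(d$theta_A, d$theta_B, d$theta_AB)
  best <- max.col(m, ties.method = "random")
  tab <- tabulate(best, 3L) / nrow(m)
  tibble(p_A_best = tab[1], p_B_best = tab[2], p_AB_best = tab[3])
}
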