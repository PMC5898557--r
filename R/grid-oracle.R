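#' Brute-force grid posterior (verification oracle)
#'
#' Tabulates the unnormalised posterior on a bounded lattice over the model's
#' 2-3 free parameters, normalises it, and computes posterior probabilities of
#' superiority and posterior means by direct summation. Intended purely as an
#' independent check of the Metropolis sampler on modest counts; it shares no
#' code path with [sample_posterior()] beyond [log_posterior()]'s definition
#' of the target density.
#'
#' Grid bounds are set from empirical-logit estimates plus a wide multiple of
#' their standard errors (and, for `f`, the prior). If more than 1e-4 of the
#' normalised mass sits on the outermost grid slices a warning is issued.
#'
#' @param spec An `fa_model`.
#' @param counts Counts tibble as from [arm_counts()]; keep counts modest
#'   (the lattice is cubic in the resolution).
#' @param n_grid Lattice points per dimension; defaults to 601 for the
#'   two-parameter (full-additivity) model and 201 for the three-parameter
#'   models, keeping the discretisation error at the superiority decision
#'   boundary well below the sampler's Monte-Carlo error.
#' @param expand Half-width of each axis in standard-error units (default 7).
#' @return A list with `p_best` (one-row tibble as from [prob_best()]),
#'   `means` (named numeric: posterior means of `theta_A`, `theta_B`,
#'   `theta_AB`, and `f` for the fractional model), and `boundary_mass`.
#' @export
grid_posterior_oracle <- function(spec, counts, n_grid = NULL, expand = 7) {
  stopifnot(inherits(spec, "fa_model"))
  if (is.null(n_grid)) {
    n_grid <- if (spec$kind == "full_additivity") 601 else 201
  }
  stopifnot(n_grid >= 11)
  cv <- as_counts_vectors(counts)
  n <- cv$n; y <- cv$y
  el <- empirical_logit(y, n)
  se <- pmin(empirical_logit_se(y, n), spec$prior_sd_theta / 2)
  el[n == 0] <- 0

  axis <- function(center, half) seq(center - half, center + half, length.out = n_grid)
  g_A <- axis(el[1], expand * se[1])
  g_B <- axis(el[2], expand * se[2])

  v_theta <- spec$prior_sd_theta^2
  binom_ll <- function(theta, nn, yy) {
    yy * theta - nn * (log1p(exp(-abs(theta))) + pmax(theta, 0))
  }
  lp_A <- binom_ll(g_A, n[1], y[1]) - 0.5 * g_A^2 / v_theta
  lp_B <- binom_ll(g_B, n[2], y[2]) - 0.5 * g_B^2 / v_theta

  if (spec$kind == "fractional") {
    sd_f <- sqrt(spec$prior_var_f)
    g_3 <- axis(spec$prior_mean_f, 6 * sd_f)
    lp_3 <- -0.5 * (g_3 - spec$prior_mean_f)^2 / spec$prior_var_f
  } else if (spec$kind == "conventional") {
    g_3 <- axis(el[3], expand * se[3])
    lp_3 <- -0.5 * g_3^2 / v_theta
  } else {
    g_3 <- NULL
  }

  if (spec$kind == "full_additivity") {
    gr <- expand.grid(theta_A = g_A, theta_B = g_B, KEEP.OUT.ATTRS = FALSE)
    lp <- outer(lp_A, lp_B, "+")
    theta_AB <- gr$theta_A + gr$theta_B
    lp <- as.vector(lp) + binom_ll(theta_AB, n[3], y[3])
    f_col <- NULL
    idx_edge <- with(gr, theta_A %in% g_A[c(1, n_grid)] |
                       theta_B %in% g_B[c(1, n_grid)])
  } else {
    gr <- expand.grid(theta_A = g_A, theta_B = g_B, par3 = g_3,
                      KEEP.OUT.ATTRS = FALSE)
    lp <- as.vector(outer(outer(lp_A, lp_B, "+"), lp_3, "+"))
    if (spec$kind == "fractional") {
      theta_AB <- combination_log_odds(gr$theta_A, gr$theta_B, gr$par3)
      f_col <- gr$par3
    } else {
      theta_AB <- gr$par3
      f_col <- NULL
    }
    lp <- lp + binom_ll(theta_AB, n[3], y[3])
    idx_edge <- with(gr, theta_A %in% g_A[c(1, n_grid)] |
                       theta_B %in% g_B[c(1, n_grid)] |
                       par3 %in% g_3[c(1, n_grid)])
  }

  w <- exp(lp - max(lp))
  post <- w / sum(w)
  boundary_mass <- sum(post[idx_edge])
  if (boundary_mass > 1e-4) {
    warning(sprintf(
      "grid truncates %.2g of posterior mass at its boundary; widen `expand`",
      boundary_mass))
  }

  m <- cbind(gr$theta_A, gr$theta_B, theta_AB)
  best <- max.col(m, ties.method = "first")
  ties <- (m[, 1] == m[, 2]) | (m[, 1] == m[, 3]) | (m[, 2] == m[, 3])
  p <- vapply(1:3, function(j) sum(post[best == j & !ties]), numeric(1))
  # split any tied mass evenly among the tied maximal arms
  if (any(ties)) {
    for (i in which(ties & post > 0)) {
      mx <- max(m[i, ])
      winners <- which(m[i, ] == mx)
      p[winners] <- p[winners] + post[i] / length(winners)
    }
  }

  means <- c(theta_A = sum(post * gr$theta_A),
             theta_B = sum(post * gr$theta_B),
             theta_AB = sum(post * theta_AB))
  if (!is.null(f_col)) means <- c(means, f = sum(post * f_col))

  list(
    p_best = tibble(p_A_best = p[1], p_B_best = p[2], p_AB_best = p[3]),
    means = means,
    boundary_mass = boundary_mass
  )
}
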