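test_that("log_posterior reduces to the prior with no data and adds exact binomial terms", {
  empty <- make_counts(c(0, 0, 0), c(0, 0, 0))
  spec <- model_spec("fractional", prior_mean_f = 0.5)
  params <- c(0.3, -0.2, 0.7)
  prior_only <- dnorm(0.3, 0, 10, log = TRUE) + dnorm(-0.2, 0, 10, log = TRUE) +
    dnorm(0.7, 0.5, 0.4, log = TRUE)
  expect_equal(log_posterior(spec, params, empty), prior_only)

  # combination-arm likelihood uses the linked theta: 100 enrolled, 74 responses
  cts <- make_counts(c(0, 0, 100), c(0, 0, 74))
  params2 <- c(0.61904, 0.405465, 1)
  p_ab <- plogis(combination_log_odds(0.61904, 0.405465, 1))  # 0.73585
  lik <- 74 * log(p_ab) + 26 * log(1 - p_ab)
  prior2 <- dnorm(0.61904, 0, 10, log = TRUE) +
    dnorm(0.405465, 0, 10, log = TRUE) + dnorm(1, 0.5, 0.4, log = TRUE)
  expect_equal(log_posterior(spec, params2, cts), prior2 + lik, tolerance = 1e-10)

  expect_error(log_posterior(spec, c(1, 2), empty), "length 3")
  expect_error(log_posterior(model_spec("full_additivity"), c(1, 2, 3), empty),
               "length 2")
})

test_that("adding successes to an arm shifts its conditional maximizer upward", {
  spec <- model_spec("conventional")
  before <- make_counts(c(40, 50, 50), c(20, 30, 30))
  after <- make_counts(c(50, 50, 50), c(30, 30, 30))  # +10 enrolled, +10 responses on A
  argmax_A <- function(cts) {
    stats::optimize(function(tA) log_posterior(spec, c(tA, 0.4, 0.4), cts),
                    c(-5, 5), maximum = TRUE)$maximum
  }
  expect_gt(argmax_A(after), argmax_A(before))
})

test_that("zero-data posteriors recover their priors", {
  empty <- make_counts(c(0, 0, 0), c(0, 0, 0))
  spec <- model_spec("fractional", prior_mean_f = 0.75)
  d <- sample_posterior(spec, empty, seed = 5)
  expect_equal(mean(d$draws$f), 0.75, tolerance = 0.02 / 0.75)
  expect_equal(var(d$draws$f), 0.16, tolerance = 0.01 / 0.16)
  s <- posterior_summary(d)
  expect_equal(s$mean[s$parameter == "f"], mean(d$draws$f))
})

test_that("single-arm posterior agrees with the conjugate beta oracle", {
  cts <- make_counts(c(1000, 0, 0), c(650, 0, 0))
  d <- sample_posterior(model_spec("conventional"), cts, seed = 6)
  # Beta(650.5, 350.5) posterior mean under a flat-on-probability prior;
  # tolerance absorbs the (diffuse-normal-on-logit) prior difference
  expect_equal(mean(plogis(d$draws$theta_A)), 0.650, tolerance = 0.005 / 0.650)
})

test_that("prob_best is the counting definition with exact normalization", {
  d <- tibble::tibble(theta_A = rep(0, 4000), theta_B = rep(0.1, 4000),
                      theta_AB = rep(1, 4000))
  expect_equal(prob_best(d), tibble::tibble(p_A_best = 0, p_B_best = 0,
                                            p_AB_best = 1))
  d2 <- tibble::tibble(
    theta_A = c(rep(2, 200), rep(0, 3800)),
    theta_B = rep(0.5, 4000),
    theta_AB = c(rep(0, 200), rep(1, 3800))
  )
  expect_equal(prob_best(d2)$p_AB_best, 0.95)
  # exchangeable draws: each arm best ~1/3
  set.seed(7)
  m <- matrix(rnorm(3 * 30000), ncol = 3)
  d3 <- tibble::tibble(theta_A = m[, 1], theta_B = m[, 2], theta_AB = m[, 3])
  pb <- prob_best(d3)
  expect_true(all(abs(unlist(pb) - 1 / 3) < 0.01))
  expect_equal(sum(unlist(pb)), 1)
})

test_that("posterior_summary handles constant and empty draws", {
  d <- tibble::tibble(theta_A = rep(1.5, 100), theta_B = rep(0, 100),
                      theta_AB = rep(1.5, 100), f = rep(NA_real_, 100))
  s <- posterior_summary(d)
  expect_equal(s$mean[s$parameter == "theta_A"], 1.5)
  expect_equal(s$lower, s$upper)
  expect_false("f" %in% s$parameter)  # all-NA columns are skipped
  expect_error(posterior_summary(d[0, ]), "empty")
})

test_that("fractional model recovers f from its own generative process", {
  sc <- scenario_config(0.40, 0.40, f_true = 0.5, sigma2 = 0)
  truth <- scenario_truth(sc)
  set.seed(8)
  n <- 5000
  y <- rbinom(3, n, plogis(c(truth$theta_A, truth$theta_B, truth$theta_AB)))
  cts <- make_counts(rep(n, 3), y)
  d <- sample_posterior(model_spec("fractional", prior_mean_f = 0.5), cts,
                        seed = 9)
  expect_lt(abs(mean(d$draws$f) - 0.5), 0.1)
  expect_lt(abs(mean(d$draws$theta_A) - truth$theta_A), 0.1)
})

test_that("posterior-mean error shrinks with sample size (asymptotic unbiasedness)", {
  sc <- scenario_config(0.35, 0.40, f_true = 0.75, sigma2 = 0)
  truth <- scenario_truth(sc)
  spec <- model_spec("fractional", prior_mean_f = 0.75)
  err <- vapply(c(200, 2000, 20000), function(n) {
    set.seed(n)
    y <- rbinom(3, n, plogis(c(truth$theta_A, truth$theta_B, truth$theta_AB)))
    d <- sample_posterior(spec, make_counts(rep(n, 3), y), seed = n + 1)
    max(abs(c(mean(d$draws$theta_A) - truth$theta_A,
              mean(d$draws$theta_B) - truth$theta_B,
              mean(d$draws$f) - truth$f)))
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.05)
})

test_that("fractional model with a degenerate f prior at 1 nests full additivity", {
  cts <- make_counts(c(80, 90, 85), c(45, 50, 60))
  d_full <- sample_posterior(model_spec("full_additivity"), cts, seed = 10,
                             n_draws = 8000, thin = 10)
  d_frac <- sample_posterior(
    model_spec("fractional", prior_mean_f = 1, prior_var_f = 1e-6), cts,
    seed = 11, n_draws = 8000, thin = 10)
  expect_true(all(abs(d_frac$draws$f - 1) < 0.01))
  p_full <- unlist(prob_best(d_full))
  p_frac <- unlist(prob_best(d_frac))
  expect_true(all(abs(p_full - p_frac) < 0.03))
})

test_that("sampling is deterministic given a seed and flags diagnostics", {
  cts <- make_counts(c(50, 50, 50), c(30, 28, 40))
  spec <- model_spec("fractional", prior_mean_f = 0.75)
  a <- sample_posterior(spec, cts, seed = 12)
  b <- sample_posterior(spec, cts, seed = 12)
  expect_identical(a$draws, b$draws)
  g <- glance(a)
  expect_true(g$acceptance_rate > 0.05 && g$acceptance_rate < 0.8)
  expect_true(g$converged)
  expect_identical(tidy(a), a$draws)
  # fractional draws satisfy the linkage invariant row-wise, exactly
  expect_identical(a$draws$theta_AB,
                   combination_log_odds(a$draws$theta_A, a$draws$theta_B,
                                        a$draws$f))
})

test_that("model_spec rejects meaningless prior combinations", {
  expect_error(model_spec("conventional", prior_mean_f = 0.5), "no meaning")
  expect_error(model_spec("fractional"), "prior_mean_f")
  expect_error(model_spec("fractional", prior_mean_f = 0.5, prior_var_f = 0))
})
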