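probs_tbl <- function(a, b, ab) {
  tibble::tibble(p_A_best = a, p_B_best = b, p_AB_best = ab)
}

test_that("allocation follows the square-root-probability rule", {
  expect_equal(update_allocation(probs_tbl(1 / 3, 1 / 3, 1 / 3)),
               c(A = 1 / 3, B = 1 / 3, AB = 1 / 3))
  al <- update_allocation(probs_tbl(0.04, 0.32, 0.64))
  expect_equal(unname(al), c(0.12774, 0.36130, 0.51096), tolerance = 1e-4)
  expect_equal(sum(al), 1)
  al2 <- update_allocation(probs_tbl(0.04, 0.32, 0.64),
                           active_arms = c("B", "AB"))
  expect_equal(unname(al2), c(0, 0.41421, 0.58579), tolerance = 1e-4)
  expect_error(update_allocation(probs_tbl(0.5, 0.5, 0), active_arms = "AB"),
               "zero probability")
})

test_that("the drop rule thresholds on the square-root probability", {
  expect_identical(apply_drop_rule(probs_tbl(9e-5, 0.5, 0.49991)),
                   c("B", "AB"))
  expect_identical(apply_drop_rule(probs_tbl(1.1e-4, 0.5, 0.4999)),
                   c("A", "B", "AB"))
  expect_identical(apply_drop_rule(probs_tbl(1 / 3, 1 / 3, 1 / 3)),
                   c("A", "B", "AB"))
  # dropped arms never re-enter: engine passes only currently active arms
  expect_identical(apply_drop_rule(probs_tbl(0.4, 9e-5, 0.6),
                                   active_arms = c("B", "AB")), "AB")
})

test_that("the stop rule is a strict threshold and arm-agnostic", {
  expect_identical(check_stop(probs_tbl(0.02, 0.02, 0.96)),
                   list(stop = TRUE, winner = "AB"))
  expect_identical(check_stop(probs_tbl(0.02, 0.03, 0.95)),
                   list(stop = FALSE, winner = NA_character_))
  expect_identical(check_stop(probs_tbl(0.96, 0.02, 0.02)),
                   list(stop = TRUE, winner = "A"))
})

test_that("an overwhelmingly superior combination stops early with winner AB", {
  # combination failure ~0.05 against single agents at 0.40/0.40
  f_big <- (logit(0.95) - log(1.5)) / log(1.5)
  sc <- scenario_config(0.40, 0.40, f_true = f_big)
  sch <- build_schedule(60)
  res <- lapply(1:60, function(s) {
    run_trial(sc, model_spec("fractional", prior_mean_f = f_big), sch,
              seed = 4000 + s)
  })
  early_ab <- vapply(res, function(r) {
    r$termination_reason == "early_superiority" && r$winner == "AB"
  }, logical(1))
  expect_gte(mean(early_ab), 0.95)
})

test_that("identical arms give a small stop rate and a uniform winner", {
  sc <- scenario_config(0.40, 0.40, f_true = 0, sigma2 = 0)
  sch <- build_schedule(60)
  spec <- model_spec("conventional")
  res <- lapply(1:300, function(s) run_trial(sc, spec, sch, seed = 5000 + s))
  winners <- vapply(res, function(r) r$winner, character(1))
  early <- vapply(res, function(r)
    r$termination_reason == "early_superiority", logical(1))
  expect_lt(mean(early), 0.25)
  chi <- stats::chisq.test(table(factor(winners, levels = c("A", "B", "AB"))))
  expect_gt(chi$p.value, 0.01)
})

test_that("trial bookkeeping, allocation invariants, and dropped-arm persistence hold", {
  sc <- scenario_config(0.35, 0.40, f_true = 1)
  sch <- fractrial:::schedule_for_scenario(sc)
  for (s in 1:15) {
    tr <- run_trial(sc, model_spec("fractional", prior_mean_f = 1), sch,
                    seed = 6000 + s)
    lk <- tidy(tr)
    # enrolment equals the last reached look target
    expect_identical(tr$total_enrolled, as.integer(lk$target[nrow(lk)]))
    # allocations are probability vectors at every look
    al <- as.matrix(lk[, c("alloc_A", "alloc_B", "alloc_AB")])
    expect_true(all(al >= 0))
    expect_equal(rowSums(al), rep(1, nrow(al)))
    # cumulative counts never decrease
    for (cn in c("n_A", "n_B", "n_AB", "y_A", "y_B", "y_AB")) {
      expect_true(all(diff(lk[[cn]]) >= 0))
    }
    # once an arm leaves the active set it stays out and gets zero allocation
    act <- strsplit(lk$active, ",")
    for (k in seq_along(act)[-1]) {
      expect_true(all(act[[k]] %in% act[[k - 1]]))
      gone <- setdiff(c("A", "B", "AB"), act[[k - 1]])
      if (length(gone) && k <= nrow(lk)) {
        expect_true(all(al[k, match(gone, c("A", "B", "AB"))] == 0))
      }
    }
    expect_lte(tr$total_enrolled, sch$total_max_n)
  }
})

test_that("fixed 1:1:1 mode never adapts or drops but still stops", {
  sc <- scenario_config(0.35, 0.40, f_true = 1, allocation_mode = "fixed_111")
  tr <- run_trial(sc, model_spec("fractional", prior_mean_f = 1),
                  build_schedule(100), seed = 21)
  lk <- tidy(tr)
  expect_true(all(abs(as.matrix(lk[, c("alloc_A", "alloc_B", "alloc_AB")]) -
                        1 / 3) < 1e-12))
  expect_true(all(lk$active == "A,B,AB"))
})

test_that("a trial is fully reproducible from its seed", {
  sc <- scenario_config(0.40, 0.40, f_true = 0.75)
  sch <- build_schedule(80)
  spec <- model_spec("fractional", prior_mean_f = 0.75)
  a <- run_trial(sc, spec, sch, seed = 77)
  b <- run_trial(sc, spec, sch, seed = 77)
  expect_identical(tidy(a), tidy(b))
  expect_identical(glance(a), glance(b))
  c <- run_trial(sc, spec, sch, seed = 78)
  expect_false(identical(tidy(a), tidy(c)))
})

test_that("the fractional model terminates earlier than the conventional one when f >= 0.5", {
  pr <- paired_f075(200)
  t_frac <- vapply(pr$fractional, function(r) r$termination_look, numeric(1))
  t_conv <- vapply(pr$conventional, function(r) r$termination_look, numeric(1))
  expect_lt(mean(t_frac), mean(t_conv))
  # sign test on paired seeds (ties dropped)
  d <- t_conv - t_frac
  bt <- stats::binom.test(sum(d > 0), sum(d != 0))
  expect_lt(bt$p.value, 0.01)
  expect_gt(sum(d > 0), sum(d < 0))
})

test_that("autoplot returns a ggplot of the superiority trajectory", {
  sc <- scenario_config(0.35, 0.40, f_true = 1)
  tr <- run_trial(sc, model_spec("fractional", prior_mean_f = 1),
                  build_schedule(100), seed = 3)
  p <- ggplot2::autoplot(tr)
  expect_s3_class(p, "ggplot")
})
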