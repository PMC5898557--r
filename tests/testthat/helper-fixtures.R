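# Shared helpers for the test suite. Fixtures are built in code; nothing is
# read from disk.

make_counts <- function(n, y) {
  cts <- arm_counts()
  cts$n_enrolled <- as.integer(n)
  cts$n_responses <- as.integer(y)
  cts
}

# Randomized small-count fixtures for the sampler-vs-oracle equivalence suite.
# Generated once up front under a fixed seed so individual checks cannot
# perturb each other's RNG stream.
oracle_fixtures <- function(n_fix = 20, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n_fix), function(i) {
    n <- sample(20:200, 3, replace = TRUE)
    y <- rbinom(3, n, runif(3, 0.3, 0.8))
    kind <- sample(c("fractional", "conventional", "full_additivity"), 1)
    pm <- if (kind == "fractional") runif(1, 0, 1) else NULL
    list(counts = make_counts(n, y), kind = kind, prior_mean_f = pm)
  })
}

fixture_model <- function(fx) {
  if (fx$kind == "fractional") {
    model_spec("fractional", prior_mean_f = fx$prior_mean_f)
  } else {
    model_spec(fx$kind)
  }
}

# Minimal stand-in trial object for metric-definition tests (only the fields
# the metrics read).
fake_trial <- function(total_enrolled, total_failures, termination_look = 1,
                       looks = NULL, schedule = build_schedule(452),
                       kind = "conventional") {
  structure(
    list(
      looks = looks,
      termination_look = termination_look,
      termination_reason = if (termination_look <
                               length(schedule$look_targets))
        "early_superiority" else "max_n_reached",
      winner = "AB",
      total_enrolled = total_enrolled,
      total_failures = total_failures,
      scenario = scenario_config(0.35, 0.40, f_true = 1),
      spec = model_spec(kind),
      schedule = schedule,
      seed = 0
    ),
    class = "fa_trial"
  )
}

# Cache for expensive shared simulation batches (filled lazily by tests).
.sim_cache <- new.env(parent = emptyenv())

run_trials <- function(scenario, spec, M, seed0, schedule = NULL) {
  if (is.null(schedule)) schedule <- fractrial:::schedule_for_scenario(scenario)
  lapply(seq_len(M), function(m) {
    run_trial(scenario, spec, schedule, seed = seed0 + m)
  })
}

cached_trials <- function(key, scenario, spec, M, seed0) {
  if (!exists(key, .sim_cache)) {
    assign(key, run_trials(scenario, spec, M, seed0), .sim_cache)
  }
  get(key, .sim_cache)
}

# The paired fractional/conventional batches on the f = 0.75 scenario are
# shared between engine-ordering, metrics-ordering and acceptance tests.
paired_f075 <- function(M = 200) {
  sc <- scenario_config(0.35, 0.40, f_true = 0.75)
  list(
    fractional = cached_trials("f075_frac", sc,
                               model_spec("fractional", prior_mean_f = 0.75),
                               M, 7100),
    conventional = cached_trials("f075_conv", sc,
                                 model_spec("conventional"), M, 7300),
    full = cached_trials("f075_full", sc,
                         model_spec("full_additivity"), M, 7500),
    scenario = sc
  )
}
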