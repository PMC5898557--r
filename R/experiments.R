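# Stable 31-bit hash of a label, for deriving per-cell seeds that do not
# depend on a cell's position in the plan.
hash_label <- function(label) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

cell_seed <- function(master_seed, label) {
  s <- (as.numeric(master_seed) + hash_label(label)) %% 2147483647
  as.integer(max(1, s))
}

replicate_seeds <- function(cell_seed, M) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cell_seed)
  sample.int(2147483646L, M)
}

#' The five analysis-model specifications of the simulation study
#'
#' Fractional-additivity model with an unbiased prior (mean = true `f`), with
#' a +0.25 and a -0.25 biased prior (25% absolute bias, variance 0.16), the
#' conventional independent-arm model, and the full-additivity model.
#'
#' @param f_true True fractional additivity of the scenario (sets the
#'   unbiased prior mean).
#' @param prior_var_f Prior variance on `f` (default 0.16).
#' @param prior_means Optional explicit fractional prior means (overrides the
#'   unbiased/biased triple; used for weak-additivity scenarios, where only
#'   optimistic means 0.5 and 0.75 are studied).
#' @return Named list of `fa_model` objects.
#' @export
model_grid <- function(f_true, prior_var_f = 0.16, prior_means = NULL) {
  if (is.null(prior_means)) {
    frac <- list(
      fractional_unbiased = model_spec("fractional", prior_mean_f = f_true,
                                       prior_var_f = prior_var_f),
      fractional_bias_pos = model_spec("fractional", prior_mean_f = f_true + 0.25,
                                       prior_var_f = prior_var_f),
      fractional_bias_neg = model_spec("fractional", prior_mean_f = f_true - 0.25,
                                       prior_var_f = prior_var_f)
    )
  } else {
    frac <- setNames(
      lapply(prior_means, function(m)
        model_spec("fractional", prior_mean_f = m, prior_var_f = prior_var_f)),
      paste0("fractional_prior_", prior_means)
    )
  }
  c(frac, list(conventional = model_spec("conventional"),
               full_additivity = model_spec("full_additivity")))
}

#' Build a simulation experiment plan
#'
#' Expands the study's scenario grid crossed with the analysis-model grid
#' into a plan tibble, one row per (scenario, model) cell, with a
#' deterministic per-cell seed derived from the master seed and the cell
#' label (so a cell's results do not depend on which other cells are
#' present).
#'
#' Two built-in grids:
#' * `"meaningful"` — failure pairs (0.35, 0.40) and (0.40, 0.40) crossed
#'   with true `f` in 0.5 / 0.75 / 1, analysed with all five model
#'   specifications (unbiased and ±0.25-biased fractional priors,
#'   conventional, full additivity).
#' * `"weak"` — the same failure pairs with true `f` in 0 / 0.25, sized under
#'   the optimistic design additivity `f + 0.5`, analysed with fractional
#'   priors at means 0.5 and 0.75 only, plus the conventional and
#'   full-additivity models.
#'
#' @param grid `"meaningful"`, `"weak"`, or a list of `fa_scenario` objects
#'   for a custom grid (then analysed with the five-model grid at each
#'   scenario's `f_true`).
#' @param M Simulated trials per cell.
#' @param master_seed Master integer seed.
#' @param allocation_mode `"adaptive"` or `"fixed_111"`.
#' @param sigma2 Prognostic-offset variance (default 0.16).
#' @param config Alternatively, a YAML file path or named list with entries
#'   `grid`, `M`, `master_seed`, `allocation_mode`, `sigma2` overriding the
#'   other arguments.
#' @return A plan tibble of class `fa_plan` with columns `cell`, `scenario`
#'   (list), `model` (list), `model_label`, `M`, `seed`.
#' @export
build_plan <- function(grid = "meaningful", M = 200, master_seed = 1,
                       allocation_mode = "adaptive", sigma2 = 0.16,
                       config = NULL) {
  if (!is.null(config)) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (!is.null(config$grid)) grid <- config$grid
    if (!is.null(config$M)) M <- config$M
    if (!is.null(config$master_seed)) master_seed <- config$master_seed
    if (!is.null(config$allocation_mode)) allocation_mode <- config$allocation_mode
    if (!is.null(config$sigma2)) sigma2 <- config$sigma2
  }
  stopifnot(M >= 1)
  pairs <- list(c(0.35, 0.40), c(0.40, 0.40))

  cells <- list()
  add_cell <- function(sc, model, model_label) {
    label <- sprintf("pA%.2f_pB%.2f_f%.2f_%s",
                     sc$p_fail_A, sc$p_fail_B, sc$f_true, model_label)
    cells[[length(cells) + 1]] <<- tibble(
      cell = label, scenario = list(sc), model = list(model),
      model_label = model_label, M = as.integer(M),
      seed = cell_seed(master_seed, label)
    )
  }

  if (is.list(grid) && all(vapply(grid, inherits, logical(1), "fa_scenario"))) {
    for (sc in grid) {
      for (ml in names(mods <- model_grid(sc$f_true))) add_cell(sc, mods[[ml]], ml)
    }
  } else if (identical(grid, "meaningful")) {
    for (pp in pairs) for (f in c(0.5, 0.75, 1)) {
      sc <- scenario_config(pp[1], pp[2], f_true = f, sigma2 = sigma2,
                            allocation_mode = allocation_mode)
      for (ml in names(mods <- model_grid(f))) add_cell(sc, mods[[ml]], ml)
    }
  } else if (identical(grid, "weak")) {
    for (pp in pairs) for (f in c(0, 0.25)) {
      sc <- scenario_config(pp[1], pp[2], f_true = f, sigma2 = sigma2,
                            allocation_mode = allocation_mode,
                            design_f = design_effect_for_weak_scenarios(f))
      mods <- model_grid(f, prior_means = c(0.5, 0.75))
      for (ml in names(mods)) add_cell(sc, mods[[ml]], ml)
    }
  } else {
    abort("`grid` must be \"meaningful\", \"weak\", or a list of fa_scenario objects.")
  }
  plan <- dplyr::bind_rows(cells)
  class(plan) <- c("fa_plan", class(plan))
  attr(plan, "master_seed") <- master_seed
  plan
}

#' Run an experiment plan
#'
#' Executes [run_trial()] for every replicate of every cell and aggregates
#' operating characteristics with [summarize_trials()]. Per-trial failures
#' are caught, logged, and counted; a cell with more than 1% failed trials is
#' flagged. If `out_dir` is given, each cell's summary and termination
#' distribution are written as CSVs as soon as the cell completes, and cells
#' whose summary file already exists are loaded rather than recomputed
#' (cheap resumability).
#'
#' @param plan An `fa_plan` from [build_plan()].
#' @param out_dir Optional output directory for per-cell CSVs and a manifest.
#' @param n_draws,warmup,thin Passed to [sample_posterior()].
#' @param keep_results Return the raw `fa_trial` lists as well (memory-heavy
#'   for large plans). Default `FALSE`.
#' @param progress Print per-cell progress to stderr. Default `TRUE`.
#' @return A list with `summaries` (tibble, one row per cell, including an
#'   `ecdf` list-column and `failed_trials` / `flagged` columns) and, if
#'   requested, `results` (named list of per-cell trial lists).
#' @export
run_plan <- function(plan, out_dir = NULL, n_draws = 4000, warmup = 1000,
                     thin = 5, keep_results = FALSE, progress = TRUE) {
  stopifnot(inherits(plan, "fa_plan"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  all_results <- if (keep_results) list() else NULL
  rows <- vector("list", nrow(plan))

  for (i in seq_len(nrow(plan))) {
    cell <- plan$cell[i]
    sum_path <- if (!is.null(out_dir)) {
      file.path(out_dir, paste0("summary_", cell, ".csv"))
    } else NULL
    ecdf_path <- if (!is.null(out_dir)) {
      file.path(out_dir, paste0("ecdf_", cell, ".csv"))
    } else NULL

    if (!is.null(sum_path) && file.exists(sum_path)) {
      if (progress) message("cell ", cell, ": loading existing summary")
      s <- as_tibble(utils::read.csv(sum_path))
      s$ecdf <- list(as_tibble(utils::read.csv(ecdf_path)))
      rows[[i]] <- s
      next
    }
    if (progress) message("cell ", cell, " (", plan$M[i], " trials)")

    sc <- plan$scenario[[i]]
    spec <- plan$model[[i]]
    schedule <- schedule_for_scenario(sc)
    seeds <- replicate_seeds(plan$seed[i], plan$M[i])
    trials <- vector("list", plan$M[i])
    failed <- 0L
    for (m in seq_len(plan$M[i])) {
      tr <- tryCatch(
        run_trial(sc, spec, schedule, seed = seeds[m],
                  n_draws = n_draws, warmup = warmup, thin = thin),
        error = function(e) {
          message("  trial ", m, " failed: ", conditionMessage(e))
          NULL
        })
      if (is.null(tr)) failed <- failed + 1L else trials[[m]] <- tr
    }
    trials <- trials[!vapply(trials, is.null, logical(1))]
    s <- summarize_trials(trials, model = plan$model_label[i],
                          scenario = cell)
    s$failed_trials <- failed
    s$flagged <- failed > 0.01 * plan$M[i]
    rows[[i]] <- s
    if (keep_results) all_results[[cell]] <- trials

    if (!is.null(sum_path)) {
      utils::write.csv(dplyr::select(s, -"ecdf"), sum_path, row.names = FALSE)
      ec <- dplyr::mutate(s$ecdf[[1]], model = s$model, scenario = s$scenario,
                          .before = 1)
      utils::write.csv(ec, ecdf_path, row.names = FALSE)
    }
  }

  summaries <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    yaml::write_yaml(
      list(master_seed = attr(plan, "master_seed"),
           n_cells = nrow(plan), M = unique(plan$M),
           package_version = as.character(utils::packageVersion("fractrial"))),
      file.path(out_dir, "manifest.yaml"))
    utils::write.csv(dplyr::select(summaries, -"ecdf"),
                     file.path(out_dir, "summaries.csv"), row.names = FALSE)
  }
  out <- list(summaries = summaries)
  if (keep_results) out$results <- all_results
  out
}
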