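#' Run a full selection experiment from a config file
#'
#' Chains the staged pipeline — synthesise or load a dataset, pre-select
#' genes by |t|, run the GA or stepwise selector, evaluate the selected
#' subset under repeated holdout, and write the reports — from one flat
#' YAML configuration. All randomness derives from a single master seed,
#' so the same config and seed give byte-identical outputs.
#'
#' Recognised config keys (flat, with sub-maps): `seed`; either
#' `dataset: {path: <tsv/csv>}` or `synth: {n_samples, n_genes,
#' n_informative, effect_size, n_redundant_per_informative,
#' redundancy_rho, class0_proportion, noise_sd}`; `preselect: {fraction}`
#' (default 0.05); `classifier: {method, params}` (required);
#' `selector: "ga"` or `"sfs"`; `ga: {lambda, beta, population_size,
#' elite_count, crossover_rate, mutation_rate, generations,
#' init_max_active}`; `evaluate: {n_reps, per_repetition}`.
#'
#' @param config Path to the YAML config, or an equivalent named list.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional master-seed override of the config's `seed`.
#' @return A `run_manifest` list: config snapshot, seeds, stage output
#'   paths, and headline numbers. Written to `manifest.json` as well.
#' @export
run_experiment <- function(config, out_dir = ".", seed = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) abort_format(paste0("config not found: ", config))
    yaml::read_yaml(config)
  } else {
    config
  }
  if (is.null(cfg$classifier) || is.null(cfg$classifier$method)) {
    abort(
      "config key `classifier` (with `method`) is required.",
      class = "evoselect_config_error"
    )
  }
  master_seed <- as.integer(seed %||% cfg$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  t_start <- Sys.time()

  on_failure <- function(e) {
    writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
    abort(
      paste0("pipeline stage failed: ", conditionMessage(e)),
      class = "evoselect_pipeline_error", parent = e
    )
  }

  withCallingHandlers(
    {
      # --- stage 1: data ---
      if (!is.null(cfg$dataset$path)) {
        data <- read_expression(cfg$dataset$path)
        truth <- NULL
      } else if (!is.null(cfg$synth)) {
        s <- cfg$synth
        spec <- synthetic_spec(
          n_samples = s$n_samples %||% 100L,
          n_genes = s$n_genes %||% 2000L,
          n_informative = s$n_informative %||% 5L,
          effect_size = s$effect_size %||% 2,
          n_redundant_per_informative = s$n_redundant_per_informative %||% 0L,
          redundancy_rho = s$redundancy_rho %||% 0,
          class0_proportion = s$class0_proportion %||% 0.5,
          noise_sd = s$noise_sd %||% 1,
          seed = derive_seed(master_seed, 1L)
        )
        data <- generate_dataset(spec)
        truth <- informative_genes(data)
        paths$dataset <- file.path(out_dir, "dataset.tsv")
        write_expression(data, paths$dataset)
        paths$truth <- file.path(out_dir, "informative_genes.txt")
        writeLines(truth, paths$truth)
      } else {
        abort("config needs `dataset: {path}` or `synth: {...}`.",
          class = "evoselect_config_error"
        )
      }

      # --- stage 2: pre-selection ---
      fraction <- cfg$preselect$fraction %||% 0.05
      pool <- preselect_top_fraction(data, fraction)
      paths$ranking <- file.path(out_dir, "ranking.csv")
      readr::write_csv(rank_genes(data), paths$ranking)

      # --- stage 3: classifier + selector ---
      clf <- classifier_spec(
        cfg$classifier$method,
        as.list(cfg$classifier$params %||% list()),
        seed = derive_seed(master_seed, 2L),
        strict = !isFALSE(cfg$classifier$strict)
      )
      selector_kind <- cfg$selector %||% "ga"
      ga_opts <- as.list(cfg$ga %||% list())
      gcfg <- ga_config(
        population_size = ga_opts$population_size %||% 100L,
        elite_count = ga_opts$elite_count %||% 10L,
        crossover_rate = ga_opts$crossover_rate %||% 0.8,
        mutation_rate = ga_opts$mutation_rate %||% 0.2,
        generations = ga_opts$generations %||% 200L,
        lambda = ga_opts$lambda %||% 0.4,
        beta = ga_opts$beta %||% 0.25,
        init_max_active = ga_opts$init_max_active %||% 50L,
        seed = derive_seed(master_seed, 3L)
      )

      if (identical(selector_kind, "ga")) {
        fit <- run_ga(pool, clf, gcfg)
        selected <- fit$best_genes
        paths$history <- file.path(out_dir, "fitness_history.csv")
        readr::write_csv(fit$history, paths$history)
        selector_summary <- glance(fit)
      } else if (identical(selector_kind, "sfs")) {
        split <- split_holdout(pool, seed = derive_seed(master_seed, 4L))
        fit <- run_sfs(pool, clf, split)
        selected <- fit$subset
        paths$history <- file.path(out_dir, "sfs_trace.csv")
        readr::write_csv(tidy(fit), paths$history)
        selector_summary <- glance(fit)
      } else {
        abort(paste0("unknown `selector`: ", selector_kind),
          class = "evoselect_config_error"
        )
      }
      if (length(selected) == 0L) {
        abort("selector returned an empty gene set.")
      }
      paths$genes <- file.path(out_dir, "selected_genes.txt")
      writeLines(selected, paths$genes)

      # --- stage 4: repeated-holdout evaluation ---
      n_reps <- cfg$evaluate$n_reps %||% 50L
      per_rep <- isTRUE(cfg$evaluate$per_repetition)
      selector_fun <- if (!per_rep) {
        NULL
      } else if (identical(selector_kind, "ga")) {
        function(d, split, s) {
          run_ga(d, clf, modify_ga_seed(gcfg, s))$best_genes
        }
      } else {
        function(d, split, s) run_sfs(d, clf, split)$subset
      }
      rr <- repeated_holdout(
        pool, clf,
        genes = if (per_rep) NULL else selected,
        selector = selector_fun,
        n_reps = n_reps, base_seed = derive_seed(master_seed, 5L)
      )
      paths$scores <- file.path(out_dir, "repetition_scores.csv")
      readr::write_csv(
        dplyr::mutate(rr$scores, genes = purrr::map_chr(genes, paste, collapse = ";")),
        paths$scores
      )
      freq <- selection_frequency(rr$scores$genes)
      paths$frequency <- file.path(out_dir, "selection_frequency.csv")
      readr::write_csv(freq, paths$frequency)

      recovery <- if (!is.null(truth)) recovery_score(selected, truth) else NULL

      manifest <- list(
        config = cfg, master_seed = master_seed,
        paths = lapply(paths, normalizePath),
        selector = selector_kind,
        selector_summary = as.list(selector_summary),
        evaluation = as.list(glance(rr)),
        selected_genes = selected,
        recovery = if (!is.null(recovery)) as.list(recovery),
        wall_clock_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
      )
      paths$manifest <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
      manifest$paths$manifest <- normalizePath(paths$manifest)
      message("run complete (master seed ", master_seed, "); outputs in ", out_dir)
      structure(manifest, class = "run_manifest")
    },
    error = on_failure
  )
}

# Clone a ga_config with a new master seed (per-repetition selector runs).
modify_ga_seed <- function(gcfg, seed) {
  gcfg$seed <- as.integer(seed)
  gcfg
}
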