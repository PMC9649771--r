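#' Validate and complete a run configuration
#'
#' Accepts a YAML/JSON file path or a plain list, fills defaults, enforces
#' invariants, and rejects unknown keys. A seed is mandatory: every random
#' stage of the pipeline draws from named substreams of it, so a config fully
#' determines the outputs.
#'
#' Defaults follow the method's standard settings: ~10,000 background points,
#' 5-fold cross-validation, a 10% training-presence threshold, 10 trait
#' deciles, and the 12-future-scenario grid (3 GCMs x 2 RCPs x 2 periods)
#' plus the current baseline.
#'
#' @param config A file path or named list. Recognized keys: `mode`
#'   (`"synthetic"` or `"user_data"`), `synthetic` (list passed to
#'   [synthetic_config()]), `paths` (for user data: `occurrences`, named
#'   raster `layers`), `n_deciles`, `background_n`, `lambda`,
#'   `feature_classes`, `k_folds`, `threshold_percentile`, `scenarios`
#'   (list of gcm/rcp/period lists), `denominator_rule`, `permutations`,
#'   `seed`, `outdir`.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  known <- c("mode", "synthetic", "paths", "n_deciles", "background_n",
             "lambda", "feature_classes", "k_folds", "threshold_percentile",
             "scenarios", "denominator_rule", "permutations", "seed", "outdir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    ts_abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
             "config_invalid")
  }
  if (is.null(config$seed)) {
    ts_abort("config$seed is mandatory (outputs must be reproducible)",
             "config_invalid")
  }
  cfg <- list(
    mode = config$mode %||% "synthetic",
    n_deciles = config$n_deciles %||% 10,
    background_n = config$background_n %||% 10000,
    lambda = config$lambda %||% 1.0,
    feature_classes = config$feature_classes %||% c("linear", "quadratic"),
    k_folds = config$k_folds %||% 5,
    threshold_percentile = config$threshold_percentile %||% 10,
    denominator_rule = config$denominator_rule %||% "all_valid",
    permutations = config$permutations %||% 999,
    seed = as.integer(config$seed),
    outdir = config$outdir,
    paths = config$paths
  )
  if (!cfg$mode %in% c("synthetic", "user_data")) {
    ts_abort("mode must be 'synthetic' or 'user_data'", "config_invalid")
  }
  if (cfg$n_deciles < 2) {
    ts_abort("n_deciles must be >= 2", "config_invalid")
  }
  if (cfg$threshold_percentile <= 0 || cfg$threshold_percentile >= 50) {
    ts_abort("threshold_percentile must lie in (0, 50)", "config_invalid")
  }
  if (!cfg$denominator_rule %in% c("all_valid", "suitable_only")) {
    ts_abort("denominator_rule must be 'all_valid' or 'suitable_only'",
             "config_invalid")
  }
  if (cfg$mode == "synthetic") {
    syn_args <- config$synthetic %||% list()
    syn_args$seed <- syn_args$seed %||% cfg$seed
    cfg$synthetic <- do.call(synthetic_config, syn_args)
  } else if (is.null(cfg$paths$occurrences) || is.null(cfg$paths$layers)) {
    ts_abort("user_data mode needs paths$occurrences and paths$layers",
             "config_invalid")
  }
  cfg$scenarios <- if (is.null(config$scenarios)) {
    default_scenarios()
  } else {
    lapply(config$scenarios, function(s) {
      if (inherits(s, "scenario_spec")) s
      else scenario_spec(s$gcm %||% "none", s$rcp %||% "none",
                         s$period %||% "current")
    })
  }
  periods <- vapply(cfg$scenarios, function(s) s$period, character(1))
  if (!"current" %in% periods) {
    ts_abort("the scenario list must include the current baseline",
             "config_invalid")
  }
  # Baseline first, so downstream stages can rely on position 1.
  cfg$scenarios <- c(cfg$scenarios[periods == "current"],
                     cfg$scenarios[periods != "current"])
  structure(cfg, class = "run_config")
}

#' Run the full stacked trait-decile pipeline
#'
#' Sequences the whole analysis: simulate (or load) the landscape and
#' genotypes, assign trait deciles and thin presences, fit and cross-validate
#' one presence-background model per decile, binarize at the
#' training-presence threshold, project every decile onto every scenario,
#' stack into richness maps, difference against the baseline, summarize
#' losses per extent, build the decile-combination community matrix, score
#' trait-distribution similarity, and run constrained ordination with
#' stepwise constraint selection. Rerunning with the same config reproduces
#' every output exactly.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @return A `pipeline_run` list: `occurrences`, `assignment`, `presences`,
#'   `evaluation` (per-decile tibble), `models`, `binaries` (per scenario),
#'   `richness` (per scenario), `change_summaries`, `gcm_means`,
#'   `tail_frequencies`, `community`, `similarity`, `selection`, `rda`,
#'   `manifest`. When `config$outdir` is set, rasters (ASCII grid), CSV
#'   tables and a JSON manifest are written there as well.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ts_abort(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)),
               "stage_failure", parent = e)
    })
  }

  ## Landscape and occurrences
  envs <- stage("environment", {
    if (cfg$mode == "synthetic") {
      stats::setNames(
        lapply(cfg$scenarios, function(sc) simulate_environment(cfg$synthetic, sc)),
        vapply(cfg$scenarios, scenario_label, character(1))
      )
    } else {
      lapply(cfg$paths$layers, function(set) {
        read_env_stack(unlist(set$paths), set$names)
      })
    }
  })
  env_current <- envs[["current"]]
  occ <- stage("occurrences", {
    if (cfg$mode == "synthetic") {
      simulate_populations(env_current, cfg$synthetic)
    } else {
      read_occurrences(cfg$paths$occurrences)
    }
  })

  ## Deciles and thinned presences
  assignment <- stage("assign_deciles", assign_deciles(occ, cfg$n_deciles))
  presences <- stage("thin_presences",
                     thin_presences(assignment, occ, env_current$grid))

  ## Background and per-decile models
  background <- stage("background", {
    sample_background(env_current, n = cfg$background_n,
                      seed = substream_seed(cfg$seed, "background"))
  })
  spec <- feature_spec(layers = names(env_current$layers),
                       classes = cfg$feature_classes)
  deciles <- sort(unique(presences$decile))
  evals <- list()
  models <- list()
  for (d in deciles) {
    pres_d <- dplyr::filter(tibble::as_tibble(presences), .data$decile == d)
    ev <- stage(paste0("crossvalidate_decile_", d), {
      crossvalidate(pres_d, background, env_current, spec,
                    lambda = cfg$lambda, k = min(cfg$k_folds, nrow(pres_d)),
                    seed = substream_seed(cfg$seed, paste0("cv/", d)),
                    decile = d)
    })
    evals[[as.character(d)]] <- ev
    models[[as.character(d)]] <- attr(ev, "model")
  }
  evaluation <- dplyr::bind_rows(lapply(evals, tibble::as_tibble))

  ## Project + threshold every decile under every scenario
  binaries <- stage("project", {
    lapply(envs, function(env_sc) {
      lapply(models, function(m) {
        threshold_10pct(m, predict_suitability(m, env_sc),
                        percentile = cfg$threshold_percentile)$binary
      })
    })
  })

  ## Stack, difference, summarize
  richness <- stage("stack", {
    stats::setNames(
      lapply(seq_along(cfg$scenarios), function(si) {
        stack_richness(binaries[[si]], scenario = cfg$scenarios[[si]])
      }),
      names(envs)
    )
  })
  extents <- c(list(range = env_current$valid_mask),
               population_extents(env_current$grid))
  future_idx <- which(vapply(cfg$scenarios, function(s) s$period != "current",
                             logical(1)))
  change_summaries <- stage("summarize_change", {
    purrr::map_dfr(future_idx, function(si) {
      chg <- richness_change(richness[["current"]], richness[[si]])
      purrr::map_dfr(names(extents), function(ex) {
        summarize_change(chg, extents[[ex]], cfg$denominator_rule,
                         extent_label = ex)
      })
    })
  })
  gcm_means <- if (nrow(change_summaries) > 0) {
    summarize_across_gcms(change_summaries)
  } else {
    tibble::tibble()
  }
  tail_frequencies <- stage("tail_frequency", {
    purrr::map_dfr(seq_along(cfg$scenarios), function(si) {
      purrr::map_dfr(names(extents), function(ex) {
        dplyr::mutate(
          tail_frequency(binaries[[si]], richness[[si]], extents[[ex]]),
          extent = ex, .before = 1
        )
      })
    })
  })

  ## Trait communities
  pop_extents <- population_extents(env_current$grid)
  community <- stage("community_matrix", {
    build_community_matrix(binaries, cfg$scenarios, pop_extents)
  })
  similarity <- stage("similarity", scenario_similarity(community))
  selection <- stage("select_constraints", {
    select_constraints(community,
                       permutations = min(cfg$permutations, 199),
                       seed = substream_seed(cfg$seed, "selection"))
  })
  rda <- stage("rda", {
    # The baseline sentinel levels make gcm/rcp/period partially collinear
    # (a "none" dummy in one factor equals "current" in another), so the
    # constraint set is pruned to a full-rank subset before the ordination.
    cols <- if (length(selection$selected) > 0) selection$selected
            else c("population", "gcm", "rcp", "period")
    cols <- prune_aliased(as.data.frame(cm_meta_cols(community, cols)))
    rda_communities(community,
                    constraints = as.data.frame(cm_meta_cols(community, cols)),
                    permutations = cfg$permutations,
                    seed = substream_seed(cfg$seed, "rda"))
  })

  run <- structure(
    list(
      config = cfg, occurrences = occ, assignment = assignment,
      presences = presences, evaluation = evaluation, models = models,
      background = background, envs = envs, binaries = binaries,
      richness = richness, change_summaries = change_summaries,
      gcm_means = gcm_means, tail_frequencies = tail_frequencies,
      community = community, similarity = similarity,
      selection = selection, rda = rda
    ),
    class = "pipeline_run"
  )
  if (!is.null(cfg$outdir)) {
    run$manifest <- write_run_outputs(run, cfg$outdir)
  }
  run
}

# Greedily keep factors (in the given order) while they add rank to the
# dummy-coded design; drops factors aliased by the ones already kept.
prune_aliased <- function(constraints) {
  kept <- character()
  for (nm in names(constraints)) {
    X <- model.matrix(~ ., data = constraints[, c(kept, nm), drop = FALSE])
    if (qr(X)$rank == ncol(X)) kept <- c(kept, nm)
  }
  kept
}

cm_meta_cols <- function(cm, cols) {
  out <- cm$meta[, intersect(cols, names(cm$meta)), drop = FALSE]
  # Keep only factors with >= 2 levels among the requested columns.
  out[, vapply(out, function(v) length(unique(v)) > 1, logical(1)),
      drop = FALSE]
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf(
    "<pipeline_run> %d genotypes, %d deciles, %d scenarios; mean test AUC %.3f\n",
    nrow(x$occurrences), length(x$models), length(x$richness),
    mean(x$evaluation$test_auc_mean)
  ))
  invisible(x)
}

# Write the report bundle: rasters, CSV tables and a JSON manifest whose
# config hash ties every file to the settings that produced it.
write_run_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  add <- function(path) files[[length(files) + 1L]] <<- path
  grid <- run$envs[["current"]]$grid
  for (sc_name in names(run$richness)) {
    p <- file.path(outdir, sprintf("richness_%s.asc", sc_name))
    write_raster(run$richness[[sc_name]]$values, grid, p)
    add(p)
  }
  for (b in run$binaries[["current"]]) {
    p <- file.path(outdir, sprintf("binary_current_d%02d.asc", b$decile))
    write_raster(b$values, grid, p)
    add(p)
  }
  tables <- list(
    evaluation = run$evaluation,
    change_summaries = run$change_summaries,
    gcm_means = run$gcm_means,
    tail_frequencies = run$tail_frequencies,
    similarity = tibble::as_tibble(run$similarity),
    presences = tibble::as_tibble(run$presences),
    occurrences = tibble::as_tibble(run$occurrences)
  )
  for (nm in names(tables)) {
    if (nrow(tables[[nm]]) == 0) next
    p <- file.path(outdir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p, progress = FALSE)
    add(p)
  }
  # Long-format (sparse) community matrix.
  p <- file.path(outdir, "community_matrix.csv")
  readr::write_csv(tidy(run$community), p, progress = FALSE)
  add(p)
  p <- file.path(outdir, "ordination.json")
  jsonlite::write_json(
    list(
      selected = run$selection$selected,
      constrained_fraction = run$rda$constrained_fraction,
      p_value = run$rda$p_value,
      marginal_fractions = as.list(run$rda$marginal_fractions)
    ),
    p, auto_unbox = TRUE, digits = NA
  )
  add(p)
  cfg_plain <- run$config
  cfg_plain$outdir <- NULL  # hash identifies the settings, not the destination
  cfg_plain$scenarios <- lapply(cfg_plain$scenarios, unclass)
  cfg_plain$synthetic <- if (!is.null(cfg_plain$synthetic)) {
    lapply(unclass(cfg_plain$synthetic), function(v) {
      if (inherits(v, "grid_spec")) unclass(v) else v
    })
  }
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  manifest <- list(
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
    config_hash = config_hash_hex(as.character(cfg_json)),
    seed = run$config$seed,
    files = unname(vapply(files, basename, character(1)))
  )
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  manifest
}
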