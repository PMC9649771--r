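#' Encode and decode decile combinations
#'
#' A non-empty subset of the deciles 1..10 present in a cell is encoded as a
#' 10-bit mask (bit `d - 1` set when decile `d` is present), giving a
#' bijection with the 1023 possible decile combinations. Richness-0 cells are
#' excluded, never encoded.
#'
#' @param present Integer vector: a non-empty subset of 1..10.
#' @return `encode_combination()`: the bitmask (1..1023);
#'   `decode_combination()`: the sorted decile set.
#' @export
encode_combination <- function(present) {
  present <- unique(as.integer(present))
  if (length(present) == 0) {
    ts_abort("empty decile set (richness-0 cells are excluded, not encoded)",
             "empty_set")
  }
  if (any(present < 1 | present > 10)) {
    ts_abort("decile indices must lie in 1..10", "bad_decile")
  }
  as.integer(sum(2^(present - 1)))
}

#' @rdname encode_combination
#' @param mask Bitmask in 1..1023.
#' @export
decode_combination <- function(mask) {
  mask <- as.integer(mask)
  if (mask < 1 || mask > 1023) ts_abort("mask must lie in 1..1023", "bad_mask")
  which(bitwAnd(mask, 2L^(0:9)) > 0L)
}

#' Similarity of the trait deciles present in one cell
#'
#' The mean pairwise distance \eqn{\bar d} between the present decile indices
#' (0 for a singleton) is rescaled to a similarity `1 - dbar / 9` in `[0, 1]`:
#' 1 means a single decile (narrowest possible local trait range), 0 is only
#' reached by the widest pair \{1, 10\}.
#'
#' @param present Non-empty subset of 1..10.
#' @return Similarity in `[0, 1]`.
#' @export
cell_similarity <- function(present) {
  present <- unique(as.integer(present))
  if (length(present) == 0) ts_abort("empty decile set", "empty_set")
  if (length(present) == 1) return(1)
  dbar <- mean(stats::dist(present))
  1 - dbar / 9
}

# Similarity for every mask 1..1023, computed once.
similarity_table <- function() {
  vapply(1:1023, function(m) cell_similarity(decode_combination(m)),
         numeric(1))
}

#' Build the scenario-by-combination community matrix
#'
#' For each (population, scenario) pair, tallies the suitable cells of the
#' stacked decile maps by their decile-combination bitmask: a "site" (row) by
#' "species" (one of the 1023 combinations) abundance matrix whose entries
#' are pixel counts. Richness-0 cells are excluded.
#'
#' @param binaries_by_scenario Named list (scenario label -> list of 10
#'   `binary_map`s) as produced per scenario by the pipeline.
#' @param scenarios List of [scenario_spec()]s matching the names.
#' @param extent_masks Named list of logical matrices, one per population.
#' @return A `community_matrix`: integer `counts` matrix (rows = population x
#'   scenario, 1023 columns), with row metadata in the `meta` tibble.
#' @export
build_community_matrix <- function(binaries_by_scenario, scenarios,
                                   extent_masks) {
  stopifnot(length(binaries_by_scenario) == length(scenarios))
  grid <- binaries_by_scenario[[1]][[1]]$grid
  rows <- list()
  meta <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    binaries <- binaries_by_scenario[[si]]
    mask_mat <- matrix(0L, grid$n_rows, grid$n_cols)
    na_mat <- matrix(FALSE, grid$n_rows, grid$n_cols)
    for (b in binaries) {
      if (!grids_equal(b$grid, grid)) {
        ts_abort("binary maps do not share one grid", "grid_mismatch")
      }
      vals <- b$values
      na_mat <- na_mat | is.na(vals)
      vals[is.na(vals)] <- 0L
      bit <- as.integer(2^(b$decile - 1L))
      mask_mat <- mask_mat + bit * (vals == 1L)
    }
    for (pop in names(extent_masks)) {
      cells <- mask_mat[extent_masks[[pop]] & !na_mat]
      cells <- cells[cells > 0L]
      counts <- tabulate(cells, nbins = 1023)
      label <- paste(pop, scenario_label(sc), sep = "/")
      rows[[label]] <- counts
      meta[[label]] <- dplyr::bind_cols(tibble::tibble(population = pop),
                                        scenario_fields(sc))
    }
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- sprintf("m%04d", 1:1023)
  structure(
    list(counts = counts, meta = dplyr::bind_rows(meta), grid = grid),
    class = "community_matrix"
  )
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf(
    "<community_matrix> %d rows (population x scenario) x %d combinations, %d occupied\n",
    nrow(x$counts), ncol(x$counts), sum(colSums(x$counts) > 0)
  ))
  invisible(x)
}

#' Per-scenario trait-distribution similarity scores
#'
#' The count-weighted mean of the per-cell similarity over each community
#' matrix row, and its delta against the same population's current baseline
#' row. A positive delta means the population's local trait ranges are
#' becoming narrower -- trait distributions converging.
#'
#' @param cm A [build_community_matrix()] result.
#' @return A `similarity_scores` tibble: `population`, scenario fields,
#'   `n_cells`, `similarity`, `baseline_delta`.
#' @export
scenario_similarity <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  sim <- similarity_table()
  values <- apply(cm$counts, 1, function(counts) {
    total <- sum(counts)
    if (total == 0) return(NA_real_)
    sum(counts * sim) / total
  })
  out <- cm$meta |>
    dplyr::mutate(n_cells = rowSums(cm$counts), similarity = unname(values)) |>
    dplyr::group_by(.data$population) |>
    dplyr::mutate(
      baseline_delta = .data$similarity -
        .data$similarity[.data$period == "current"][1]
    ) |>
    dplyr::ungroup()
  structure(out, class = c("similarity_scores", class(out)))
}

## ---- Redundancy analysis ----------------------------------------------------

# Column-centred response and dummy-coded constraint matrix.
rda_prepare <- function(counts, constraints) {
  Y <- scale(as.matrix(counts), center = TRUE, scale = FALSE)
  constraints <- as.data.frame(lapply(constraints, function(v) {
    factor(as.character(v))
  }))
  list(Y = Y, constraints = constraints)
}

# Constrained variance fraction: SS of the least-squares projection of the
# centred response onto span(1, dummy-coded constraints), over total SS.
rda_fraction <- function(Y, constraints) {
  if (ncol(as.data.frame(constraints)) == 0) return(0)
  X <- model.matrix(~ ., data = as.data.frame(constraints))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    ts_abort(paste("rank-deficient constraints; aliased:",
                   paste(aliased, collapse = ", ")),
             "aliased_constraints")
  }
  fitted <- qr.fitted(qx, Y)
  tot <- sum(Y^2)
  if (tot == 0) return(0)
  sum(fitted^2) / tot
}

#' Redundancy analysis of the community matrix
#'
#' Column-centres the count matrix, regresses it on the dummy-coded
#' constraint factors, and reports the constrained variance fraction
#' (sum of squares of fitted values over total sum of squares) with a
#' permutation p-value from seeded row permutations of the constraint table.
#' Marginal fractions are each factor's fraction fitted alone.
#'
#' @param cm A [build_community_matrix()] result, or a plain numeric matrix
#'   of counts.
#' @param constraints Data frame of factors aligned with the matrix rows
#'   (default: population, gcm, rcp, period from the matrix metadata).
#' @param permutations Number of row permutations (>= 199 recommended;
#'   default 999).
#' @param seed Integer seed.
#' @param hellinger If `TRUE`, Hellinger-transform the counts (square root of
#'   row-relative abundances) before centring; off by default.
#' @return A `trait_rda`: list with `constrained_fraction`, `p_value`,
#'   `terms`, `marginal_fractions`, `permutations`.
#' @export
rda_communities <- function(cm, constraints = NULL, permutations = 999,
                            seed = 1L, hellinger = FALSE) {
  counts <- if (inherits(cm, "community_matrix")) cm$counts else as.matrix(cm)
  if (is.null(constraints)) {
    if (!inherits(cm, "community_matrix")) {
      ts_abort("constraints are required for a plain matrix", "bad_constraints")
    }
    constraints <- as.data.frame(
      cm$meta[, c("population", "gcm", "rcp", "period")]
    )
  }
  if (nrow(counts) < 2) ts_abort("need at least 2 rows", "too_few")
  if (nrow(as.data.frame(constraints)) != nrow(counts)) {
    ts_abort("constraints do not align with the matrix rows", "bad_constraints")
  }
  if (hellinger) {
    counts <- sqrt(counts / pmax(rowSums(counts), 1))
  }
  prep <- rda_prepare(counts, constraints)
  # Drop constant factors (a single level explains nothing and would alias).
  keep <- vapply(prep$constraints, function(f) nlevels(f) > 1, logical(1))
  active <- prep$constraints[, keep, drop = FALSE]
  obs <- rda_fraction(prep$Y, active)
  n <- nrow(prep$Y)
  perm_stats <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(permutations), function(i) {
      rda_fraction(prep$Y, active[sample.int(n), , drop = FALSE])
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats >= obs)) / (1 + permutations)
  marginal <- vapply(names(active), function(nm) {
    rda_fraction(prep$Y, active[, nm, drop = FALSE])
  }, numeric(1))
  structure(
    list(
      constrained_fraction = obs, p_value = p,
      terms = names(active), marginal_fractions = marginal,
      permutations = permutations, n_rows = n
    ),
    class = "trait_rda"
  )
}

#' @export
print.trait_rda <- function(x, ...) {
  cat(sprintf(
    "<trait_rda> constraints [%s] explain %.1f%% of variation (p = %.4g, %d permutations)\n",
    paste(x$terms, collapse = ", "), 100 * x$constrained_fraction,
    x$p_value, x$permutations
  ))
  invisible(x)
}

# Permutation test for adding `term` to the model containing `current`:
# pseudo-F on reduced-model residuals, residual-permutation scheme.
rda_term_test <- function(Y, constraints, current, term, permutations, seed) {
  n <- nrow(Y)
  Xr <- if (length(current) > 0) {
    model.matrix(~ ., data = constraints[, current, drop = FALSE])
  } else {
    matrix(1, n, 1)
  }
  qr_r <- qr(Xr)
  fit_r <- qr.fitted(qr_r, Y)
  res_r <- Y - fit_r
  full <- c(current, term)
  Xf <- model.matrix(~ ., data = constraints[, full, drop = FALSE])
  qf <- qr(Xf)
  df_add <- qf$rank - qr_r$rank
  df_res <- n - qf$rank
  if (df_add <= 0 || df_res <= 0) {
    return(list(p = NA_real_, stat = NA_real_))
  }
  fstat <- function(Yk) {
    ss_full <- sum(qr.fitted(qf, Yk)^2)
    ss_red <- sum(qr.fitted(qr_r, Yk)^2)
    ((ss_full - ss_red) / df_add) / ((sum(Yk^2) - ss_full) / df_res)
  }
  obs <- fstat(Y)
  perms <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(permutations), function(i) {
      fstat(fit_r + res_r[sample.int(n), , drop = FALSE])
    }, numeric(1))
  })
  list(p = (1 + sum(perms >= obs)) / (1 + permutations), stat = obs)
}

#' Stepwise constraint selection by permutation tests
#'
#' Forward-and-backward selection over candidate constraint factors: at each
#' forward step the candidate with the smallest permutation p-value below
#' `alpha` is added (reduced-model residual permutation, pseudo-F statistic);
#' after each addition, terms whose marginal test given the rest is no longer
#' significant are dropped. Repeats to a fixed point. Deterministic under a
#' fixed seed; an empty selection is a valid outcome.
#'
#' @param cm A [build_community_matrix()] result or counts matrix.
#' @param candidates Data frame of candidate factors (default: the matrix
#'   metadata factors).
#' @param alpha Significance level (default 0.05).
#' @param permutations Permutations per test (default 199).
#' @param seed Integer seed.
#' @return A `constraint_selection`: list with `selected` (character),
#'   `path` tibble of tested steps, and `alpha`.
#' @export
select_constraints <- function(cm, candidates = NULL, alpha = 0.05,
                               permutations = 199, seed = 1L) {
  counts <- if (inherits(cm, "community_matrix")) cm$counts else as.matrix(cm)
  if (is.null(candidates)) {
    candidates <- as.data.frame(
      cm$meta[, c("population", "gcm", "rcp", "period")]
    )
  }
  prep <- rda_prepare(counts, candidates)
  keep <- vapply(prep$constraints, function(f) nlevels(f) > 1, logical(1))
  constraints <- prep$constraints[, keep, drop = FALSE]
  pool <- names(constraints)
  if (length(pool) == 0) {
    return(structure(list(selected = character(), path = tibble::tibble(),
                          alpha = alpha),
                     class = "constraint_selection"))
  }
  selected <- character()
  path <- list()
  step <- 0L
  seen <- character()
  repeat {
    state <- paste(sort(selected), collapse = "+")
    if (state %in% seen) break  # cycle guard: fixed point reached
    seen <- c(seen, state)
    changed <- FALSE
    # Forward: add the most significant remaining candidate, if any.
    remaining <- setdiff(pool, selected)
    if (length(remaining) > 0) {
      step <- step + 1L
      tests <- purrr::map(remaining, function(term) {
        rda_term_test(prep$Y, constraints, selected, term, permutations,
                      substream_seed(seed, paste0("fwd/", step, "/", term)))
      })
      ps <- vapply(tests, function(t) t$p, numeric(1))
      path[[length(path) + 1L]] <- tibble::tibble(
        step = step, action = "forward", term = remaining, p = ps
      )
      if (any(!is.na(ps) & ps < alpha)) {
        best <- remaining[which.min(ifelse(is.na(ps), Inf, ps))]
        selected <- c(selected, best)
        changed <- TRUE
      }
    }
    # Backward: drop any term whose removal is not significant.
    if (length(selected) > 1) {
      step <- step + 1L
      drop_ps <- vapply(selected, function(term) {
        rda_term_test(prep$Y, constraints, setdiff(selected, term), term,
                      permutations,
                      substream_seed(seed, paste0("bwd/", step, "/", term)))$p
      }, numeric(1))
      path[[length(path) + 1L]] <- tibble::tibble(
        step = step, action = "backward", term = selected, p = drop_ps
      )
      worst <- which.max(drop_ps)
      if (!is.na(drop_ps[worst]) && drop_ps[worst] >= alpha) {
        selected <- selected[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(
    list(selected = selected, path = dplyr::bind_rows(path), alpha = alpha),
    class = "constraint_selection"
  )
}

#' @export
print.constraint_selection <- function(x, ...) {
  cat(sprintf("<constraint_selection> selected: %s (alpha = %g)\n",
              if (length(x$selected) > 0) paste(x$selected, collapse = " + ")
              else "(none)", x$alpha))
  invisible(x)
}
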