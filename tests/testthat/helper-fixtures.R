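# Shared fixture builders: everything is generated in code at test time.

# A small grid with the package's half-open, 0-based convention.
toy_grid <- function(n_rows = 10, n_cols = 10, origin_lon = -110,
                     origin_lat = 45, cell_size = 0.5) {
  grid_spec(n_rows, n_cols, origin_lon, origin_lat, cell_size)
}

# An env stack with two deterministic layers: `a` increases along columns,
# `b` increases along rows (southward).
toy_env <- function(grid = toy_grid(), na_cells_a = NULL, na_cells_b = NULL) {
  a <- matrix(rep(seq_len(grid$n_cols), each = grid$n_rows),
              grid$n_rows, grid$n_cols) * 1.0
  b <- matrix(rep(seq_len(grid$n_rows), grid$n_cols),
              grid$n_rows, grid$n_cols) * 1.0
  a[na_cells_a] <- NA
  b[na_cells_b] <- NA
  env_stack(grid, list(a = a, b = b))
}

# A binary map built directly from a 0/1 matrix.
toy_binary <- function(values, grid = NULL, decile = 1,
                       scenario = scenario_spec()) {
  if (is.null(grid)) {
    grid <- grid_spec(nrow(values), ncol(values), -110, 45, 0.5)
  }
  structure(list(grid = grid, values = values, decile = decile, tau = 0.5),
            class = "binary_map")
}

toy_richness <- function(values, grid = NULL, scenario = scenario_spec(),
                         n_deciles = 10) {
  if (is.null(grid)) {
    grid <- grid_spec(nrow(values), ncol(values), -110, 45, 0.5)
  }
  structure(list(grid = grid, values = values, scenario = scenario,
                 n_deciles = n_deciles),
            class = "richness_map")
}

# Occurrence table with distinct leaf-out days at given cells of a grid.
toy_occurrences <- function(grid, rows, cols, days,
                            population = "central", ids = NULL) {
  centers <- cell_center(grid, rows, cols)
  occurrence_table(tibble::tibble(
    genotype_id = ids %||% sprintf("g%03d", seq_along(days)),
    lon = centers$lon, lat = centers$lat,
    population = population, leafout_day = days
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A separable presence/background fixture on toy_env: presences sit at high
# values of layer `a`, background is everything.
separable_fixture <- function(n_pres = 20, seed = 1) {
  grid <- toy_grid(20, 20)
  env <- toy_env(grid)
  withr::with_seed(seed, {
    pres <- tibble::tibble(
      row = sample(0:19, n_pres, replace = TRUE),
      col = sample(15:19, n_pres, replace = TRUE)
    )
    bg <- sample_background(env, 400, seed = seed)
    list(grid = grid, env = env, presences = pres, background = bg)
  })
}
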