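#' Configure the synthetic landscape generator
#'
#' The generator emulates the statistical structure the stacked-decile
#' analysis assumes: four continuous environmental layers built as a
#' latitudinal gradient plus smooth spatial noise, a dendritic stream network
#' (Strahler orders 1-6) confining riparian habitat, and genotypes from three
#' latitudinal populations whose greenhouse leaf-out day is a linear function
#' of the environment at their field location plus a population offset and
#' residual noise. Future scenarios are additive layer shifts scaled by GCM,
#' RCP and period factors, so planted-niche change is analytically computable.
#'
#' Defaults mirror the study conditions: 400 genotypes split 57 (southern) /
#' 157 (central) / 186 (northern), leaf-out spanning Julian days 71-125, and
#' trait-environment relationships with earlier leaf-out at higher moisture
#' index and winter precipitation and lower relative humidity and
#' continentality. Coefficient magnitudes and noise are set so that fitted
#' decile models evaluate in the test-AUC band the method is expected to
#' reach (about 0.8-0.9).
#'
#' @param n_rows,n_cols,origin_lon,origin_lat,cell_size Grid geometry
#'   (see [grid_spec()]).
#' @param pop_sizes Named integer vector of genotypes per population.
#' @param trait_min,trait_max Endpoints of the leaf-out range (Julian days);
#'   generated traits are clipped to this range.
#' @param trait_baseline Baseline leaf-out day before environmental and
#'   population effects.
#' @param pop_offsets Named numeric vector of per-population trait offsets
#'   (days); stands in for neutral genetic structure.
#' @param trait_coefs Days of leaf-out shift per standard deviation of each
#'   environmental layer. Sign convention: negative for `cmi` and `ppt_wt`
#'   (earlier leaf-out where moister), positive for `rh` and `td`.
#' @param trait_noise_sd Residual trait noise, days.
#' @param layer_params Named list of `c(center, lat_range, noise_amp)` per
#'   continuous layer: value = center + lat_range * (latitude fraction - 1/2)
#'   + noise_amp * smooth noise. Latitude fraction is 1 at the northern edge.
#' @param noise_spacing Coarse-knot spacing (cells) of the smooth spatial
#'   noise field.
#' @param stream_spacing Coarse-lattice spacing (cells) of the stream network.
#' @param shift_base Named additive shifts (layer units) defining the
#'   full-strength climate-change signal per layer.
#' @param gcm_factors,rcp_factors,period_factors Named multipliers applied to
#'   `shift_base` for each scenario; the realized shift is their product.
#' @param seed Master seed; named substreams are derived from it so each
#'   generator stage draws independently.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_rows = 150, n_cols = 100,
    origin_lon = -112, origin_lat = 47, cell_size = 0.05,
    pop_sizes = c(southern = 57, central = 157, northern = 186),
    trait_min = 71, trait_max = 125, trait_baseline = 98,
    pop_offsets = c(southern = 5, central = 0, northern = -5),
    trait_coefs = c(cmi = -5, ppt_wt = -3, rh = 2.5, td = 2.5),
    trait_noise_sd = 8,
    layer_params = list(
      cmi    = c(center = 30,  lat_range = 30,  noise_amp = 8),
      ppt_wt = c(center = 120, lat_range = 80,  noise_amp = 25),
      rh     = c(center = 55,  lat_range = -20, noise_amp = 5),
      td     = c(center = 30,  lat_range = -10, noise_amp = 3)
    ),
    noise_spacing = 15,
    stream_spacing = 3,
    shift_base = c(cmi = -3, ppt_wt = -8, rh = -1.5, td = 1),
    gcm_factors = c("inm-cm4" = 0.8, "mpi-esm-lr" = 1.0, "gfdl-cm3" = 1.2),
    rcp_factors = c("4.5" = 0.75, "8.5" = 1.25),
    period_factors = c("2050s" = 0.8, "2080s" = 1.2),
    seed = 1L) {
  if (any(pop_sizes < 0) || all(pop_sizes == 0)) {
    ts_abort("population sizes must be >= 0 with at least one > 0",
             "config_invalid")
  }
  if (!(trait_min < trait_max)) {
    ts_abort("trait endpoints must be ordered (trait_min < trait_max)",
             "config_invalid")
  }
  if (trait_noise_sd < 0) {
    ts_abort("trait_noise_sd must be >= 0", "config_invalid")
  }
  structure(
    list(
      grid = grid_spec(n_rows, n_cols, origin_lon, origin_lat, cell_size),
      pop_sizes = pop_sizes,
      trait_min = trait_min, trait_max = trait_max,
      trait_baseline = trait_baseline,
      pop_offsets = pop_offsets,
      trait_coefs = trait_coefs,
      trait_noise_sd = trait_noise_sd,
      layer_params = layer_params,
      noise_spacing = noise_spacing,
      stream_spacing = stream_spacing,
      shift_base = shift_base,
      gcm_factors = gcm_factors,
      rcp_factors = rcp_factors,
      period_factors = period_factors,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Smooth spatial noise: standard-normal knots on a coarse lattice,
# bilinearly interpolated to the full grid.
smooth_noise_field <- function(n_rows, n_cols, spacing) {
  cr <- ceiling(n_rows / spacing) + 1L
  cc <- ceiling(n_cols / spacing) + 1L
  z <- matrix(rnorm(cr * cc), cr, cc)
  ri <- (seq_len(n_rows) - 1) / spacing
  ci <- (seq_len(n_cols) - 1) / spacing
  r0 <- pmin(floor(ri), cr - 2)
  rf <- ri - r0
  c0 <- pmin(floor(ci), cc - 2)
  cf <- ci - c0
  out <- matrix(0, n_rows, n_cols)
  for (j in seq_len(n_cols)) {
    za <- z[, c0[j] + 1L]
    zb <- z[, c0[j] + 2L]
    v0 <- za[r0 + 1L] * (1 - rf) + za[r0 + 2L] * rf
    v1 <- zb[r0 + 1L] * (1 - rf) + zb[r0 + 2L] * rf
    out[, j] <- v0 * (1 - cf[j]) + v1 * cf[j]
  }
  out
}

# Random spanning tree on a coarse lattice (randomized DFS), rasterized to
# the grid with Strahler orders. Returns an integer matrix, 0 off-stream.
simulate_stream_network <- function(grid, spacing) {
  nr <- max(2L, grid$n_rows %/% spacing)
  nc <- max(2L, grid$n_cols %/% spacing)
  n <- nr * nc
  id <- function(i, j) (j - 1L) * nr + i
  neighbours <- function(v) {
    i <- (v - 1L) %% nr + 1L
    j <- (v - 1L) %/% nr + 1L
    out <- integer(0)
    if (i > 1L) out <- c(out, id(i - 1L, j))
    if (i < nr) out <- c(out, id(i + 1L, j))
    if (j > 1L) out <- c(out, id(i, j - 1L))
    if (j < nc) out <- c(out, id(i, j + 1L))
    out
  }
  # Root at the southern edge: the outlet of the dendritic network.
  root <- id(nr, sample.int(nc, 1))
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  stack <- root
  visited[root] <- TRUE
  order_visited <- integer(0)
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order_visited <- c(order_visited, v)
    nb <- neighbours(v)
    nb <- nb[!visited[nb]]
    if (length(nb) > 1) nb <- sample(nb)
    for (u in nb) {
      visited[u] <- TRUE
      parent[u] <- v
      stack <- c(stack, u)
    }
  }
  children <- split(which(!is.na(parent)), parent[!is.na(parent)])
  # Strahler order per node, children before parents (reverse DFS order).
  strahler <- rep(1L, n)
  for (v in rev(order_visited)) {
    ch <- children[[as.character(v)]]
    if (length(ch) > 0) {
      m <- max(strahler[ch])
      strahler[v] <- if (sum(strahler[ch] == m) >= 2) m + 1L else m
    }
  }
  strahler <- pmin(strahler, 6L)
  # Rasterize: each child-parent edge is a straight run of cells carrying the
  # child's order; a cell shared by several edges keeps the highest order.
  node_row <- function(v) pmin(((v - 1L) %% nr) * spacing + spacing %/% 2L,
                               grid$n_rows - 1L)
  node_col <- function(v) pmin(((v - 1L) %/% nr) * spacing + spacing %/% 2L,
                               grid$n_cols - 1L)
  so <- matrix(0L, grid$n_rows, grid$n_cols)
  for (v in which(!is.na(parent))) {
    p <- parent[v]
    r1 <- node_row(v); c1 <- node_col(v)
    r2 <- node_row(p); c2 <- node_col(p)
    rr <- if (r1 == r2) rep(r1, abs(c2 - c1) + 1L) else r1:r2
    cc <- if (c1 == c2) rep(c1, abs(r2 - r1) + 1L) else c1:c2
    idx <- cbind(rr + 1L, cc + 1L)
    so[idx] <- pmax(so[idx], strahler[v])
  }
  so
}

get_named <- function(vec, name, default) {
  if (is.null(vec) || !name %in% names(vec)) return(default)
  unname(vec[[name]])
}

scenario_shift <- function(cfg, scenario, layer) {
  if (scenario$period == "current") return(0)
  base <- get_named(cfg$shift_base, layer, 0)
  if (is.na(base) || base == 0) return(0)
  base *
    get_named(cfg$gcm_factors, scenario$gcm, 1) *
    get_named(cfg$rcp_factors, scenario$rcp, 1) *
    get_named(cfg$period_factors, scenario$period, 1)
}

#' Simulate an environmental raster stack
#'
#' Builds the four continuous layers (latitudinal gradient plus smooth
#' spatial noise) and the stream-order layer for one scenario. Future
#' scenarios are the current stack plus configured additive shifts scaled by
#' GCM/RCP/period factors -- noise is never resimulated, so the same master
#' seed yields bit-identical current layers under every scenario.
#'
#' @param cfg A [synthetic_config()].
#' @param scenario A [scenario_spec()]; default is the current baseline.
#' @return An [env_stack()] with layers `cmi`, `ppt_wt`, `rh`, `td`,
#'   `stream_order`.
#' @export
simulate_environment <- function(cfg, scenario = scenario_spec()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  grid <- cfg$grid
  latfrac <- matrix(
    rep(1 - (seq_len(grid$n_rows) - 0.5) / grid$n_rows, grid$n_cols),
    grid$n_rows, grid$n_cols
  )
  layers <- list()
  for (nm in names(cfg$layer_params)) {
    p <- cfg$layer_params[[nm]]
    noise <- withr::with_seed(
      substream_seed(cfg$seed, paste0("environment/", nm)),
      smooth_noise_field(grid$n_rows, grid$n_cols, cfg$noise_spacing)
    )
    layers[[nm]] <- p[["center"]] + p[["lat_range"]] * (latfrac - 0.5) +
      p[["noise_amp"]] * noise + scenario_shift(cfg, scenario, nm)
  }
  layers$stream_order <- withr::with_seed(
    substream_seed(cfg$seed, "stream"),
    simulate_stream_network(grid, cfg$stream_spacing)
  )
  storage.mode(layers$stream_order) <- "double"
  env_stack(grid, layers, valid_mask = matrix(TRUE, grid$n_rows, grid$n_cols))
}

# 0-based row bands per population: northern third / central third / southern
# third of the grid's rows.
population_bands <- function(grid) {
  b1 <- grid$n_rows %/% 3
  b2 <- 2L * (grid$n_rows %/% 3)
  list(
    northern = c(0L, b1 - 1L),
    central = c(b1, b2 - 1L),
    southern = c(b2, grid$n_rows - 1L)
  )
}

#' Extent masks for the population latitude bands
#'
#' Watershed-style reporting extents for the synthetic landscape: each
#' population's latitudinal third of the grid.
#'
#' @param grid A [grid_spec()].
#' @return Named list of logical matrices, one per population.
#' @export
population_extents <- function(grid) {
  bands <- population_bands(grid)
  lapply(bands, function(b) {
    m <- matrix(FALSE, grid$n_rows, grid$n_cols)
    m[(b[1] + 1L):(b[2] + 1L), ] <- TRUE
    m
  })
}

#' Simulate population-structured genotypes
#'
#' Draws genotype locations on stream cells only (riparian confinement), each
#' population confined to its latitude band, and assigns each genotype a
#' leaf-out day: baseline + per-layer coefficients times the standardized
#' environment at its cell + population offset + Gaussian noise, rounded half
#' away from zero and clipped to the configured trait range.
#'
#' @param env Current-scenario [env_stack()] with a `stream_order` layer.
#' @param cfg A [synthetic_config()].
#' @return An [occurrence_table()] with `nrow = sum(cfg$pop_sizes)`.
#' @export
simulate_populations <- function(env, cfg) {
  stopifnot(inherits(env, "env_stack"), inherits(cfg, "synthetic_config"))
  grid <- env$grid
  so <- env$layers$stream_order
  bands <- population_bands(grid)
  cont <- names(cfg$trait_coefs)
  # Standardize layers over valid cells (generator-internal z-scores).
  zstats <- lapply(cont, function(nm) {
    v <- env$layers[[nm]][env$valid_mask]
    c(mean = mean(v), sd = sd(v))
  })
  names(zstats) <- cont
  rows <- list()
  withr::with_seed(substream_seed(cfg$seed, "populations"), {
    for (pop in names(cfg$pop_sizes)) {
      n <- cfg$pop_sizes[[pop]]
      if (n == 0) next
      b <- bands[[pop]]
      cells <- which(so >= 1 & env$valid_mask &
                       row(so) - 1L >= b[1] & row(so) - 1L <= b[2])
      if (length(cells) < n) {
        ts_abort(sprintf(
          "insufficient stream cells for population '%s' (%d available, %d needed)",
          pop, length(cells), n), "capacity")
      }
      pick <- sample(cells, n)
      r0 <- (pick - 1L) %% grid$n_rows
      c0 <- (pick - 1L) %/% grid$n_rows
      effect <- rep(cfg$trait_baseline + cfg$pop_offsets[[pop]], n)
      for (nm in cont) {
        z <- (env$layers[[nm]][pick] - zstats[[nm]]["mean"]) / zstats[[nm]]["sd"]
        effect <- effect + cfg$trait_coefs[[nm]] * z
      }
      effect <- effect + rnorm(n, sd = cfg$trait_noise_sd)
      day <- pmin(pmax(round_half_away(effect), cfg$trait_min), cfg$trait_max)
      centers <- cell_center(grid, r0, c0)
      rows[[pop]] <- tibble::tibble(
        genotype_id = sprintf("%s_%03d", substr(pop, 1, 1), seq_len(n)),
        lon = centers$lon, lat = centers$lat,
        population = pop, leafout_day = as.integer(day)
      )
    }
  })
  occurrence_table(dplyr::bind_rows(rows))
}

#' Plant analytically known decile niches
#'
#' Partitions one driver layer's value range (over stream cells, current
#' scenario) into `n_bins` contiguous bands; decile `d` is "truly suitable"
#' at a stream cell when the driver falls inside band `d` widened by
#' `overlap` band-widths on each side. Future scenarios are evaluated by
#' shifting the driver (per the config's scenario shifts) against the same
#' band edges, so true decile loss under climate change is exact. The result
#' is the parameter-recovery oracle for the fitted pipeline.
#'
#' @param env Current-scenario [env_stack()].
#' @param cfg A [synthetic_config()].
#' @param scenarios List of [scenario_spec()]s to evaluate (default: current
#'   only).
#' @param driver Name of the driver layer (default `"cmi"`).
#' @param overlap Band widening, in band-widths per side.
#' @param n_bins Number of bands/deciles.
#' @param breaks `"width"` (equal-width bands over the driver's value range)
#'   or `"quantile"` (bands holding equal shares of the stream cells; the
#'   natural counterpart of equal-count trait deciles when the trait tracks
#'   the driver).
#' @param descending If `TRUE`, decile 1 sits at the top of the driver range
#'   (the natural pairing when the trait-driver coefficient is negative, as
#'   earliest leaf-out then occurs at the highest driver values). Default is
#'   chosen from the sign of `cfg$trait_coefs[driver]`.
#' @return A `truth_record`: band edges plus, per scenario, an integer matrix
#'   of true decile bitmasks (bit `d - 1` set when decile `d` is truly
#'   suitable; 0 off-stream or outside every band).
#' @export
plant_decile_niches <- function(env, cfg, scenarios = list(scenario_spec()),
                                driver = "cmi", overlap = 0.5, n_bins = 10,
                                descending = NULL,
                                breaks = c("width", "quantile")) {
  stopifnot(inherits(env, "env_stack"))
  breaks <- match.arg(breaks)
  if (is.null(descending)) {
    descending <- get_named(cfg$trait_coefs, driver, 1) < 0
  }
  stream <- env$layers$stream_order >= 1 & env$valid_mask
  v <- env$layers[[driver]][stream]
  if (length(unique(v)) < 2 || diff(range(v)) == 0) {
    ts_abort(sprintf("driver layer '%s' is (near) constant on stream cells",
                     driver), "degenerate_driver")
  }
  edges <- if (breaks == "width") {
    seq(min(v), max(v), length.out = n_bins + 1)
  } else {
    unname(quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
  }
  widths <- diff(edges)
  sets <- list()
  for (sc in scenarios) {
    shifted <- env$layers[[driver]] + scenario_shift(cfg, sc, driver)
    mask <- matrix(0L, env$grid$n_rows, env$grid$n_cols)
    for (b in seq_len(n_bins)) {
      lo <- edges[b] - overlap * widths[b]
      hi <- edges[b + 1] + overlap * widths[b]
      inband <- stream & shifted >= lo &
        (shifted < hi | (b == n_bins & shifted <= hi))
      d <- if (descending) n_bins + 1L - b else b
      mask[inband] <- bitwOr(mask[inband], as.integer(2^(d - 1L)))
    }
    sets[[scenario_label(sc)]] <- mask
  }
  structure(
    list(driver = driver, edges = edges, overlap = overlap,
         descending = descending, n_bins = n_bins, breaks = breaks,
         grid = env$grid, stream_mask = stream, sets = sets),
    class = "truth_record"
  )
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf(
    "<truth_record> %d planted bands on '%s' (%s), %d stream cells, scenarios: %s\n",
    x$n_bins, x$driver, if (x$descending) "descending" else "ascending",
    sum(x$stream_mask), paste(names(x$sets), collapse = ", ")
  ))
  invisible(x)
}
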