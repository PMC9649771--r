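#' Stack binary decile maps into a richness map
#'
#' Cell-wise sum of the per-decile binary presence-absence maps: the value at
#' a cell is the number of trait deciles whose climatic niche is predicted
#' suitable there (0-10, the "decile richness"). Nodata propagates: a cell is
#' nodata in the richness map when any contributing map is nodata there.
#'
#' @param binaries List of `binary_map` objects on one grid (one per decile).
#' @param scenario The [scenario_spec()] the maps belong to.
#' @return A `richness_map`: list with `grid`, `values` (integer matrix),
#'   `scenario`, `n_deciles`.
#' @export
stack_richness <- function(binaries, scenario = scenario_spec()) {
  stopifnot(length(binaries) >= 1)
  grid <- binaries[[1]]$grid
  for (b in binaries) {
    if (!inherits(b, "binary_map") || !grids_equal(b$grid, grid)) {
      ts_abort("binary maps do not share one grid", "grid_mismatch")
    }
  }
  vals <- Reduce(`+`, lapply(binaries, function(b) b$values))
  structure(
    list(grid = grid, values = vals, scenario = scenario,
         n_deciles = length(binaries)),
    class = "richness_map"
  )
}

#' @export
print.richness_map <- function(x, ...) {
  cat(sprintf(
    "<richness_map> %s: %d deciles, richness %d-%d over %d valid cells\n",
    scenario_label(x$scenario), x$n_deciles,
    min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
    sum(!is.na(x$values))
  ))
  invisible(x)
}

#' Richness change between scenarios
#'
#' Cell-wise `future - current` richness, in -10..10. Cells whose current
#' richness is 0 are flagged in `unsuitable_baseline_mask`, disambiguating
#' "no change" zeros from "nothing there to begin with" zeros.
#'
#' @param current,future `richness_map`s on one grid; `current` must be the
#'   baseline scenario.
#' @return A `change_map`: `grid`, `delta` (integer matrix),
#'   `unsuitable_baseline_mask`, `scenario` (the future one).
#' @export
richness_change <- function(current, future) {
  stopifnot(inherits(current, "richness_map"), inherits(future, "richness_map"))
  if (!grids_equal(current$grid, future$grid)) {
    ts_abort("richness maps are on different grids", "grid_mismatch")
  }
  if (current$scenario$period != "current") {
    ts_abort("`current` must carry the baseline scenario", "scenario_mismatch")
  }
  structure(
    list(
      grid = current$grid,
      delta = future$values - current$values,
      unsuitable_baseline_mask = !is.na(current$values) & current$values == 0,
      scenario = future$scenario
    ),
    class = "change_map"
  )
}

#' Summarize richness change over an extent
#'
#' Percent loss is the share of denominator cells with negative change,
#' percent gain the share with positive change, and net loss their
#' difference; magnitude of change is tabulated separately (a loss of 2 and a
#' loss of 7 both count once as "loss"). Under the default `"all_valid"`
#' denominator rule the denominator is every valid cell of the extent; the
#' `"suitable_only"` variant restricts to cells that were suitable for at
#' least one decile under current conditions.
#'
#' @param chg A [richness_change()] map.
#' @param extent_mask Optional logical matrix naming the reporting extent
#'   (default: all valid cells).
#' @param denominator_rule `"all_valid"` or `"suitable_only"`.
#' @param extent_label Label carried into the summary row.
#' @return A `change_summary` one-row tibble: extent, scenario fields,
#'   `denominator`, `percent_loss`, `percent_gain`, `net_loss`, and one
#'   `delta_*` column per change value -10..10.
#' @export
summarize_change <- function(chg, extent_mask = NULL,
                             denominator_rule = c("all_valid", "suitable_only"),
                             extent_label = "range") {
  stopifnot(inherits(chg, "change_map"))
  denominator_rule <- match.arg(denominator_rule)
  in_extent <- !is.na(chg$delta)
  if (!is.null(extent_mask)) {
    stopifnot(all(dim(extent_mask) == dim(chg$delta)))
    in_extent <- in_extent & extent_mask
  }
  if (denominator_rule == "suitable_only") {
    in_extent <- in_extent & !chg$unsuitable_baseline_mask
  }
  denom <- sum(in_extent)
  if (denom == 0) ts_abort("empty extent", "empty_extent")
  d <- chg$delta[in_extent]
  hist_counts <- vapply(-10:10, function(k) sum(d == k), integer(1))
  hist <- tibble::as_tibble(as.list(stats::setNames(
    hist_counts, sprintf("delta_%d", -10:10)
  )))
  out <- dplyr::bind_cols(
    tibble::tibble(
      extent = extent_label,
      denominator_rule = denominator_rule,
      denominator = denom,
      percent_loss = 100 * sum(d < 0) / denom,
      percent_gain = 100 * sum(d > 0) / denom,
      net_loss = 100 * (sum(d < 0) - sum(d > 0)) / denom
    ),
    scenario_fields(chg$scenario), hist
  )
  structure(out, class = c("change_summary", class(out)))
}

#' Average change summaries across GCMs
#'
#' Reporting-layer mean of net loss over the GCMs for each extent x RCP x
#' period combination, with a t-based 95% confidence interval on that mean.
#'
#' @param summaries A tibble of stacked [summarize_change()] rows.
#' @return Tibble with `extent`, `rcp`, `period`, `n_gcm`, `net_loss_mean`,
#'   `net_loss_lo`, `net_loss_hi`.
#' @export
summarize_across_gcms <- function(summaries) {
  tibble::as_tibble(summaries) |>
    dplyr::group_by(.data$extent, .data$denominator_rule, .data$rcp,
                    .data$period) |>
    dplyr::summarise(
      n_gcm = dplyr::n(),
      net_loss_mean = mean(.data$net_loss),
      net_loss_sd = sd(.data$net_loss),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      half = ifelse(.data$n_gcm > 1,
                    qt(0.975, .data$n_gcm - 1) *
                      .data$net_loss_sd / sqrt(.data$n_gcm), NA_real_),
      net_loss_lo = .data$net_loss_mean - .data$half,
      net_loss_hi = .data$net_loss_mean + .data$half
    ) |>
    dplyr::select(-"half")
}

#' Percent of landscape area, printed convention
#'
#' `100 * count_suitable / count_total` rounded half-up to one decimal, the
#' convention used for reporting suitable area as percent of the modeled
#' landscape.
#'
#' @param count_suitable,count_total Cell counts (`count_total > 0`,
#'   `count_suitable <= count_total`).
#' @return Percentage with one decimal.
#' @export
percent_area <- function(count_suitable, count_total) {
  if (any(count_total <= 0)) ts_abort("count_total must be > 0", "bad_count")
  if (any(count_suitable > count_total) || any(count_suitable < 0)) {
    ts_abort("count_suitable must lie in [0, count_total]", "bad_count")
  }
  x <- 100 * count_suitable / count_total
  floor(x * 10 + 0.5) / 10
}

#' Frequency of the tail deciles over the suitable landscape
#'
#' For each requested decile, the number of extent cells where that decile is
#' predicted present divided by the number of extent cells with richness of
#' at least 1. Undefined (no suitable cells) is reported as `NA`, not 0.
#'
#' @param binaries List of `binary_map`s (indexed by their `decile` field).
#' @param richness The matching [stack_richness()] map.
#' @param extent_mask Optional logical extent matrix.
#' @param deciles Decile indices to report (default the tails, 1 and 10).
#' @return Tibble with `decile`, `n_cells`, `n_suitable`, `frequency` plus
#'   scenario fields.
#' @export
tail_frequency <- function(binaries, richness, extent_mask = NULL,
                           deciles = c(1, 10)) {
  stopifnot(inherits(richness, "richness_map"))
  in_extent <- !is.na(richness$values)
  if (!is.null(extent_mask)) in_extent <- in_extent & extent_mask
  n_suitable <- sum(richness$values[in_extent] >= 1)
  by_decile <- stats::setNames(binaries,
                               vapply(binaries, function(b) format(b$decile),
                                      character(1)))
  purrr::map_dfr(deciles, function(d) {
    b <- by_decile[[format(d)]]
    if (is.null(b)) ts_abort(sprintf("no binary map for decile %d", d),
                             "missing_decile")
    if (!grids_equal(b$grid, richness$grid)) {
      ts_abort("binary and richness maps are on different grids",
               "grid_mismatch")
    }
    n_cells <- sum(b$values[in_extent] == 1, na.rm = TRUE)
    dplyr::bind_cols(
      tibble::tibble(
        decile = d, n_cells = n_cells, n_suitable = n_suitable,
        frequency = if (n_suitable > 0) n_cells / n_suitable else NA_real_
      ),
      scenario_fields(richness$scenario)
    )
  })
}
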