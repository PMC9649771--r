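#' Partition genotypes into trait deciles
#'
#' Sorts genotypes by `(leafout_day, genotype_id)` and cuts the sorted order
#' at the ideal boundaries `i * n / n_bins`; position `p` ideally belongs to
#' bin `ceiling(p * n_bins / n)`. Because no trait value may span two
#' deciles, any group of genotypes sharing a trait value that straddles a
#' boundary moves entirely into the earlier (lower) decile -- decile 1, the
#' earliest leaf-out, is kept maximal. Bin sizes are whatever the cut
#' produces; there is no rebalancing.
#'
#' @param occ An [occurrence_table()] (>= `n_bins` genotypes).
#' @param n_bins Number of trait bins (default 10, i.e. deciles).
#' @return A `decile_assignment`: a tibble with columns `genotype_id`,
#'   `leafout_day`, `population`, `decile`, carrying a `summary` attribute
#'   (per-decile size and trait range).
#' @export
assign_deciles <- function(occ, n_bins = 10) {
  occ <- occurrence_table(occ)
  n <- nrow(occ)
  if (n < n_bins) {
    ts_abort(sprintf("need at least %d genotypes, got %d", n_bins, n),
             "degenerate_input")
  }
  ord <- order(occ$leafout_day, occ$genotype_id)
  sorted <- occ[ord, ]
  ideal <- ceiling(seq_len(n) * n_bins / n)
  # Collapse each tie group (equal trait value) to its lowest straddled bin.
  decile <- stats::ave(ideal, sorted$leafout_day, FUN = min)
  out <- tibble::tibble(
    genotype_id = sorted$genotype_id,
    leafout_day = sorted$leafout_day,
    population = sorted$population,
    decile = as.integer(decile)
  )
  empty <- setdiff(seq_len(n_bins), unique(out$decile))
  n_distinct_vals <- length(unique(occ$leafout_day))
  if (length(empty) > 0) {
    msg <- sprintf("empty decile(s): %s", paste(empty, collapse = ", "))
    if (n_distinct_vals < n_bins) {
      ts_abort(paste0("fewer than ", n_bins, " distinct trait values; ", msg),
               "degenerate_input")
    }
    warn(paste0("tie handling produced ", msg))
  }
  summary <- out |>
    dplyr::group_by(.data$decile) |>
    dplyr::summarise(
      n = dplyr::n(),
      day_min = min(.data$leafout_day),
      day_max = max(.data$leafout_day),
      .groups = "drop"
    )
  structure(out, summary = summary, n_bins = n_bins,
            class = c("decile_assignment", class(out)))
}

#' @rdname assign_deciles
#' @param assign A `decile_assignment`.
#' @export
decile_summary <- function(assign) {
  attr(assign, "summary")
}

#' Spatially thin per-decile presences
#'
#' Maps each genotype to its grid cell and keeps, within each decile, at most
#' one genotype per cell (the first in `(leafout_day, genotype_id)` order),
#' eliminating pseudo-replication. The same cell may legitimately appear in
#' several deciles' presence sets. Thinning is idempotent.
#'
#' @param assign A [assign_deciles()] result.
#' @param occ The matching [occurrence_table()] (provides coordinates).
#' @param grid A [grid_spec()]; every occurrence must fall inside its extent.
#' @return A `presence_sets` tibble with columns `decile`, `genotype_id`,
#'   `leafout_day`, `lon`, `lat`, `row`, `col` (0-based cells).
#' @export
thin_presences <- function(assign, occ, grid) {
  stopifnot(inherits(assign, "decile_assignment"))
  occ <- occurrence_table(occ)
  joined <- dplyr::inner_join(
    tibble::as_tibble(assign)[, c("genotype_id", "leafout_day", "decile")],
    tibble::as_tibble(occ)[, c("genotype_id", "lon", "lat")],
    by = "genotype_id"
  )
  cells <- point_to_cell(grid, joined$lon, joined$lat)
  outside <- which(!cells$in_extent)
  if (length(outside) > 0) {
    ts_abort(sprintf("occurrence(s) outside the grid extent: %s",
                     paste(joined$genotype_id[outside], collapse = ", ")),
             "out_of_extent")
  }
  joined$row <- cells$row
  joined$col <- cells$col
  out <- joined |>
    dplyr::arrange(.data$decile, .data$leafout_day, .data$genotype_id) |>
    dplyr::distinct(.data$decile, .data$row, .data$col, .keep_all = TRUE) |>
    dplyr::select("decile", "genotype_id", "leafout_day", "lon", "lat",
                  "row", "col")
  structure(out, class = c("presence_sets", class(out)))
}

#' Per-decile presence counts after thinning
#'
#' @param presences A [thin_presences()] result.
#' @return Tibble with columns `decile`, `n_occ`.
#' @export
presence_counts <- function(presences) {
  tibble::as_tibble(presences) |>
    dplyr::count(.data$decile, name = "n_occ")
}

#' Write the thinned presence sets to CSV for audit
#'
#' @param presences A [thin_presences()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_presences <- function(presences, path) {
  readr::write_csv(tibble::as_tibble(presences), path, progress = FALSE)
  invisible(path)
}
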