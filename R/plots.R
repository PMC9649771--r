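# ggplot2 visualizations for the map and result types.

raster_tiles <- function(grid, values, name) {
  idx <- which(!is.na(values), arr.ind = TRUE)
  centers <- cell_center(grid, idx[, 1] - 1L, idx[, 2] - 1L)
  tibble::tibble(lon = centers$lon, lat = centers$lat,
                 value = values[idx]) |>
    stats::setNames(c("lon", "lat", name))
}

#' Plot a decile-richness map
#'
#' @param object A [stack_richness()] map.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.richness_map <- function(object, ...) {
  df <- raster_tiles(object$grid, object$values, "richness")
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$richness)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, object$n_deciles)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste("Trait-decile richness,",
                    scenario_label(object$scenario)),
      x = "Longitude", y = "Latitude", fill = "Richness"
    )
}

#' Plot a richness-change map
#'
#' Diverging palette on the -10..10 change scale; cells unsuitable at
#' baseline are drawn grey so their zeros are not mistaken for stability.
#'
#' @param object A [richness_change()] map.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.change_map <- function(object, ...) {
  vals <- object$delta
  vals[object$unsuitable_baseline_mask & vals == 0] <- NA
  df <- raster_tiles(object$grid, vals, "delta")
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$delta)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "#f7f7f7",
                                  high = "#2166ac", limits = c(-10, 10)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste("Richness change,", scenario_label(object$scenario)),
      x = "Longitude", y = "Latitude", fill = expression(Delta ~ "richness")
    )
}

#' Plot per-decile model evaluation
#'
#' Test AUC (mean over the cross-validation folds, +/- one standard
#' deviation) and training AUC by trait decile.
#'
#' @param evaluation The per-decile evaluation tibble from [run_pipeline()]
#'   (or stacked [crossvalidate()] rows).
#' @return A ggplot.
#' @export
plot_evaluation <- function(evaluation) {
  ggplot2::ggplot(evaluation, ggplot2::aes(.data$decile)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$test_auc_mean,
      ymin = .data$test_auc_mean - .data$test_auc_sd,
      ymax = .data$test_auc_mean + .data$test_auc_sd
    )) +
    ggplot2::geom_point(ggplot2::aes(y = .data$train_auc), shape = 1) +
    ggplot2::scale_x_continuous(breaks = evaluation$decile) +
    ggplot2::labs(x = "Trait decile", y = "AUC",
                  title = "Decile model evaluation (filled: test, open: train)")
}

#' Plot similarity trajectories
#'
#' Per-population trait-distribution similarity across scenarios, with the
#' current baseline as a dashed reference; points above the baseline indicate
#' converging (narrowing) trait distributions.
#'
#' @param similarity A [scenario_similarity()] tibble.
#' @return A ggplot.
#' @export
plot_similarity <- function(similarity) {
  sim <- tibble::as_tibble(similarity)
  fut <- dplyr::filter(sim, .data$period != "current")
  base <- dplyr::filter(sim, .data$period == "current")
  ggplot2::ggplot(fut, ggplot2::aes(.data$period, .data$similarity,
                                    colour = .data$gcm,
                                    shape = .data$rcp)) +
    ggplot2::geom_point(size = 2, position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_hline(data = base,
                        ggplot2::aes(yintercept = .data$similarity),
                        linetype = "dashed", colour = "goldenrod") +
    ggplot2::facet_wrap(~population) +
    ggplot2::labs(x = "Period", y = "Similarity",
                  title = "Trait-distribution similarity vs current baseline")
}
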