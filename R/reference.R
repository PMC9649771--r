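#' Published decile-model evaluation reference
#'
#' The published evaluation summary of the original field study's ten
#' leaf-out decile distribution models: occurrence count after thinning,
#' pixels predicted suitable under current climate, percent of the modeled
#' landscape (156,659 pixels total; the stacked models covered 53,727
#' pixels), 5-fold test AUC (mean and sd), training AUC, and training
#' omission rate under the 10% training-presence threshold. Used by the
#' reporting helpers and consistency checks; the study's occurrence and
#' climate data themselves are not redistributable.
#'
#' @return A tibble with one row per decile: `decile`, `n_occ`,
#'   `pixels_suitable`, `pct_area`, `test_auc`, `test_auc_sd`, `train_auc`,
#'   `omission_rate`.
#' @export
decile_reference <- function() {
  path <- system.file("extdata", "decile_model_reference.csv",
                      package = "traitstack", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Landscape constants of the reference analysis
#'
#' Total modeled landscape (pixels) and the stacked-model suitable pixel
#' count of the reference analysis summarized by [decile_reference()].
#'
#' @return Named list with `total_pixels` and `stacked_pixels`.
#' @export
reference_landscape <- function() {
  list(total_pixels = 156659L, stacked_pixels = 53727L)
}
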