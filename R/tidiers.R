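# broom-style tidiers for the package's fitted objects.

#' Tidy an SDM model's coefficients
#'
#' @param x An [fit_sdm()] model.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`.
#' @export
tidy.sdm_model <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' One-row summary of an SDM model
#'
#' @param x An [fit_sdm()] model.
#' @param ... Unused.
#' @return Tibble with decile, sizes, penalty, iterations, threshold and
#'   omission rate.
#' @export
glance.sdm_model <- function(x, ...) {
  tibble::tibble(
    decile = x$decile,
    n_presence = nrow(x$presence_cells),
    n_background = nrow(x$background_cells),
    n_features = length(x$beta),
    lambda = x$lambda,
    n_iter = x$n_iter,
    tau10 = x$tau10,
    omission_rate = x$omission_rate
  )
}

#' Tidy a constrained-ordination result
#'
#' @param x An [rda_communities()] result.
#' @param ... Unused.
#' @return Tibble with one row per constraint: `term`, `marginal_fraction`.
#' @export
tidy.trait_rda <- function(x, ...) {
  tibble::tibble(term = x$terms,
                 marginal_fraction = unname(x$marginal_fractions))
}

#' One-row summary of a constrained-ordination result
#'
#' @param x An [rda_communities()] result.
#' @param ... Unused.
#' @return Tibble with `constrained_fraction`, `p_value`, `permutations`,
#'   `n_rows`.
#' @export
glance.trait_rda <- function(x, ...) {
  tibble::tibble(
    constrained_fraction = x$constrained_fraction,
    p_value = x$p_value,
    permutations = x$permutations,
    n_rows = x$n_rows
  )
}

#' Tidy a community matrix into long format
#'
#' Sparse long form: one row per (population x scenario, occupied decile
#' combination), with the combination decoded into its decile set and
#' richness.
#'
#' @param x A [build_community_matrix()] result.
#' @param ... Unused.
#' @return Tibble with `population`, scenario fields, `mask`, `deciles`
#'   (slash-separated), `richness`, `n_cells`.
#' @export
tidy.community_matrix <- function(x, ...) {
  long <- tibble::as_tibble(x$counts) |>
    dplyr::bind_cols(x$meta) |>
    tidyr::pivot_longer(dplyr::starts_with("m"), names_to = "mask_id",
                        values_to = "n_cells") |>
    dplyr::filter(.data$n_cells > 0) |>
    dplyr::mutate(mask = as.integer(sub("^m", "", .data$mask_id)))
  long$deciles <- vapply(long$mask, function(m) {
    paste(decode_combination(m), collapse = "/")
  }, character(1))
  long$richness <- popcount10(long$mask)
  dplyr::select(long, "population", "gcm", "rcp", "period", "scenario",
                "mask", "deciles", "richness", "n_cells")
}

#' Tidy a decile assignment
#'
#' @param x An [assign_deciles()] result.
#' @param ... Unused.
#' @return The per-decile summary tibble (`decile`, `n`, `day_min`,
#'   `day_max`).
#' @export
tidy.decile_assignment <- function(x, ...) {
  decile_summary(x)
}
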