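#' Aggregate transect surveys to analysis rows
#'
#' The density models are fitted at the landscape-by-round level: one row
#' per (landscape, round) cell holding the arithmetic mean, across that
#' cell's transects, of bee and hoverfly densities (counts rescaled to a
#' 150 m2 transect equivalent, `count * 150 / area_m2`), of flower cover
#' and of flower richness, together with the cell's mass-flowering-crop
#' flag.  Woody and herbaceous transects are pooled unweighted.
#'
#' `level = "transect"` instead returns one row per transect (densities
#' and flower measures of that transect alone), for sensitivity analyses
#' of the aggregation choice; the column schema is identical so the same
#' model-fitting code runs on either.
#'
#' In addition to the mean cover on the percent scale
#' (`mean_flower_cover_pct`, transformed to log10 inside the model by
#' default), the mean of per-transect log10 cover is carried along
#' (`mean_log10_flower_cover`) so the alternative
#' transform-before-averaging covariate is available; zero-cover transects
#' enter that column at the 0.025% recording floor.
#'
#' @param data A [study_dataset()].
#' @param level `"cell"` (default, landscape-by-round means) or
#'   `"transect"`.
#' @return A tibble with columns `landscape_id`, `round`,
#'   `snh_cover_pct`, `radius_m`, `n_transects`, `mean_bee_density`,
#'   `mean_hoverfly_density`, `mean_flower_cover_pct`,
#'   `mean_log10_flower_cover`, `mean_flower_richness`, `mfc_flowering`.
#' @examples
#' sim <- simulate_study(default_truth(n_landscapes = 5, n_rounds = 3))
#' aggregate_observations(sim$data)
#' @export
aggregate_observations <- function(data, level = c("cell", "transect")) {
  stopifnot(inherits(data, "study_dataset"))
  level <- match.arg(level)
  s <- dplyr::left_join(data$surveys, data$landscapes, by = "landscape_id")
  if (nrow(s) == 0) stop("no surveys to aggregate", call. = FALSE)

  s$bee_density <- s$bee_count * 150 / s$area_m2
  s$hoverfly_density <- s$hoverfly_count * 150 / s$area_m2
  s$log10_cover <- log10(pmax(s$flower_cover_pct, FLOWER_COVER_FLOOR))

  if (level == "transect") {
    return(tibble::tibble(
      landscape_id = s$landscape_id,
      round = s$round,
      snh_cover_pct = s$snh_cover_pct,
      radius_m = s$radius_m,
      n_transects = 1L,
      mean_bee_density = s$bee_density,
      mean_hoverfly_density = s$hoverfly_density,
      mean_flower_cover_pct = s$flower_cover_pct,
      mean_log10_flower_cover = s$log10_cover,
      mean_flower_richness = as.numeric(s$flower_richness),
      mfc_flowering = s$mfc_flowering
    ))
  }

  s |>
    dplyr::group_by(.data$landscape_id, .data$round) |>
    dplyr::summarise(
      snh_cover_pct = .data$snh_cover_pct[1],
      radius_m = .data$radius_m[1],
      n_transects = dplyr::n(),
      mean_bee_density = mean(.data$bee_density),
      mean_hoverfly_density = mean(.data$hoverfly_density),
      mean_flower_cover_pct = mean(.data$flower_cover_pct),
      mean_log10_flower_cover = mean(.data$log10_cover),
      mean_flower_richness = mean(.data$flower_richness),
      mfc_flowering = any(.data$mfc_flowering),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$landscape_id, .data$round)
}
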