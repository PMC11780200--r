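# Fixtures are built in code; nothing is read from disk.

# minimal hand-written study: n landscapes, one round, one transect each
tiny_study <- function(n_landscapes = 2) {
  ids <- sprintf("L%02d", seq_len(n_landscapes))
  surveys <- tibble::tibble(
    landscape_id = ids,
    round = 1L,
    transect_id = "T1",
    habitat_class = "herbaceous",
    bee_count = 7L,
    hoverfly_count = 3L,
    area_m2 = 150,
    flower_cover_pct = 4.5,
    flower_richness = 12L,
    mfc_flowering = FALSE
  )
  landscapes <- tibble::tibble(
    landscape_id = ids,
    snh_cover_pct = seq(10, 60, length.out = n_landscapes),
    radius_m = 750
  )
  study_dataset(surveys, landscapes)
}

# aggregated observations built directly from a simulation's latent table,
# i.e. with the exact (unrounded) cell densities
obs_from_latent <- function(latent) {
  tibble::tibble(
    landscape_id = latent$landscape_id,
    round = latent$round,
    snh_cover_pct = latent$snh_cover_pct,
    mean_bee_density = latent$density_bee,
    mean_hoverfly_density = latent$density_hoverfly,
    mean_flower_cover_pct = latent$mean_flower_cover_pct,
    mean_log10_flower_cover = log10(latent$mean_flower_cover_pct),
    mean_flower_richness = latent$mean_flower_richness,
    mfc_flowering = latent$mfc_flowering
  )
}

# quality grid with prescribed cover/richness levels (bypasses quantiles)
manual_quality_grid <- function(cover, richness = rep(0, length(cover))) {
  tibble::tibble(
    level = seq_along(cover),
    prob = seq_along(cover) / length(cover),
    flower_cover_pct = cover,
    flower_richness = richness
  )
}

# truth whose coefficient sets are all zero except the intercepts
constant_truth <- function(intercept_bee, intercept_hov = intercept_bee, ...) {
  zero <- c(
    intercept = 0, snh = 0, log10_flower_cover = 0,
    flower_richness = 0, mfc = 0, snh_mfc = 0
  )
  bee <- zero
  bee["intercept"] <- intercept_bee
  hov <- zero
  hov["intercept"] <- intercept_hov
  default_truth(coef = list(bee = bee, hoverfly = hov), ...)
}
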