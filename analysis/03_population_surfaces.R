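#!/usr/bin/env Rscript

# Step 3: extrapolate fitted densities to landscape-level populations.
#
# Predictions on a 15 x 20 grid (SNH cover 0.35, 5, ..., 70% by flower-
# availability quantiles Q1-Q20, crop bloom held at "no", random effects
# at zero) are converted to per-m2 densities and multiplied by the
# habitat area (SNH proportion x pi x 750^2) to give population sizes per
# landscape.

library(pollscape)

mdir <- "results/models"
if (!file.exists(file.path(mdir, "aggregated.csv"))) {
  stop("run analysis/02_fit_density_models.R first", call. = FALSE)
}
out <- "results/surfaces"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

obs <- readr::read_csv(file.path(mdir, "aggregated.csv"), show_col_types = FALSE)
quality <- make_quality_grid(obs)
write_table(quality, file.path(out, "quality_grid.csv"))

for (taxon in c("bee", "hoverfly")) {
  model <- read_model_json(file.path(mdir, paste0("model_", taxon, ".json")))
  pm <- suppressWarnings(build_population_matrix(model, quality = quality))
  write_table(tibble::as_tibble(pm), file.path(out, paste0("matrix_", taxon, ".csv")))
  plot_population_surface(pm, file.path(out, paste0("population_", taxon, ".png")))
  cat(sprintf(
    "%s: population %s - %s individuals per landscape (Q1 at 0.35%% SNH vs Q20 at 70%% SNH)\n",
    taxon,
    format(round(min(pm$population)), big.mark = ","),
    format(round(max(pm$population)), big.mark = ",")
  ))
}
cat("surfaces written to", out, "\n")
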