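#!/usr/bin/env Rscript

# Step 4: the quality-vs-quantity trade-off.
#
# For each cell of the population surface, the gain from k quality steps
# is divided by the gain from one 5-point SNH step; where this ratio
# crosses 1, improving habitat quality starts to beat adding habitat.
# Thresholds are located by linear interpolation along the SNH axis for
# step ratios 1:1, 2:1 and 3:1, and two policy scenarios translate fixed
# SNH increases (5->10% and 15->20%) into the equivalent quality
# increase at median quality.

library(pollscape)

mdir <- "results/models"
sdir <- "results/surfaces"
if (!file.exists(file.path(sdir, "quality_grid.csv"))) {
  stop("run analysis/03_population_surfaces.R first", call. = FALSE)
}
out <- "results/tradeoff"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

obs <- readr::read_csv(file.path(mdir, "aggregated.csv"), show_col_types = FALSE)
models <- list(
  bee = read_model_json(file.path(mdir, "model_bee.json")),
  hoverfly = read_model_json(file.path(mdir, "model_hoverfly.json"))
)

report <- suppressWarnings(scenario_report(models, obs))
write_table(report, file.path(out, "scenario_report.csv"))

quality <- make_quality_grid(obs)
for (taxon in names(models)) {
  pm <- suppressWarnings(build_population_matrix(models[[taxon]], quality = quality))
  rc <- ratio_curve(pm, 1)
  plot_ratio_curves(rc, file.path(out, paste0("ratios_", taxon, ".png")))

  thr <- report[report$component == "threshold" & report$taxon == taxon, ]
  cat("==", taxon, "==\n")
  for (k in 1:3) {
    tk <- thr$value[thr$step_ratio == k]
    ok <- which(!is.na(tk))
    if (length(ok) == 0) {
      cat(sprintf("  %d:1 steps: ratio never reaches 1 within the grid\n", k))
    } else {
      cat(sprintf(
        "  %d:1 steps: break-even at %.1f%% SNH (quality level Q%d) up to Q%d (%.1f%%)\n",
        k, tk[min(ok)], min(ok), max(ok), tk[max(ok)]
      ))
    }
  }
  sc <- report[report$component == "scenario" & report$taxon == taxon &
    report$name == "required_quality_pct", ]
  for (r in seq_len(nrow(sc))) {
    cat(sprintf(
      "  scenario %s: matched by a %.0f%% habitat-quality increase\n",
      sc$scenario[r], sc$value[r]
    ))
  }
}
cat("trade-off outputs written to", out, "\n")
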