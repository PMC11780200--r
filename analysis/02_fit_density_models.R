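#!/usr/bin/env Rscript

# Step 2: fit the density models.
#
# Surveys are averaged to one row per landscape x round; wild bee
# densities are modelled on the log10 scale and hoverfly densities on the
# log10(+1) scale, each with fixed effects for SNH cover, log10 flower
# cover, flower richness, crop bloom and the SNH x bloom interaction, and
# crossed random intercepts for landscape and round.  The interaction is
# dropped when a likelihood-ratio test finds it non-significant; all main
# effects are always retained for the landscape extrapolation.

library(pollscape)

ind <- "results/synthetic"
if (!file.exists(file.path(ind, "surveys.csv"))) {
  stop("run analysis/01_simulate_study.R first", call. = FALSE)
}
out <- "results/models"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

data <- read_study(file.path(ind, "surveys.csv"), file.path(ind, "landscapes.csv"))
obs <- aggregate_observations(data)
write_table(obs, file.path(out, "aggregated.csv"))
cat(sprintf("%d landscape x round analysis rows\n\n", nrow(obs)))

for (taxon in c("bee", "hoverfly")) {
  sel <- select_model(obs, taxon)
  write_model_json(sel, file.path(out, paste0("model_", taxon, ".json")))
  cat("==", taxon, "==\n")
  cat("likelihood-ratio tests (chi-square, 1 df):\n")
  print(as.data.frame(sel$lrt_table), digits = 3)
  cat(sprintf(
    "interaction retained: %s | max VIF %.2f\n",
    sel$interaction_retained, max(sel$vif)
  ))
  print(sel$model)
  cat("\n")
}
cat("models written to", out, "\n")
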