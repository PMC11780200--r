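#!/usr/bin/env Rscript

# Step 1: generate the synthetic transect study.
#
# The generator emulates the sampling design the package targets: 26
# agricultural landscapes (750 m radius) spanning 0.35-70% seminatural
# habitat cover, 8 biweekly sampling rounds, on average 2.8 transects of
# 150 m2 per landscape and round, lognormal flower cover (geometric mean
# 2.0%) and ~13 flowering species per transect.  The ground-truth
# coefficients encode the published effect pattern: wild bee densities
# respond to flower cover only; hoverfly densities also respond to SNH
# cover and to mass-flowering-crop bloom.

library(pollscape)

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- default_truth(seed = 2026L)
sim <- simulate_study(truth)
write_study(sim$data, out)
write_table(sim$latent, file.path(out, "latent.csv"))
jsonlite::write_json(
  truth[setdiff(names(truth), "coef")],
  file.path(out, "truth.json"),
  auto_unbox = TRUE, digits = NA
)
jsonlite::write_json(
  lapply(truth$coef, as.list), file.path(out, "truth_coefficients.json"),
  auto_unbox = TRUE, digits = NA
)

s <- sim$data$surveys
cat(sprintf(
  paste0(
    "Simulated study written to %s\n",
    "  %d transect visits (%d herbaceous, %d woody) in %d landscapes x %d rounds\n",
    "  total counts: %d wild bees, %d hoverflies\n",
    "  flower cover: arithmetic mean %.1f%%, geometric mean %.1f%%\n",
    "  flower richness: mean %.1f species (SD %.1f)\n"
  ),
  out, nrow(s), sum(s$habitat_class == "herbaceous"),
  sum(s$habitat_class == "woody"),
  nrow(sim$data$landscapes), max(s$round),
  sum(s$bee_count), sum(s$hoverfly_count),
  mean(s$flower_cover_pct), exp(mean(log(s$flower_cover_pct))),
  mean(s$flower_richness), sd(s$flower_richness)
))
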