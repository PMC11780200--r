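#' Ground truth for a simulated transect study
#'
#' Defines every parameter of the synthetic survey generator: the sampling
#' design (landscapes, rounds, transect intensity), the covariate
#' distributions (SNH gradient, lognormal flower cover, richness), and the
#' density model itself (fixed-effect coefficients per taxon on the
#' transformed scale, plus landscape, round and residual standard
#' deviations).  [default_truth()] mirrors the study design the package
#' emulates: 26 landscapes of 750 m radius sampled over 8 rounds with on
#' average 2.8 transects per landscape and round, an SNH gradient from
#' 0.35% to 70%, flower cover lognormal with geometric mean 2.0% (and
#' arithmetic mean 4.6%), and flower richness with mean 12.8 species
#' (SD 5.8).
#'
#' The default coefficient sets are illustrative, not estimated: they are
#' chosen to reproduce the qualitative effect pattern reported for the two
#' taxa (bees responding to flower cover only; hoverflies responding to
#' flower cover, richness, SNH cover and mass-flowering-crop bloom) at
#' realistic count magnitudes (thousands of individuals over a season).
#'
#' @param ... Named overrides of any truth field, e.g.
#'   `default_truth(n_landscapes = 10, sd_resid = 0)`.
#' @return An object of class `simulation_truth` (a named list).
#' @section Fields:
#' `n_landscapes`, `n_rounds`, `transects_per_cell_mean`,
#' `transects_per_cell_sd`, `snh_range_pct` (low, high),
#' `coef` (per-taxon named vectors: `intercept`, `snh` per % cover,
#' `log10_flower_cover` per log10 %, `flower_richness` per species,
#' `mfc` indicator, `snh_mfc` interaction), `sd_landscape`, `sd_round`,
#' `sd_resid` (all on the transformed-density scale),
#' `flower_cover_logmean`/`flower_cover_logsd` (natural-log scale of %),
#' `richness_mean`, `richness_sd`, `mfc_prob`, `woody_prob`,
#' `area_m2`, `radius_m`, `obs_model` (`"round"` or `"poisson"`), `seed`.
#' @examples
#' default_truth()$n_landscapes  # 26
#' exp(default_truth()$flower_cover_logmean)  # geometric mean 2.0%
#' @export
default_truth <- function(...) {
  truth <- list(
    n_landscapes = 26L,
    n_rounds = 8L,
    transects_per_cell_mean = 2.8,
    transects_per_cell_sd = 0.8,
    snh_range_pct = c(0.35, 70),
    coef = list(
      bee = c(
        intercept = 1.0, snh = 0, log10_flower_cover = 0.4,
        flower_richness = 0, mfc = 0, snh_mfc = 0
      ),
      hoverfly = c(
        intercept = 0.57, snh = 0.004, log10_flower_cover = 0.35,
        flower_richness = 0.015, mfc = 0.23, snh_mfc = 0
      )
    ),
    sd_landscape = 0.15,
    sd_round = 0.10,
    sd_resid = 0.25,
    # lognormal with geometric mean 2.0% and arithmetic mean 4.6%:
    # sdlog = sqrt(2 * log(4.6 / 2.0))
    flower_cover_logmean = log(2.0),
    flower_cover_logsd = sqrt(2 * log(4.6 / 2.0)),
    richness_mean = 12.8,
    richness_sd = 5.8,
    mfc_prob = 0.4,
    woody_prob = 0.3,
    area_m2 = 150,
    radius_m = 750,
    obs_model = "round",
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(truth))
  if (length(unknown) > 0) {
    stop("unknown truth field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  truth[names(dots)] <- dots
  validate_truth(truth)
  structure(truth, class = "simulation_truth")
}

COEF_NAMES <- c(
  "intercept", "snh", "log10_flower_cover", "flower_richness", "mfc", "snh_mfc"
)

validate_truth <- function(truth) {
  bad <- function(...) stop("invalid simulation truth: ", ..., call. = FALSE)
  if (truth$n_landscapes < 1 || truth$n_rounds < 1) bad("need >= 1 landscape and round")
  if (truth$transects_per_cell_mean <= 0) bad("transects_per_cell_mean must be > 0")
  for (f in c("sd_landscape", "sd_round", "sd_resid", "transects_per_cell_sd")) {
    if (truth[[f]] < 0) bad(f, " must be >= 0")
  }
  r <- truth$snh_range_pct
  if (length(r) != 2 || r[1] <= 0 || r[2] > 100 || r[1] > r[2]) {
    bad("snh_range_pct must be (low, high) within (0, 100]")
  }
  if (truth$mfc_prob < 0 || truth$mfc_prob > 1) bad("mfc_prob must be in [0, 1]")
  if (truth$woody_prob < 0 || truth$woody_prob > 1) bad("woody_prob must be in [0, 1]")
  if (!all(sort(names(truth$coef)) == c("bee", "hoverfly"))) {
    bad("coef must have elements 'bee' and 'hoverfly'")
  }
  for (taxon in names(truth$coef)) {
    if (!all(COEF_NAMES %in% names(truth$coef[[taxon]]))) {
      bad("coef$", taxon, " must name all of: ", paste(COEF_NAMES, collapse = ", "))
    }
  }
  if (!truth$obs_model %in% c("round", "poisson")) {
    bad("obs_model must be 'round' or 'poisson'")
  }
  if (truth$area_m2 <= 0 || truth$radius_m <= 0) bad("area_m2 and radius_m must be > 0")
  invisible(truth)
}

#' Simulate a transect study with known ground truth
#'
#' Draws a complete study dataset under the generative model the analysis
#' assumes.  Landscape SNH covers are uniform over `snh_range_pct` with
#' the first landscape pinned to the low end of the range; each
#' landscape-by-round cell receives a discretised-normal number of
#' transects (clamped at 1) and a Bernoulli mass-flowering-crop flag.
#' Per-transect flower cover is lognormal, floored at the 0.025% recording
#' convention; richness is a rounded normal clamped at 0.
#'
#' The latent density process operates at the landscape-by-round cell, the
#' unit the mixed model is fitted at: transformed density equals the
#' linear predictor (evaluated at the cell-mean covariates) plus a
#' landscape intercept `N(0, sd_landscape)`, a round intercept
#' `N(0, sd_round)` and a cell residual `N(0, sd_resid)`.  Transects
#' within a cell share this latent density; their counts are the density
#' back-transformed to the transect area and rounded to the nearest
#' non-negative integer (or Poisson-sampled when
#' `truth$obs_model == "poisson"`).  Identical truth (including its
#' `seed`) always yields an identical dataset.
#'
#' @param truth A [default_truth()]-style `simulation_truth`.
#' @return A list with elements `data` (a [study_dataset()]) and `latent`
#'   (tibble of per-cell latent states: random intercepts, residuals,
#'   linear predictors `eta_bee`/`eta_hoverfly` and true densities).
#' @export
simulate_study <- function(truth = default_truth()) {
  validate_truth(truth)
  withr::with_seed(as.integer(truth$seed), simulate_study_impl(truth))
}

simulate_study_impl <- function(truth) {
  nL <- as.integer(truth$n_landscapes)
  nR <- as.integer(truth$n_rounds)

  snh <- stats::runif(nL, truth$snh_range_pct[1], truth$snh_range_pct[2])
  snh[1] <- truth$snh_range_pct[1]
  land_ids <- sprintf("L%02d", seq_len(nL))
  landscapes <- tibble::tibble(
    landscape_id = land_ids,
    snh_cover_pct = snh,
    radius_m = truth$radius_m
  )

  cells <- tidyr::expand_grid(land = seq_len(nL), round = seq_len(nR))
  ncell <- nrow(cells)
  cells$n_transects <- pmax(
    1L,
    as.integer(round(stats::rnorm(
      ncell, truth$transects_per_cell_mean, truth$transects_per_cell_sd
    )))
  )
  cells$mfc_flowering <- stats::runif(ncell) < truth$mfc_prob

  u <- list(
    bee = stats::rnorm(nL, 0, truth$sd_landscape),
    hoverfly = stats::rnorm(nL, 0, truth$sd_landscape)
  )
  v <- list(
    bee = stats::rnorm(nR, 0, truth$sd_round),
    hoverfly = stats::rnorm(nR, 0, truth$sd_round)
  )
  e <- list(
    bee = stats::rnorm(ncell, 0, truth$sd_resid),
    hoverfly = stats::rnorm(ncell, 0, truth$sd_resid)
  )

  idx <- rep(seq_len(ncell), cells$n_transects)
  nT <- length(idx)
  cover <- pmax(
    stats::rlnorm(nT, truth$flower_cover_logmean, truth$flower_cover_logsd),
    FLOWER_COVER_FLOOR
  )
  cover <- pmin(cover, 100)
  richness <- pmax(0L, as.integer(round(
    stats::rnorm(nT, truth$richness_mean, truth$richness_sd)
  )))
  habitat <- ifelse(
    stats::runif(nT) < truth$woody_prob, "woody", "herbaceous"
  )

  mean_cover <- as.numeric(rowsum(cover, idx)) / cells$n_transects
  mean_rich <- as.numeric(rowsum(as.numeric(richness), idx)) / cells$n_transects
  snh_cell <- snh[cells$land]
  mfc_cell <- as.numeric(cells$mfc_flowering)

  eta <- function(taxon) {
    co <- truth$coef[[taxon]]
    co[["intercept"]] +
      co[["snh"]] * snh_cell +
      co[["log10_flower_cover"]] * log10(mean_cover) +
      co[["flower_richness"]] * mean_rich +
      co[["mfc"]] * mfc_cell +
      co[["snh_mfc"]] * snh_cell * mfc_cell +
      u[[taxon]][cells$land] + v[[taxon]][cells$round] + e[[taxon]]
  }
  eta_bee <- eta("bee")
  eta_hov <- eta("hoverfly")
  dens_bee <- back_transform(eta_bee, "log10")
  dens_hov <- back_transform(eta_hov, "log10_plus1")

  expected_count <- function(dens) dens[idx] * truth$area_m2 / 150
  observe <- function(mu) {
    if (truth$obs_model == "poisson") {
      stats::rpois(nT, mu)
    } else {
      pmax(0L, as.integer(round(mu)))
    }
  }
  bee_count <- observe(expected_count(dens_bee))
  hov_count <- observe(expected_count(dens_hov))

  surveys <- tibble::tibble(
    landscape_id = land_ids[cells$land[idx]],
    round = as.integer(cells$round[idx]),
    transect_id = sprintf("T%d", as.integer(stats::ave(idx, idx, FUN = seq_along))),
    habitat_class = habitat,
    bee_count = as.integer(bee_count),
    hoverfly_count = as.integer(hov_count),
    area_m2 = truth$area_m2,
    flower_cover_pct = cover,
    flower_richness = richness,
    mfc_flowering = cells$mfc_flowering[idx]
  )

  latent <- tibble::tibble(
    landscape_id = land_ids[cells$land],
    round = as.integer(cells$round),
    snh_cover_pct = snh_cell,
    n_transects = cells$n_transects,
    mfc_flowering = cells$mfc_flowering,
    mean_flower_cover_pct = mean_cover,
    mean_flower_richness = mean_rich,
    u_bee = u$bee[cells$land], u_hoverfly = u$hoverfly[cells$land],
    v_bee = v$bee[cells$round], v_hoverfly = v$hoverfly[cells$round],
    e_bee = e$bee, e_hoverfly = e$hoverfly,
    eta_bee = eta_bee, eta_hoverfly = eta_hov,
    density_bee = dens_bee, density_hoverfly = dens_hov
  )

  list(data = study_dataset(surveys, landscapes), latent = latent)
}

#' Parameter-recovery experiment over repeated simulations
#'
#' The acceptance surface for the whole chain: repeatedly simulate a study
#' from `truth`, aggregate it, fit the generating model specification per
#' taxon, and summarise how well the fixed coefficients are re-estimated.
#'
#' @param truth Generating [default_truth()]-style truth.
#' @param n_sims Number of simulated studies (`>= 2`).
#' @param seed Integer; replicate `s` simulates with seed `seed + s - 1`.
#' @param taxa Taxa to fit (default both).
#' @return A list with `table` (tibble: `taxon`, `coefficient`, `truth`,
#'   `mean_estimate`, `bias`, `rmse`, `coverage` of nominal Wald 95%
#'   intervals, `n_fits`) and `n_failed` (replicate-by-taxon fits that
#'   errored or did not converge; these are excluded from the table).
#' @export
recovery_experiment <- function(truth = default_truth(), n_sims = 200,
                                seed = 1L, taxa = c("bee", "hoverfly")) {
  if (n_sims < 2) stop("`n_sims` must be >= 2", call. = FALSE)
  taxa <- match.arg(taxa, several.ok = TRUE)
  est <- list()
  n_failed <- 0L
  for (s in seq_len(n_sims)) {
    t2 <- truth
    t2$seed <- as.integer((as.numeric(seed) + s - 1) %% .Machine$integer.max)
    sim <- simulate_study(t2)
    obs <- aggregate_observations(sim$data)
    for (taxon in taxa) {
      fit <- tryCatch(
        fit_lmm(obs, model_spec(taxon), objective = "reml"),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$converged) {
        n_failed <- n_failed + 1L
        next
      }
      se <- sqrt(diag(fit$vcov))
      est[[length(est) + 1L]] <- tibble::tibble(
        sim = s, taxon = taxon,
        coefficient = names(fit$coefficients),
        estimate = unname(fit$coefficients),
        se = unname(se)
      )
    }
  }
  if (length(est) == 0) stop("every replicate fit failed", call. = FALSE)
  all_est <- dplyr::bind_rows(est)
  truth_tbl <- dplyr::bind_rows(lapply(taxa, function(tx) {
    true_values <- unname(truth$coef[[tx]][COEF_NAMES])
    tibble::tibble(taxon = tx, coefficient = COEF_NAMES, truth = true_values)
  }))
  table <- all_est |>
    dplyr::inner_join(truth_tbl, by = c("taxon", "coefficient")) |>
    dplyr::group_by(.data$taxon, .data$coefficient, .data$truth) |>
    dplyr::summarise(
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = mean(abs(.data$estimate - .data$truth) <= 1.96 * .data$se),
      n_fits = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::ungroup()
  list(table = table, n_failed = n_failed)
}
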