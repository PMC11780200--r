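#' Habitat-quantity grid: SNH cover levels
#'
#' The observed SNH gradient discretised in 15 steps of 5 percentage
#' points: 0.35 (the observed minimum), 5, 10, ..., 70.
#'
#' @return Numeric vector of length 15.
#' @export
make_snh_grid <- function() {
  c(0.35, seq(5, 70, by = 5))
}

#' Habitat-quality grid: 20 quantile levels of flower availability
#'
#' Discretises habitat quality into 20 levels Q1-Q20 by taking empirical
#' quantiles of cell-mean flower cover and of cell-mean flower richness,
#' computed independently and paired by rank: level j couples the j-th
#' cover quantile with the j-th richness quantile, collapsing the two
#' quality proxies onto one "flower availability" axis.
#'
#' @param obs Aggregated observations ([aggregate_observations()]).
#' @param n_levels Number of quality levels (default 20).
#' @param convention Quantile probabilities: `"upper"` (default;
#'   0.05, 0.10, ..., 1.00, so the top level is the observed maximum),
#'   `"lower"` (0, ..., 0.95) or `"midpoint"` ((j - 0.5) / n).
#' @return A `quality_grid` tibble with columns `level`, `prob`,
#'   `flower_cover_pct`, `flower_richness`; both level sequences are
#'   non-decreasing.
#' @export
make_quality_grid <- function(obs, n_levels = 20,
                              convention = c("upper", "lower", "midpoint")) {
  convention <- match.arg(convention)
  ok <- obs$mean_flower_cover_pct > 0
  if (sum(ok) < n_levels) {
    stop(
      "need at least ", n_levels, " observations with positive flower ",
      "cover (have ", sum(ok), "); use fewer levels",
      call. = FALSE
    )
  }
  probs <- switch(convention,
    upper = seq_len(n_levels) / n_levels,
    lower = (seq_len(n_levels) - 1) / n_levels,
    midpoint = (seq_len(n_levels) - 0.5) / n_levels
  )
  out <- tibble::tibble(
    level = seq_len(n_levels),
    prob = probs,
    flower_cover_pct = unname(
      stats::quantile(obs$mean_flower_cover_pct[ok], probs, type = 7)
    ),
    flower_richness = unname(
      stats::quantile(obs$mean_flower_richness[ok], probs, type = 7)
    )
  )
  class(out) <- c("quality_grid", class(out))
  out
}

#' Predict pollinator density from a fitted model
#'
#' Evaluates the fixed-effect linear predictor at the supplied covariates
#' with the mass-flowering-crop indicator held at "no" and random effects
#' at zero, then back-transforms to the density scale (individuals per
#' 150 m2 transect).  Covariate values outside the observed fitted range
#' trigger an extrapolation warning, not an error — the prediction grid's
#' 0.35% SNH anchor sits at the data edge by design.
#'
#' @param model A `density_model`.
#' @param snh_pct Percent SNH cover (scalar or vector).
#' @param flower_cover_pct Mean flower cover, percent, `> 0`.
#' @param richness Mean flower richness (species).
#' @return Predicted densities (vectorised over the inputs).
#' @export
predict_density <- function(model, snh_pct, flower_cover_pct, richness) {
  stopifnot(inherits(model, "density_model"))
  if (!model$converged) {
    stop("refusing to predict from a non-converged model", call. = FALSE)
  }
  if (any(flower_cover_pct <= 0)) {
    stop("flower_cover_pct must be > 0", call. = FALSE)
  }
  if (!is.null(model$ranges)) {
    out_of <- character()
    chk <- function(x, rng, nm) {
      if (any(x < rng[1] - 1e-9 | x > rng[2] + 1e-9)) nm else NULL
    }
    out_of <- c(
      chk(snh_pct, model$ranges$snh_cover_pct, "snh_pct"),
      chk(flower_cover_pct, model$ranges$flower_cover_pct, "flower_cover_pct"),
      chk(richness, model$ranges$flower_richness, "richness")
    )
    if (length(out_of) > 0) {
      warning(
        "extrapolating beyond the fitted covariate range: ",
        paste(out_of, collapse = ", "),
        call. = FALSE
      )
    }
  }
  co <- function(nm) {
    if (nm %in% names(model$coefficients)) model$coefficients[[nm]] else 0
  }
  eta <- co("intercept") +
    co("snh") * snh_pct +
    co("log10_flower_cover") * log10(flower_cover_pct) +
    co("flower_richness") * richness
  # mfc = "no": mfc and snh_mfc terms contribute nothing
  back_transform(eta, model$spec$response_transform)
}

#' Build the habitat quantity-by-quality population matrix
#'
#' The landscape-extrapolation step: predicted density at every
#' combination of the 15 SNH levels and 20 quality levels is divided by
#' the transect area to a per-square-metre density, then multiplied by the
#' area of seminatural habitat in the landscape (SNH proportion x pi x
#' radius^2) to give a landscape-level population size.  Because all main
#' effects are retained in the final models, the SNH level enters both the
#' linear predictor and the habitat-area multiplier.
#'
#' @param model A `density_model`.
#' @param snh Numeric vector of SNH cover levels (default
#'   [make_snh_grid()]).
#' @param quality A [make_quality_grid()] tibble.
#' @param radius_m Landscape radius in metres (default 750).
#' @param transect_area_m2 Area a predicted density refers to (default
#'   150 m2, the standard transect).
#' @return A `population_matrix`: list with `taxon`, `snh_pct`,
#'   `quality`, matrices `density_per_m2` and `population` (rows = SNH
#'   levels, columns = quality levels), `radius_m`, `transect_area_m2`.
#' @examples
#' m <- density_model("bee", c(intercept = 1, log10_flower_cover = 0.4))
#' obs <- aggregate_observations(simulate_study(default_truth(seed = 7))$data)
#' pm <- build_population_matrix(m, quality = make_quality_grid(obs))
#' dim(pm$population)  # 15 x 20
#' @export
build_population_matrix <- function(model, snh = make_snh_grid(), quality,
                                    radius_m = 750, transect_area_m2 = 150) {
  stopifnot(inherits(model, "density_model"))
  if (!all(c("flower_cover_pct", "flower_richness") %in% names(quality))) {
    stop("`quality` must be a quality grid with flower_cover_pct and flower_richness",
      call. = FALSE
    )
  }
  if (any(diff(snh) <= 0)) stop("SNH levels must be strictly increasing", call. = FALSE)
  nS <- length(snh)
  nQ <- nrow(quality)
  dens <- matrix(NA_real_, nS, nQ)
  for (j in seq_len(nQ)) {
    dens[, j] <- predict_density(
      model, snh, quality$flower_cover_pct[j], quality$flower_richness[j]
    )
  }
  dens_m2 <- dens / transect_area_m2
  habitat_area <- (snh / 100) * pi * radius_m^2
  population <- dens_m2 * habitat_area # recycles by row (SNH)
  dimnames(dens_m2) <- dimnames(population) <- list(
    paste0("snh_", format(snh, trim = TRUE)),
    paste0("Q", seq_len(nQ))
  )
  structure(
    list(
      taxon = model$spec$taxon,
      snh_pct = snh,
      quality = quality,
      density_per_m2 = dens_m2,
      population = population,
      radius_m = radius_m,
      transect_area_m2 = transect_area_m2
    ),
    class = "population_matrix"
  )
}

#' @export
print.population_matrix <- function(x, ...) {
  cat(
    "<population_matrix> ", x$taxon, ": ", length(x$snh_pct), " SNH levels x ",
    nrow(x$quality), " quality levels; population ",
    format(round(min(x$population))), " - ", format(round(max(x$population))),
    " individuals per landscape\n",
    sep = ""
  )
  invisible(x)
}

#' Long-format view of a population matrix
#'
#' @param x A `population_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per (SNH level, quality level): `taxon`,
#'   `snh_pct`, `quality_level`, `flower_cover_pct`, `flower_richness`,
#'   `density_per_m2`, `population`.
#' @export
as_tibble.population_matrix <- function(x, ...) {
  grid <- expand.grid(
    i = seq_along(x$snh_pct), j = seq_len(nrow(x$quality))
  )
  tibble::tibble(
    taxon = x$taxon,
    snh_pct = x$snh_pct[grid$i],
    quality_level = grid$j,
    flower_cover_pct = x$quality$flower_cover_pct[grid$j],
    flower_richness = x$quality$flower_richness[grid$j],
    density_per_m2 = x$density_per_m2[cbind(grid$i, grid$j)],
    population = x$population[cbind(grid$i, grid$j)]
  )
}
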