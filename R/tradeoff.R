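#' Quality:quantity population response-ratio curve
#'
#' For each cell of a population matrix, the population gain from
#' `k_quality` steps up the quality axis divided by the gain from one step
#' up the SNH axis:
#' `ratio(i, j) = (P[i, j + k] - P[i, j]) / (P[i + 1, j] - P[i, j])`.
#' Ratios above 1 mean improving habitat quality beats adding habitat
#' area at that landscape configuration.  Step ratios of 2:1 and 3:1
#' (`k_quality` = 2, 3) proxy the higher feasibility of quality measures
#' relative to taking land out of production.
#'
#' Cells whose quality or quantity step would leave the grid are absent;
#' cells with a non-positive quantity gain are kept but flagged
#' (`quantity_gain_positive = FALSE`) with an undefined (NA) ratio.
#'
#' @param matrix A [build_population_matrix()] result.
#' @param k_quality Quality steps per one quantity step; 1, 2 or 3 unless
#'   `allow_any_k = TRUE`.
#' @param allow_any_k Permit other positive integer `k_quality`.
#' @return A `tradeoff_result`: list with `taxon`, `step_ratio`, `curve`
#'   (tibble: `snh_level`, `snh_pct`, `quality_level`, `quality_gain`,
#'   `quantity_gain`, `ratio`, `quantity_gain_positive`) and `thresholds`
#'   (tibble: `quality_level`, `threshold_snh_pct` from
#'   [find_threshold()]).
#' @export
ratio_curve <- function(matrix, k_quality = 1, allow_any_k = FALSE) {
  stopifnot(inherits(matrix, "population_matrix"))
  if (!allow_any_k && !k_quality %in% 1:3) {
    stop("`k_quality` must be 1, 2 or 3 (set allow_any_k = TRUE to override)",
      call. = FALSE
    )
  }
  if (allow_any_k && (k_quality < 1 || k_quality != round(k_quality))) {
    stop("`k_quality` must be a positive integer", call. = FALSE)
  }
  P <- matrix$population
  nS <- nrow(P)
  nQ <- ncol(P)
  if (nQ <= k_quality || nS < 2) {
    stop("population matrix too small for a ", k_quality, "-step ratio curve",
      call. = FALSE
    )
  }
  grid <- expand.grid(i = seq_len(nS - 1), j = seq_len(nQ - k_quality))
  q_gain <- P[cbind(grid$i, grid$j + k_quality)] - P[cbind(grid$i, grid$j)]
  c_gain <- P[cbind(grid$i + 1, grid$j)] - P[cbind(grid$i, grid$j)]
  positive <- c_gain > 0
  curve <- tibble::tibble(
    snh_level = grid$i,
    snh_pct = matrix$snh_pct[grid$i],
    quality_level = grid$j,
    quality_gain = q_gain,
    quantity_gain = c_gain,
    ratio = ifelse(positive, q_gain / c_gain, NA_real_),
    quantity_gain_positive = positive
  ) |>
    dplyr::arrange(.data$quality_level, .data$snh_level)
  out <- structure(
    list(
      taxon = matrix$taxon,
      step_ratio = as.integer(k_quality),
      curve = curve,
      thresholds = NULL
    ),
    class = "tradeoff_result"
  )
  out$thresholds <- tibble::tibble(
    quality_level = seq_len(nQ - k_quality),
    threshold_snh_pct = vapply(
      seq_len(nQ - k_quality),
      function(j) {
        defined <- sum(!is.na(curve$ratio[curve$quality_level == j]))
        if (defined < 2) NA_real_ else find_threshold(out, j)
      },
      numeric(1)
    )
  )
  out
}

#' @export
print.tradeoff_result <- function(x, ...) {
  thr <- x$thresholds$threshold_snh_pct
  cat(
    "<tradeoff_result> ", x$taxon, ", step ratio ", x$step_ratio, ":1; ",
    sum(!is.na(thr)), "/", length(thr),
    " quality levels reach the break-even ratio",
    if (any(!is.na(thr))) {
      sprintf(
        " (thresholds %.1f-%.1f%% SNH)",
        min(thr, na.rm = TRUE), max(thr, na.rm = TRUE)
      )
    } else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Break-even SNH threshold at one quality level
#'
#' The smallest SNH cover at which the response-ratio curve crosses 1 from
#' below, located by piecewise-linear interpolation between the curve's
#' SNH grid points (monotone-spline interpolation available).  Exact grid
#' hits are returned as-is; a curve already at or above 1 at the lowest
#' grid level returns that level; a curve that never reaches 1 returns
#' `NA`.  Non-monotone curves with several upward crossings return the
#' first with a warning.
#'
#' @param result A [ratio_curve()] result.
#' @param quality_level Quality level `j` to examine.
#' @param method `"linear"` (default) or `"spline"` (monotone Hermite).
#' @return SNH cover percent, or `NA_real_` when no crossing exists.
#' @export
find_threshold <- function(result, quality_level,
                           method = c("linear", "spline")) {
  stopifnot(inherits(result, "tradeoff_result"))
  method <- match.arg(method)
  cur <- result$curve[result$curve$quality_level == quality_level &
    !is.na(result$curve$ratio), ]
  if (nrow(cur) < 2) {
    stop("ratio curve must cover >= 2 SNH levels at quality level ",
      quality_level,
      call. = FALSE
    )
  }
  cur <- cur[order(cur$snh_pct), ]
  x <- cur$snh_pct
  r <- cur$ratio
  if (r[1] >= 1) {
    return(x[1])
  }
  above <- r >= 1
  upward <- which(!above[-length(above)] & above[-1])
  if (length(upward) == 0) {
    return(NA_real_)
  }
  if (length(upward) > 1) {
    warning(
      "ratio curve crosses 1 more than once at quality level ",
      quality_level, "; returning the first crossing",
      call. = FALSE
    )
  }
  i <- upward[1]
  if (method == "linear") {
    x[i] + (1 - r[i]) * (x[i + 1] - x[i]) / (r[i + 1] - r[i])
  } else {
    f <- stats::splinefun(x, r, method = "monoH.FC")
    stats::uniroot(function(s) f(s) - 1,
      lower = x[i], upper = x[i + 1], tol = 1e-9
    )$root
  }
}

#' Quality increase equivalent to a habitat-quantity increase
#'
#' Answers scenario questions of the form "how much habitat-quality
#' improvement matches raising SNH cover from 5% to 10%?": the target is
#' the population gain of the quantity move at the baseline quality level,
#' and the answer is the smallest number of quality-grid steps whose gain
#' at the starting SNH cover meets or exceeds it.  Populations at
#' off-grid SNH values are linearly interpolated between grid rows.
#'
#' @param matrix A [build_population_matrix()] result.
#' @param snh_from_pct,snh_to_pct SNH covers within the grid range, with
#'   `snh_to_pct > snh_from_pct` (equality gives the null scenario: zero
#'   steps).
#' @param quality_baseline_level Baseline quality level (default 10, the
#'   median level of a 20-level grid).
#' @return A one-row tibble: `taxon`, `snh_from_pct`, `snh_to_pct`,
#'   `quality_baseline_level`, `required_quality_steps`,
#'   `required_quality_pct` (steps x 5), `delta_flower_cover_pct`,
#'   `delta_flower_richness`.  Steps are `NA` (with a warning) when no
#'   step count within the grid suffices.
#' @export
equivalent_quality_steps <- function(matrix, snh_from_pct, snh_to_pct,
                                     quality_baseline_level = 10) {
  stopifnot(inherits(matrix, "population_matrix"))
  if (snh_to_pct < snh_from_pct) {
    stop("`snh_to_pct` must be >= `snh_from_pct`", call. = FALSE)
  }
  rng <- range(matrix$snh_pct)
  if (snh_from_pct < rng[1] || snh_to_pct > rng[2]) {
    stop("SNH values must lie within the grid range [",
      rng[1], ", ", rng[2], "]",
      call. = FALSE
    )
  }
  q <- quality_baseline_level
  nQ <- ncol(matrix$population)
  if (q < 1 || q > nQ) stop("invalid quality_baseline_level", call. = FALSE)
  pop_at <- function(snh, j) {
    stats::approx(matrix$snh_pct, matrix$population[, j], xout = snh)$y
  }
  target <- pop_at(snh_to_pct, q) - pop_at(snh_from_pct, q)
  step_pct_per_level <- 100 / nQ
  k_max <- nQ - q
  k <- NA_integer_
  tol <- 1e-9 * max(abs(target), 1)
  for (kk in 0:k_max) {
    gain <- pop_at(snh_from_pct, q + kk) - pop_at(snh_from_pct, q)
    if (gain >= target - tol) {
      k <- kk
      break
    }
  }
  if (is.na(k)) {
    warning(
      "no quality increase within the grid matches the quantity gain (",
      "baseline level ", q, ", headroom ", k_max, " steps)",
      call. = FALSE
    )
  }
  tibble::tibble(
    taxon = matrix$taxon,
    snh_from_pct = snh_from_pct,
    snh_to_pct = snh_to_pct,
    quality_baseline_level = q,
    required_quality_steps = k,
    required_quality_pct = k * step_pct_per_level,
    delta_flower_cover_pct = if (is.na(k)) NA_real_ else {
      matrix$quality$flower_cover_pct[q + k] - matrix$quality$flower_cover_pct[q]
    },
    delta_flower_richness = if (is.na(k)) NA_real_ else {
      matrix$quality$flower_richness[q + k] - matrix$quality$flower_richness[q]
    }
  )
}

#' End-to-end trade-off report for both taxa
#'
#' Convenience wrapper: builds the quality grid from the observations, the
#' population matrix per taxon, ratio curves and break-even thresholds for
#' step ratios 1:1, 2:1 and 3:1, and two policy scenarios (raising SNH
#' cover 5% to 10%, and 15% to 20%, each matched by quality steps at the
#' median quality level), emitted as one tidy table.
#'
#' @param models Named list of `density_model`s, e.g.
#'   `list(bee = ..., hoverfly = ...)`.
#' @param obs Aggregated observations used for the quality grid.
#' @param step_ratios Integer step ratios (default `1:3`).
#' @param scenarios List of `c(snh_from, snh_to)` pairs.
#' @param median_level Baseline quality level for scenarios (default 10).
#' @param quantile_convention Passed to [make_quality_grid()].
#' @return A tidy tibble with columns `taxon`, `component`
#'   (`"threshold"` or `"scenario"`), `step_ratio`, `quality_level`,
#'   `scenario`, `name`, `value`.
#' @export
scenario_report <- function(models, obs, step_ratios = 1:3,
                            scenarios = list(c(5, 10), c(15, 20)),
                            median_level = 10,
                            quantile_convention = "upper") {
  quality <- make_quality_grid(obs, convention = quantile_convention)
  rows <- list()
  for (taxon in names(models)) {
    pm <- build_population_matrix(models[[taxon]], quality = quality)
    for (k in step_ratios) {
      rc <- ratio_curve(pm, k_quality = k)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        taxon = taxon, component = "threshold", step_ratio = as.integer(k),
        quality_level = rc$thresholds$quality_level,
        scenario = NA_character_, name = "threshold_snh_pct",
        value = rc$thresholds$threshold_snh_pct
      )
    }
    for (sc in scenarios) {
      eq <- equivalent_quality_steps(pm, sc[1], sc[2], median_level)
      lbl <- sprintf("snh_%g_to_%g", sc[1], sc[2])
      vals <- c(
        required_quality_steps = as.numeric(eq$required_quality_steps),
        required_quality_pct = eq$required_quality_pct,
        delta_flower_cover_pct = eq$delta_flower_cover_pct,
        delta_flower_richness = eq$delta_flower_richness
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        taxon = taxon, component = "scenario", step_ratio = NA_integer_,
        quality_level = median_level, scenario = lbl,
        name = names(vals), value = unname(vals)
      )
    }
  }
  dplyr::bind_rows(rows)
}
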