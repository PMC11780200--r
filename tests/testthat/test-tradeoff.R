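# population matrix with prescribed entries, for closed-form checks
matrix_from_fn <- function(fn, snh = make_snh_grid(), nQ = 20) {
  q <- manual_quality_grid(cover = seq(1, 20, length.out = nQ))
  pm <- build_population_matrix(
    density_model("bee", c(intercept = 0)),
    snh = snh, quality = q
  )
  P <- outer(seq_along(snh), seq_len(nQ), fn)
  dimnames(P) <- dimnames(pm$population)
  pm$population <- P
  pm$density_per_m2 <- P / ((snh / 100) * pi * 750^2)
  pm
}

test_that("degenerate matrices give the expected constant ratio curves", {
  # population depends only on the quantity index: no quality response
  pm_i <- matrix_from_fn(function(i, j) i)
  rc <- ratio_curve(pm_i, 1)
  expect_true(all(rc$curve$ratio == 0))
  expect_true(all(is.na(rc$thresholds$threshold_snh_pct)))
  # equal unit gains in both directions: ratio 1 everywhere
  pm_ij <- matrix_from_fn(function(i, j) i + j)
  rc1 <- ratio_curve(pm_ij, 1)
  expect_true(all(rc1$curve$ratio == 1))
  # grid sizes: (15 - 1) SNH steps x (20 - k) quality origins
  expect_equal(nrow(rc1$curve), 14L * 19L)
  expect_equal(nrow(ratio_curve(pm_ij, 3)$curve), 14L * 17L)
  expect_error(ratio_curve(pm_ij, 4), "k_quality")
  expect_silent(ratio_curve(pm_ij, 4, allow_any_k = TRUE))
})

test_that("non-positive quantity gains are flagged, not silently dropped", {
  pm <- matrix_from_fn(function(i, j) -i + 100 * j)
  rc <- ratio_curve(pm, 1)
  expect_true(all(!rc$curve$quantity_gain_positive))
  expect_true(all(is.na(rc$curve$ratio)))
})

test_that("the quality-only closed form holds on a small constructed matrix", {
  # density depends only on quality: d(j); ratio(i,j) = c_i (d(j+1)-d(j)) / (dc d(j))
  d <- c(2, 3, 4.5)
  snh <- c(10, 15, 20)
  q <- manual_quality_grid(cover = c(1, 2, 3))
  pm <- build_population_matrix(density_model("bee", c(intercept = 0)),
    snh = snh, quality = q
  )
  A <- pi * 750^2
  pm$population <- outer(snh / 100, d) * A / 150
  rc <- ratio_curve(pm, 1)
  for (r in seq_len(nrow(rc$curve))) {
    i <- rc$curve$snh_level[r]
    j <- rc$curve$quality_level[r]
    expect_equal(
      rc$curve$ratio[r],
      (snh[i] / 100) * (d[j + 1] - d[j]) / (0.05 * d[j]),
      tolerance = 1e-12
    )
  }
})

test_that("thresholds interpolate linearly and handle edge cases", {
  pm <- matrix_from_fn(function(i, j) i + j) # placeholder, curves overridden
  rc <- ratio_curve(pm, 1)
  # hand-built two-point curve: 0.5 at cover 10, 1.5 at cover 20 -> 15
  rc$curve <- tibble::tibble(
    snh_level = c(1L, 2L), snh_pct = c(10, 20), quality_level = 1L,
    quality_gain = 1, quantity_gain = 1, ratio = c(0.5, 1.5),
    quantity_gain_positive = TRUE
  )
  expect_equal(find_threshold(rc, 1), 15)
  # never crossing
  rc$curve$ratio <- c(0.5, 0.5)
  expect_true(is.na(find_threshold(rc, 1)))
  # exact grid hit returned as-is
  rc$curve$ratio <- c(0.25, 1)
  expect_equal(find_threshold(rc, 1), 20)
  # already above 1 at the lowest level
  rc$curve$ratio <- c(1.2, 1.5)
  expect_equal(find_threshold(rc, 1), 10)
  # multiple crossings: first one, with a warning
  rc$curve <- tibble::tibble(
    snh_level = 1:4, snh_pct = c(10, 20, 30, 40), quality_level = 1L,
    quality_gain = 1, quantity_gain = 1, ratio = c(0.5, 1.5, 0.5, 1.5),
    quantity_gain_positive = TRUE
  )
  expect_warning(thr <- find_threshold(rc, 1), "more than once")
  expect_equal(thr, 15)
  # too few points
  rc$curve <- rc$curve[1, ]
  expect_error(find_threshold(rc, 1), ">= 2 SNH levels")
})

test_that("quality-only thresholds match the closed form to 1e-6", {
  # geometric density sequence makes the per-step gain g constant:
  # threshold = 100 * dc / ((1 + g)^k - 1), identical at every level
  b <- 1
  growth <- 1.2
  cover <- 2 * growth^(0:19)
  m <- density_model("bee", c(intercept = 0, log10_flower_cover = b))
  pm <- build_population_matrix(m, quality = manual_quality_grid(cover))
  for (k in 1:3) {
    rc <- ratio_curve(pm, k)
    expected <- 100 * 0.05 / (growth^k - 1)
    thr <- rc$thresholds$threshold_snh_pct
    expect_equal(thr, rep(expected, length(thr)), tolerance = 1e-6)
    # monotone-spline interpolation agrees wherever the curve's support
    # points are collinear (the k = 3 crossing sits next to the off-line
    # 0.35% anchor, which bends the local Hermite slope slightly)
    expect_equal(find_threshold(rc, 1, method = "spline"), expected,
      tolerance = if (k < 3) 1e-6 else 1e-3
    )
  }
})

test_that("ratio curves and thresholds are scale-invariant", {
  sim <- simulate_study(default_truth(seed = 20L))
  obs <- aggregate_observations(sim$data)
  fit <- fit_lmm(obs, model_spec("hoverfly"), "reml")
  pm <- suppressWarnings(
    build_population_matrix(fit, quality = make_quality_grid(obs))
  )
  pm_scaled <- pm
  pm_scaled$population <- pm$population * 1234.5
  rc <- ratio_curve(pm, 1)
  rc_s <- ratio_curve(pm_scaled, 1)
  expect_equal(rc_s$curve$ratio, rc$curve$ratio, tolerance = 1e-12)
  expect_equal(
    rc_s$thresholds$threshold_snh_pct,
    rc$thresholds$threshold_snh_pct,
    tolerance = 1e-9
  )
})

test_that("equivalent quality steps solve the scenario arithmetic", {
  # null scenario: no quantity change needs no quality steps
  m <- density_model("bee", c(intercept = 0.5, log10_flower_cover = 0.6))
  pm <- build_population_matrix(m, quality = manual_quality_grid(seq(1, 20)))
  eq0 <- equivalent_quality_steps(pm, 20, 20, 5)
  expect_identical(eq0$required_quality_steps, 0L)
  expect_equal(eq0$delta_flower_cover_pct, 0)
  expect_error(equivalent_quality_steps(pm, 20, 10, 5), "snh_to_pct")

  # doubling oracle: d(j) = d0 * 2^j, quantity move that doubles population
  cover2 <- 2^(0:19)
  m2 <- density_model("bee", c(intercept = 0, log10_flower_cover = 1))
  pm2 <- build_population_matrix(m2, quality = manual_quality_grid(cover2))
  eq1 <- equivalent_quality_steps(pm2, 10, 20, 5)
  expect_identical(eq1$required_quality_steps, 1L)
  expect_equal(eq1$required_quality_pct, 5)
  expect_equal(eq1$delta_flower_cover_pct, cover2[6] - cover2[5])

  # more existing habitat makes quality cheaper: steps non-increasing in snh_from
  pm3 <- build_population_matrix(m,
    quality = manual_quality_grid(seq(0.5, 40, length.out = 20))
  )
  starts <- c(5, 15, 30, 50)
  steps <- vapply(starts, function(s) {
    as.numeric(equivalent_quality_steps(pm3, s, s + 5, 3)$required_quality_steps)
  }, numeric(1))
  expect_true(all(diff(steps) <= 0))

  # insufficient headroom is NA with a warning
  expect_warning(
    eq_na <- equivalent_quality_steps(pm, 0.35, 70, 20),
    "no quality increase"
  )
  expect_true(is.na(eq_na$required_quality_steps))
})

test_that("the scenario report covers three step ratios and both taxa", {
  sim <- simulate_study(default_truth(seed = 33L))
  obs <- aggregate_observations(sim$data)
  models <- list(
    bee = density_model("bee", c(intercept = 0.8, log10_flower_cover = 0.4)),
    hoverfly = density_model(
      "hoverfly",
      c(intercept = 0.6, log10_flower_cover = 0.35, snh = 0.004)
    )
  )
  rep <- suppressWarnings(scenario_report(models, obs))
  expect_setequal(unique(rep$taxon), c("bee", "hoverfly"))
  thr <- rep[rep$component == "threshold", ]
  expect_setequal(unique(thr$step_ratio), 1:3)
  expect_equal(sum(thr$taxon == "bee" & thr$step_ratio == 1), 19L)
  sc <- rep[rep$component == "scenario", ]
  expect_setequal(unique(sc$scenario), c("snh_5_to_10", "snh_15_to_20"))
  expect_true(all(c("required_quality_pct", "delta_flower_cover_pct") %in% sc$name))
})

test_that("thresholds are non-increasing in the step ratio k", {
  # positive quality response: bigger quality steps pay off sooner
  sim <- simulate_study(default_truth(seed = 44L))
  obs <- aggregate_observations(sim$data)
  for (taxon in c("bee", "hoverfly")) {
    fit <- fit_lmm(obs, model_spec(taxon), "reml")
    pm <- suppressWarnings(
      build_population_matrix(fit, quality = make_quality_grid(obs))
    )
    thr <- lapply(1:3, function(k) ratio_curve(pm, k)$thresholds)
    for (k in 2:3) {
      joined <- dplyr::inner_join(
        thr[[k - 1]], thr[[k]],
        by = "quality_level", suffix = c("_lo", "_hi")
      )
      # absent crossings count as "beyond the grid"
      lo <- ifelse(is.na(joined$threshold_snh_pct_lo), Inf, joined$threshold_snh_pct_lo)
      hi <- ifelse(is.na(joined$threshold_snh_pct_hi), Inf, joined$threshold_snh_pct_hi)
      expect_true(all(hi <= lo + 1e-9))
    }
  }
})
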