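test_that("the SNH grid is exactly (0.35, 5, 10, ..., 70)", {
  g <- make_snh_grid()
  expect_length(g, 15L)
  expect_identical(g, c(0.35, seq(5, 70, by = 5)))
})

test_that("the quality grid pairs rank-matched quantiles of cover and richness", {
  obs <- tibble::tibble(
    mean_flower_cover_pct = 1:100,
    mean_flower_richness = seq(2, 200, by = 2)
  )
  q <- make_quality_grid(obs)
  expect_equal(nrow(q), 20L)
  expect_equal(q$prob, seq(0.05, 1, by = 0.05))
  # empirical-quantile oracle on the known uniform sample
  expect_equal(
    q$flower_cover_pct[q$prob == 0.5],
    unname(stats::quantile(1:100, 0.5))
  )
  expect_equal(max(q$flower_cover_pct), 100) # upper-anchored: Q20 = maximum
  expect_true(all(diff(q$flower_cover_pct) >= 0))
  expect_true(all(diff(q$flower_richness) >= 0))
  # degenerate constant cover: every level equals the constant
  const <- tibble::tibble(
    mean_flower_cover_pct = rep(3.5, 40),
    mean_flower_richness = rep(8, 40)
  )
  expect_true(all(make_quality_grid(const)$flower_cover_pct == 3.5))
  # too few observations is an informative error
  expect_error(make_quality_grid(obs[1:10, ]), "fewer levels")
  # alternative conventions
  expect_equal(make_quality_grid(obs, convention = "lower")$prob[1], 0)
  expect_equal(make_quality_grid(obs, convention = "midpoint")$prob[1], 0.025)
})

test_that("density predictions follow the linear predictor and back-transform", {
  const <- density_model("bee", c(intercept = 1))
  expect_equal(predict_density(const, 50, 3, 10), 10) # 10^1 everywhere
  lf <- density_model("bee", c(intercept = 0, log10_flower_cover = 1))
  expect_equal(predict_density(lf, 0.35, 10, 0), 10) # 10^(1 * log10 10)
  hov0 <- density_model("hoverfly", c(intercept = 0))
  expect_equal(predict_density(hov0, 10, 5, 5), 0) # 10^0 - 1
  expect_error(predict_density(const, 10, 0, 5), "flower_cover_pct")
})

test_that("predictions outside the fitted range warn but do not error", {
  sim <- simulate_study(default_truth(n_landscapes = 8, n_rounds = 4, seed = 4L))
  obs <- aggregate_observations(sim$data)
  fit <- fit_lmm(obs, model_spec("bee"), "reml")
  inside <- mean(obs$snh_cover_pct)
  expect_silent(predict_density(
    fit, inside, mean(obs$mean_flower_cover_pct), mean(obs$mean_flower_richness)
  ))
  expect_warning(
    predict_density(fit, 99, mean(obs$mean_flower_cover_pct), 5),
    "extrapolating"
  )
})

test_that("the population matrix applies the habitat-area identity exactly", {
  m <- density_model("bee", c(intercept = 1, log10_flower_cover = 0.5))
  q <- manual_quality_grid(cover = seq(1, 20, length.out = 20))
  pm <- build_population_matrix(m, quality = q)
  expect_equal(dim(pm$population), c(15L, 20L))
  # population = density_per_m2 * snh proportion * pi * radius^2, all cells
  area <- (pm$snh_pct / 100) * pi * 750^2
  expect_equal(pm$population, pm$density_per_m2 * area, tolerance = 1e-12)
  # direct arithmetic oracle for one configuration
  pm30 <- build_population_matrix(m, snh = c(10, 30), quality = q[1:2, ])
  d <- pm30$density_per_m2[2, 1]
  expect_equal(pm30$population[2, 1], d * 0.30 * pi * 750^2)
  # worked magnitude check: 0.1 / m2 at 30% SNH in a 750-m landscape
  expect_equal(0.1 * 0.30 * pi * 750^2, 53014.38, tolerance = 1e-6)
  # zero habitat means zero population whatever the density
  pm0 <- build_population_matrix(m, snh = c(1e-12, 10), quality = q[1:2, ])
  expect_equal(unname(pm0$population[1, ]), c(0, 0), tolerance = 1e-6)
})

test_that("population conservation: population/density depends only on the SNH row", {
  sim <- simulate_study(default_truth(seed = 10L))
  obs <- aggregate_observations(sim$data)
  fit <- fit_lmm(obs, model_spec("hoverfly"), "reml")
  pm <- suppressWarnings(
    build_population_matrix(fit, quality = make_quality_grid(obs))
  )
  expect_true(all(pm$density_per_m2 > 0))
  ratio <- pm$population / pm$density_per_m2
  for (j in 2:ncol(ratio)) {
    expect_equal(ratio[, j], ratio[, 1], tolerance = 1e-12)
  }
})

test_that("population is monotone in quality and linear in SNH for a quality-only model", {
  m <- density_model("bee", c(intercept = 0.5, log10_flower_cover = 0.4))
  q <- manual_quality_grid(cover = seq(0.5, 30, length.out = 20))
  pm <- build_population_matrix(m, quality = q)
  # non-decreasing along the quality axis at every SNH level
  expect_true(all(apply(pm$population, 1, function(r) all(diff(r) >= 0))))
  # exactly linear in SNH proportion at fixed quality (snh coefficient 0)
  c_prop <- pm$snh_pct / 100
  for (j in c(1, 10, 20)) {
    col <- unname(pm$population[, j])
    slope <- col[1] / c_prop[1]
    expect_equal(col, slope * c_prop, tolerance = 1e-9)
  }
})

test_that("the long-format view matches the matrices cell by cell", {
  m <- density_model("hoverfly", c(intercept = 0.6, flower_richness = 0.02))
  q <- manual_quality_grid(cover = 1:20, richness = seq(2, 40, by = 2))
  pm <- build_population_matrix(m, quality = q)
  long <- tibble::as_tibble(pm)
  expect_equal(nrow(long), 300L)
  i <- match(long$snh_pct, pm$snh_pct)
  expect_equal(long$population, pm$population[cbind(i, long$quality_level)])
})
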