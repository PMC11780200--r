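test_that("transforms match their closed forms and round-trip", {
  expect_equal(transform_response(0, "log10_plus1"), 0)
  expect_equal(transform_response(99, "log10_plus1"), 2)
  expect_equal(transform_response(1, "log10"), 0)
  expect_error(transform_response(0, "log10"), "log10_plus1")
  expect_error(transform_response(-1, "log10_plus1"), "non-negative")
  for (tr in c("log10", "log10_plus1")) {
    x <- c(0.01, 1, 7, 153, 1000)
    if (tr == "log10_plus1") x <- c(0, x)
    expect_equal(back_transform(transform_response(x, tr), tr), x,
      tolerance = 1e-12
    )
  }
  # the hoverfly back-transform never returns negative densities
  expect_true(all(back_transform(seq(-5, 1, by = 0.1), "log10_plus1") >= 0))
})

test_that("aggregation averages densities on the 150 m2 transect equivalent", {
  d <- tiny_study(1)
  obs <- aggregate_observations(d)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$mean_bee_density, 7) # one transect, count 7, area 150

  two <- d
  two$surveys <- dplyr::bind_rows(d$surveys, d$surveys)
  two$surveys$transect_id <- c("T1", "T2")
  two$surveys$bee_count <- c(4L, 10L)
  obs2 <- aggregate_observations(two)
  expect_equal(obs2$mean_bee_density, 7) # arithmetic mean of 4 and 10

  half <- d
  half$surveys$area_m2 <- 75
  half$surveys$bee_count <- 5L
  obs3 <- aggregate_observations(half)
  expect_equal(obs3$mean_bee_density, 10) # 5 * 150 / 75
})

test_that("aggregation yields one row per sampled landscape-round cell", {
  sim <- simulate_study(default_truth(n_landscapes = 6, n_rounds = 4, seed = 5L))
  obs <- aggregate_observations(sim$data)
  expect_equal(nrow(obs), 24L)
  expect_true(all(obs$mean_flower_cover_pct >= FLOWER_COVER_FLOOR))
  # transect-level alternative keeps one row per visit
  obs_t <- aggregate_observations(sim$data, level = "transect")
  expect_equal(nrow(obs_t), nrow(sim$data$surveys))
})

test_that("noise-free data are recovered exactly", {
  tr <- default_truth(seed = 3L, sd_landscape = 0, sd_round = 0, sd_resid = 0)
  sim <- simulate_study(tr)
  obs <- obs_from_latent(sim$latent) # exact cell densities
  for (taxon in c("bee", "hoverfly")) {
    fit <- fit_lmm(obs, model_spec(taxon), "reml")
    expect_true(fit$converged)
    truth <- tr$coef[[taxon]]
    expect_equal(fit$coefficients[names(truth)], truth, tolerance = 1e-6)
  }
})

test_that("with random variances forced to zero the LMM equals OLS", {
  sim <- simulate_study(default_truth(seed = 9L, sd_landscape = 0, sd_round = 0))
  obs <- aggregate_observations(sim$data)
  spec <- model_spec("bee")
  fit <- fit_lmm(obs, spec, "reml", zero_random = TRUE)
  expect_equal(fit$var_landscape, 0)
  expect_equal(fit$var_round, 0)
  # independent oracle: textbook least squares on the same design
  df <- data.frame(
    y = transform_response(obs$mean_bee_density, "log10"),
    snh = obs$snh_cover_pct,
    lf = log10(obs$mean_flower_cover_pct),
    rich = obs$mean_flower_richness,
    mfc = as.numeric(obs$mfc_flowering)
  )
  ols <- stats::coef(stats::lm(y ~ snh + lf + rich + mfc + snh:mfc, df))
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-6)
})

test_that("adding a covariate never decreases the ML log-likelihood", {
  sim <- simulate_study(default_truth(seed = 15L))
  obs <- aggregate_observations(sim$data)
  terms <- c("snh", "log10_flower_cover", "flower_richness", "mfc", "snh_mfc")
  lls <- vapply(seq_along(terms), function(k) {
    fit_lmm(obs, model_spec("hoverfly", terms[seq_len(k)]), "ml")$loglik_ml
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("a singular design is refused with the collinear term named", {
  sim <- simulate_study(default_truth(n_landscapes = 6, n_rounds = 4, seed = 2L))
  obs <- aggregate_observations(sim$data)
  obs$mean_flower_richness <- 2 * obs$snh_cover_pct # duplicate information
  expect_error(
    fit_lmm(obs, model_spec("bee", c("snh", "flower_richness")), "ml"),
    "collinear"
  )
})

test_that("likelihood-ratio tests follow the chi-square closed form", {
  sim <- simulate_study(default_truth(n_landscapes = 8, n_rounds = 4, seed = 6L))
  obs <- aggregate_observations(sim$data)
  full <- fit_lmm(obs, model_spec("bee"), "ml")
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  reduced <- fit_lmm(obs, model_spec("bee", c(
    "snh", "log10_flower_cover", "flower_richness", "mfc"
  )), "ml")
  lrt <- likelihood_ratio_test(full, reduced)
  expect_equal(lrt$df, 1L)
  expect_equal(lrt$statistic, max(0, 2 * (full$loglik_ml - reduced$loglik_ml)))
  # frozen chi-square(1) upper-tail oracle: a statistic of 6 has p 0.0143
  fake_full <- reduced
  fake_full$loglik_ml <- reduced$loglik_ml + 3.0
  fake_full$spec <- model_spec("bee")
  lrt6 <- likelihood_ratio_test(fake_full, reduced)
  expect_equal(lrt6$statistic, 6.0, tolerance = 1e-9)
  expect_equal(lrt6$p_value, 0.0143058784, tolerance = 1e-6)
  # the statistic depends only on the log-likelihood difference
  shifted_full <- fake_full
  shifted_full$loglik_ml <- fake_full$loglik_ml + 100
  shifted_red <- reduced
  shifted_red$loglik_ml <- reduced$loglik_ml + 100
  expect_equal(
    likelihood_ratio_test(shifted_full, shifted_red)$statistic,
    lrt6$statistic
  )
  # non-nested specs are refused
  expect_error(
    likelihood_ratio_test(reduced, full),
    "not nested"
  )
})

test_that("model selection drops a null interaction but keeps all main effects", {
  sim <- simulate_study(default_truth(seed = 42L)) # interaction truth is zero
  obs <- aggregate_observations(sim$data)
  sel <- select_model(obs, "bee")
  expect_false(sel$interaction_retained)
  expect_setequal(
    sel$model$spec$fixed_terms,
    c("snh", "log10_flower_cover", "flower_richness", "mfc")
  )
  # the LRT table always contains one row per candidate term
  expect_setequal(
    sel$lrt_table$term,
    c("snh", "log10_flower_cover", "flower_richness", "mfc", "snh_mfc")
  )
  expect_true(all(sel$lrt_table$retained[sel$lrt_table$term != "snh_mfc"]))
  # final model is a REML fit
  expect_identical(sel$model$objective, "reml")
})

test_that("a strong generated interaction is retained", {
  coef <- default_truth()$coef
  coef$bee["snh_mfc"] <- 0.012
  sim <- simulate_study(default_truth(coef = coef, seed = 13L))
  sel <- select_model(aggregate_observations(sim$data), "bee")
  expect_true(sel$interaction_retained)
  expect_true("snh_mfc" %in% sel$model$spec$fixed_terms)
})

test_that("variance inflation factors match their closed forms", {
  n <- 400
  base <- tiny_study(2)
  obs <- tibble::tibble(
    landscape_id = rep(c("L01", "L02"), n / 2),
    round = rep(1:2, each = n / 2),
    mean_bee_density = 5,
    mean_hoverfly_density = 5,
    mfc_flowering = FALSE
  )
  set.seed(31)
  # orthogonal pair by construction
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, 1), each = n / 2)
  obs$snh_cover_pct <- x1 + 10
  obs$mean_flower_richness <- x2 + 10
  obs$mean_flower_cover_pct <- 10^stats::rnorm(n)
  v <- compute_vif(obs, model_spec("bee", c("snh", "flower_richness")))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-12)

  # correlated pair: VIF = 1 / (1 - r^2) for both
  z1 <- stats::rnorm(n)
  z2 <- 0.6 * z1 + sqrt(1 - 0.36) * stats::rnorm(n)
  obs$snh_cover_pct <- z1 * 10 + 30
  obs$mean_flower_richness <- z2 * 3 + 12
  r <- stats::cor(obs$snh_cover_pct, obs$mean_flower_richness)
  v2 <- compute_vif(obs, model_spec("bee", c("snh", "flower_richness")))
  expect_equal(unname(v2), rep(1 / (1 - r^2), 2), tolerance = 1e-9)

  # duplicated predictor: infinite VIF with a warning
  obs$mean_flower_richness <- obs$snh_cover_pct
  expect_warning(
    v3 <- compute_vif(obs, model_spec("bee", c("snh", "flower_richness"))),
    "collinearity"
  )
  expect_true(all(is.infinite(v3)))
})
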