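#' Specify a density model
#'
#' The full candidate model relates transformed pollinator density at the
#' landscape-by-round level to percent SNH cover, log10 mean flower cover,
#' mean flower richness, the mass-flowering-crop (MFC) bloom indicator and
#' the SNH-by-MFC interaction, with crossed random intercepts for
#' landscape and sampling round (always both).
#'
#' @param taxon `"bee"` or `"hoverfly"`; picks the default response
#'   transform (`log10` for bees, `log10_plus1` for hoverflies).
#' @param fixed_terms Subset of `snh`, `log10_flower_cover`,
#'   `flower_richness`, `mfc`, `snh_mfc` (interaction requires both
#'   parents).  Default: all five.
#' @param response_transform Optional override of the taxon default.
#' @return A `model_spec` object.
#' @export
model_spec <- function(taxon = c("bee", "hoverfly"),
                       fixed_terms = c("snh", "log10_flower_cover",
                                       "flower_richness", "mfc", "snh_mfc"),
                       response_transform = NULL) {
  taxon <- match.arg(taxon)
  allowed <- c("snh", "log10_flower_cover", "flower_richness", "mfc", "snh_mfc")
  if (!all(fixed_terms %in% allowed)) {
    stop(
      "unknown fixed term(s): ",
      paste(setdiff(fixed_terms, allowed), collapse = ", "),
      call. = FALSE
    )
  }
  if ("snh_mfc" %in% fixed_terms && !all(c("snh", "mfc") %in% fixed_terms)) {
    stop("the snh_mfc interaction requires both snh and mfc main effects",
      call. = FALSE
    )
  }
  if (is.null(response_transform)) response_transform <- taxon_transform(taxon)
  response_transform <- match.arg(response_transform, c("log10", "log10_plus1"))
  structure(
    list(
      taxon = taxon,
      response_transform = response_transform,
      fixed_terms = unique(fixed_terms),
      random_terms = c("landscape", "round")
    ),
    class = "model_spec"
  )
}

# data-frame column backing each canonical fixed term
TERM_COLUMNS <- c(
  snh = "snh_cover_pct",
  log10_flower_cover = "lf_cover",
  flower_richness = "mean_flower_richness",
  mfc = "mfc_num",
  snh_mfc = "snh_cover_pct:mfc_num"
)

# model-frame used by fit_lmm and compute_vif
build_model_frame <- function(obs, spec,
                              cover_covariate = c("log_of_mean", "mean_of_log")) {
  cover_covariate <- match.arg(cover_covariate)
  needed <- c(
    "landscape_id", "round", "snh_cover_pct", "mean_flower_cover_pct",
    "mean_flower_richness", "mfc_flowering",
    switch(spec$taxon, bee = "mean_bee_density", hoverfly = "mean_hoverfly_density")
  )
  missing <- setdiff(needed, names(obs))
  if (length(missing) > 0) {
    stop("observations lack column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  dens <- obs[[switch(spec$taxon,
    bee = "mean_bee_density", hoverfly = "mean_hoverfly_density"
  )]]
  df <- data.frame(
    y = transform_response(dens, spec$response_transform),
    snh_cover_pct = obs$snh_cover_pct,
    lf_cover = if (cover_covariate == "log_of_mean") {
      if (any(obs$mean_flower_cover_pct <= 0)) {
        stop("mean flower cover must be strictly positive (it is log10-transformed)",
          call. = FALSE
        )
      }
      log10(obs$mean_flower_cover_pct)
    } else {
      obs$mean_log10_flower_cover
    },
    mean_flower_richness = obs$mean_flower_richness,
    mfc_num = as.numeric(obs$mfc_flowering),
    landscape_id = factor(obs$landscape_id),
    round_f = factor(obs$round)
  )
  df
}

fixed_formula_rhs <- function(fixed_terms) {
  if (length(fixed_terms) == 0) {
    "1"
  } else {
    paste(unname(TERM_COLUMNS[fixed_terms]), collapse = " + ")
  }
}

# map lmer fixef names back to canonical term names
canonical_coef_names <- function(nms) {
  lookup <- c(
    "(Intercept)" = "intercept",
    stats::setNames(names(TERM_COLUMNS), unname(TERM_COLUMNS)),
    "mfc_num:snh_cover_pct" = "snh_mfc"
  )
  out <- lookup[nms]
  if (any(is.na(out))) stop("internal: unmapped coefficient ", nms[is.na(out)])
  unname(out)
}

#' Fit the Gaussian linear mixed model for one taxon
#'
#' Maximises the Gaussian likelihood (ML) or restricted likelihood (REML)
#' of transformed density with the spec's fixed terms and crossed random
#' intercepts for landscape and round, via [lme4::lmer()].  The ML
#' log-likelihood is always reported (from an ML refit when
#' `objective = "reml"`), so fits are directly comparable in
#' [likelihood_ratio_test()].
#'
#' @param obs Aggregated observations from [aggregate_observations()].
#' @param spec A [model_spec()].
#' @param objective `"reml"` (default; reported coefficients) or `"ml"`
#'   (used for likelihood-ratio testing).
#' @param cover_covariate `"log_of_mean"` (default: log10 of the
#'   cell-mean flower cover) or `"mean_of_log"` (cell mean of per-transect
#'   log10 cover) — the two possible orders of averaging and
#'   transformation.
#' @param zero_random If `TRUE`, both random-intercept variances are
#'   fixed at zero instead of estimated (the model is still solved
#'   through the mixed-model machinery, profiled at the boundary).  This
#'   is the degenerate limit in which the LMM coincides with ordinary
#'   least squares; it exists for verification and sensitivity checks.
#' @return A `density_model`: list with `spec`, named `coefficients` on
#'   the transformed scale, variance components `var_landscape`,
#'   `var_round`, `var_resid`, `loglik_ml`, honest `converged` flag,
#'   `n_obs`, fixed-effect `vcov`, and observed covariate `ranges` used
#'   for extrapolation warnings.
#' @section Convergence flag:
#' `converged` is `FALSE` whenever the optimiser reports failure or lme4
#' raises a non-singularity convergence warning.  The one exception is an
#' exact-fit degenerate dataset (residual variance numerically zero),
#' where lme4's scaled-gradient check is undefined and its warnings are
#' ignored; the raw messages are always kept in `$messages`.
#' @export
fit_lmm <- function(obs, spec, objective = c("reml", "ml"),
                    cover_covariate = c("log_of_mean", "mean_of_log"),
                    zero_random = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  objective <- match.arg(objective)
  cover_covariate <- match.arg(cover_covariate)
  df <- build_model_frame(obs, spec, cover_covariate)
  if (nlevels(df$landscape_id) < 2 || nlevels(df$round_f) < 2) {
    stop("need at least 2 landscapes and 2 rounds to fit the mixed model",
      call. = FALSE
    )
  }

  rhs <- fixed_formula_rhs(spec$fixed_terms)
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear term(s): ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }

  f <- stats::as.formula(
    paste("y ~", rhs, "+ (1 | landscape_id) + (1 | round_f)")
  )
  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore",
    calc.derivs = TRUE
  )
  if (zero_random) {
    return(fit_lmm_zero_random(df, f, X, spec, objective, cover_covariate, obs, ctrl))
  }
  warnings_seen <- character()
  fit <- withCallingHandlers(
    lme4::lmer(f, data = df, REML = (objective == "reml"), control = ctrl),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  opt_ok <- isTRUE(fit@optinfo$conv$opt == 0)
  lme4_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  real_problems <- c(
    warnings_seen[!grepl("singular", warnings_seen, ignore.case = TRUE)],
    lme4_msgs[!grepl("singular", lme4_msgs, ignore.case = TRUE)]
  )
  # an exact-fit dataset drives sigma to 0, where the scaled-gradient
  # convergence checks are undefined and warn spuriously
  exact_fit <- stats::sigma(fit)^2 < 1e-10 * max(1, stats::var(df$y))
  converged <- opt_ok && (length(real_problems) == 0 || exact_fit)

  loglik_ml <- if (objective == "ml") {
    as.numeric(stats::logLik(fit))
  } else {
    as.numeric(stats::logLik(lme4::refitML(fit)))
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  getvar <- function(grp) vc$vcov[match(grp, vc$grp)]
  coefs <- lme4::fixef(fit)
  names(coefs) <- canonical_coef_names(names(coefs))
  vcv <- as.matrix(stats::vcov(fit))
  dimnames(vcv) <- list(names(coefs), names(coefs))

  structure(
    list(
      spec = spec,
      coefficients = coefs,
      var_landscape = getvar("landscape_id"),
      var_round = getvar("round_f"),
      var_resid = getvar("Residual"),
      loglik_ml = loglik_ml,
      converged = converged,
      n_obs = nrow(df),
      vcov = vcv,
      objective = objective,
      cover_covariate = cover_covariate,
      ranges = list(
        snh_cover_pct = range(obs$snh_cover_pct),
        flower_cover_pct = range(obs$mean_flower_cover_pct),
        flower_richness = range(obs$mean_flower_richness)
      ),
      messages = c(warnings_seen, lme4_msgs)
    ),
    class = "density_model"
  )
}

# LMM profiled at theta = (0, 0): both random-intercept variances fixed
# at zero.  Solved through lme4's penalised-least-squares machinery, not
# by calling lm(), so the OLS-limit identity stays a genuine cross-check.
fit_lmm_zero_random <- function(df, f, X, spec, objective, cover_covariate,
                                obs, ctrl) {
  make_devfun <- function(reml) {
    lf <- lme4::lFormula(f, data = df, REML = reml, control = ctrl)
    do.call(lme4::mkLmerDevfun, lf)
  }
  devf <- make_devfun(objective == "reml")
  dev <- devf(c(0, 0))
  beta <- environment(devf)$pp$beta(1)
  names(beta) <- canonical_coef_names(colnames(X))
  n <- nrow(df)
  p <- ncol(X)
  rss <- sum((df$y - as.vector(X %*% beta))^2)
  var_resid <- rss / if (objective == "reml") (n - p) else n
  loglik_ml <- if (objective == "ml") {
    -dev / 2
  } else {
    devf_ml <- make_devfun(FALSE)
    -devf_ml(c(0, 0)) / 2
  }
  vcv <- var_resid * solve(crossprod(X))
  dimnames(vcv) <- list(names(beta), names(beta))
  structure(
    list(
      spec = spec, coefficients = beta,
      var_landscape = 0, var_round = 0, var_resid = var_resid,
      loglik_ml = loglik_ml, converged = TRUE, n_obs = n,
      vcov = vcv, objective = objective, cover_covariate = cover_covariate,
      ranges = list(
        snh_cover_pct = range(obs$snh_cover_pct),
        flower_cover_pct = range(obs$mean_flower_cover_pct),
        flower_richness = range(obs$mean_flower_richness)
      ),
      messages = character()
    ),
    class = "density_model"
  )
}

#' Construct a density model from known coefficients
#'
#' Builds a `density_model` directly from coefficient values rather than
#' from data — for scenario exploration with hypothesised effect sizes and
#' for closed-form checks of the extrapolation and trade-off machinery.
#' Terms absent from `coefficients` are treated as zero.
#'
#' @inheritParams model_spec
#' @param coefficients Named numeric vector using the canonical names
#'   `intercept`, `snh`, `log10_flower_cover`, `flower_richness`, `mfc`,
#'   `snh_mfc`; must at least name `intercept`.
#' @param ranges Optional observed-covariate ranges (as in [fit_lmm()]
#'   output) enabling extrapolation warnings.
#' @return A `density_model` with `converged = TRUE` and `n_obs = NA`.
#' @examples
#' m <- density_model("bee", c(intercept = 1, log10_flower_cover = 0.4))
#' predict_density(m, snh_pct = 30, flower_cover_pct = 10, richness = 12)
#' @export
density_model <- function(taxon = c("bee", "hoverfly"), coefficients,
                          response_transform = NULL, ranges = NULL) {
  taxon <- match.arg(taxon)
  if (!"intercept" %in% names(coefficients)) {
    stop("`coefficients` must name at least 'intercept'", call. = FALSE)
  }
  unknown <- setdiff(names(coefficients), COEF_NAMES)
  if (length(unknown) > 0) {
    stop("unknown coefficient(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  terms <- setdiff(names(coefficients), "intercept")
  if ("snh_mfc" %in% terms) terms <- union(terms, c("snh", "mfc"))
  spec <- model_spec(taxon,
    fixed_terms = if (length(terms)) terms else character(),
    response_transform = response_transform
  )
  full <- stats::setNames(numeric(length(spec$fixed_terms) + 1),
    c("intercept", spec$fixed_terms)
  )
  full[names(coefficients)] <- coefficients
  structure(
    list(
      spec = spec, coefficients = full,
      var_landscape = NA_real_, var_round = NA_real_, var_resid = NA_real_,
      loglik_ml = NA_real_, converged = TRUE, n_obs = NA_integer_,
      vcov = NULL, objective = "none", cover_covariate = "log_of_mean",
      ranges = ranges, messages = character()
    ),
    class = "density_model"
  )
}

#' @export
print.density_model <- function(x, ...) {
  cat("<density_model> taxon:", x$spec$taxon,
    "| response:", x$spec$response_transform,
    if (!x$converged) "| NOT CONVERGED" else "", "\n"
  )
  print(round(x$coefficients, 5))
  if (!is.na(x$var_resid)) {
    cat(sprintf(
      "variances: landscape %.4f, round %.4f, residual %.4f | logLik(ML) %.2f | n = %d\n",
      x$var_landscape, x$var_round, x$var_resid, x$loglik_ml, x$n_obs
    ))
  }
  invisible(x)
}

#' Likelihood-ratio test between nested density models
#'
#' Both models must be ML fits on identical observations with the reduced
#' fixed terms nested in the full set.  The statistic `2 * (logLik_full -
#' logLik_reduced)` is clamped at zero (optimizer noise can make it
#' marginally negative) and referred to the chi-square upper tail with
#' degrees of freedom equal to the difference in fixed-term count.
#'
#' @param full,reduced `density_model` objects from [fit_lmm()] with
#'   `objective = "ml"`.
#' @return An `lrt_result`: list with `term` (the tested term(s)),
#'   `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "density_model"), inherits(reduced, "density_model"))
  if (!identical(full$spec$taxon, reduced$spec$taxon) ||
    !identical(full$spec$response_transform, reduced$spec$response_transform)) {
    stop("models must share taxon and response transform", call. = FALSE)
  }
  extra <- setdiff(reduced$spec$fixed_terms, full$spec$fixed_terms)
  if (length(extra) > 0) {
    stop("models are not nested; reduced model has extra term(s): ",
      paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.na(full$n_obs) && !is.na(reduced$n_obs) &&
    full$n_obs != reduced$n_obs) {
    stop("models were fitted to different numbers of observations", call. = FALSE)
  }
  dropped <- setdiff(full$spec$fixed_terms, reduced$spec$fixed_terms)
  df <- length(dropped)
  statistic <- max(0, 2 * (full$loglik_ml - reduced$loglik_ml))
  p_value <- if (df == 0) 1 else stats::pchisq(statistic, df, lower.tail = FALSE)
  structure(
    list(
      term = if (df == 0) "(none)" else paste(dropped, collapse = " + "),
      statistic = statistic, df = df, p_value = p_value
    ),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf(
    "LRT %s: chisq(%d) = %.3f, p = %.4g\n",
    x$term, x$df, x$statistic, x$p_value
  ))
  invisible(x)
}

#' Model selection by interaction pruning
#'
#' Follows the analysis protocol: fit the full model (four main effects
#' plus the SNH-by-MFC interaction), test the interaction with a
#' likelihood-ratio test at `alpha`, drop it when non-significant so main
#' effects stay interpretable, and always retain all four main effects in
#' the final model regardless of their significance (they are needed for
#' the landscape extrapolation).  Main-effect LRTs are single-term
#' deletions from the main-effects model; the final reported model is a
#' REML refit of the selected specification.
#'
#' @inheritParams fit_lmm
#' @param taxon `"bee"` or `"hoverfly"`.
#' @param alpha Interaction-removal significance threshold (default 0.05;
#'   marginal cases such as p = 0.06 are removed).
#' @return A `model_selection` list: `model` (final REML `density_model`),
#'   `lrt_table` (tibble with one row per candidate term: `term`,
#'   `statistic`, `df`, `p_value`, `retained`), `vif` (named VIFs of the
#'   final model), `interaction_retained`.
#' @export
select_model <- function(obs, taxon = c("bee", "hoverfly"), alpha = 0.05,
                         cover_covariate = c("log_of_mean", "mean_of_log")) {
  taxon <- match.arg(taxon)
  cover_covariate <- match.arg(cover_covariate)
  mains <- c("snh", "log10_flower_cover", "flower_richness", "mfc")
  full_spec <- model_spec(taxon, c(mains, "snh_mfc"))
  main_spec <- model_spec(taxon, mains)

  full_ml <- fit_lmm(obs, full_spec, "ml", cover_covariate)
  main_ml <- fit_lmm(obs, main_spec, "ml", cover_covariate)
  int_lrt <- likelihood_ratio_test(full_ml, main_ml)
  keep_interaction <- int_lrt$p_value < alpha

  rows <- list(tibble::tibble(
    term = "snh_mfc", statistic = int_lrt$statistic, df = int_lrt$df,
    p_value = int_lrt$p_value, retained = keep_interaction
  ))
  for (m in mains) {
    red <- fit_lmm(obs, model_spec(taxon, setdiff(mains, m)), "ml", cover_covariate)
    lrt <- likelihood_ratio_test(main_ml, red)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      term = m, statistic = lrt$statistic, df = lrt$df,
      p_value = lrt$p_value, retained = TRUE
    )
  }
  final_spec <- if (keep_interaction) full_spec else main_spec
  final <- fit_lmm(obs, final_spec, "reml", cover_covariate)
  structure(
    list(
      model = final,
      lrt_table = dplyr::bind_rows(rows),
      vif = compute_vif(obs, final_spec, cover_covariate),
      interaction_retained = keep_interaction
    ),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection for", x$spec$taxon %||% x$model$spec$taxon, "\n")
  print(x$lrt_table)
  cat("\nFinal model:\n")
  print(x$model)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variance inflation factors of the fixed-effect design
#'
#' Computes, for every non-intercept fixed term, `1 / (1 - R^2)` where
#' `R^2` is from regressing that design column on all the others — the
#' collinearity diagnostic checked on every fitted model (all below 1.5
#' in the study design this package emulates).
#'
#' @inheritParams fit_lmm
#' @return Named numeric vector of VIFs.  Perfect collinearity yields
#'   `Inf` with a warning.
#' @export
compute_vif <- function(obs, spec,
                        cover_covariate = c("log_of_mean", "mean_of_log")) {
  stopifnot(inherits(spec, "model_spec"))
  cover_covariate <- match.arg(cover_covariate)
  if (length(spec$fixed_terms) < 2) {
    stop("VIFs need at least 2 fixed terms", call. = FALSE)
  }
  df <- build_model_frame(obs, spec, cover_covariate)
  X <- stats::model.matrix(
    stats::as.formula(paste("~", fixed_formula_rhs(spec$fixed_terms))), df
  )
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2 > 1 - 1e-12) {
      warning("perfect collinearity involving term ", colnames(X)[j],
        call. = FALSE
      )
      Inf
    } else {
      1 / (1 - r2)
    }
  }, numeric(1))
  stats::setNames(vifs, canonical_coef_names(colnames(X)))
}
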