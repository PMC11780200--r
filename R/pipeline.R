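#' Pipeline configuration
#'
#' Validates and normalises the configuration driving [run_pipeline()].
#' Unknown keys and undocumented enum tokens are rejected before any
#' computation.
#'
#' @param surveys,landscapes Paths to the input CSV tables.
#' @param out_dir Output directory for the run.
#' @param taxa Character subset of `c("bee", "hoverfly")`.
#' @param aggregation `"cell"` or `"transect"` (see
#'   [aggregate_observations()]).
#' @param cover_covariate `"log_of_mean"` or `"mean_of_log"` (see
#'   [fit_lmm()]).
#' @param quantile_convention `"upper"`, `"lower"` or `"midpoint"` (see
#'   [make_quality_grid()]).
#' @param step_ratios Integer vector within 1..3.
#' @param interpolation `"linear"` or `"spline"` threshold interpolation.
#' @param strict Strict flower-cover floor validation (see
#'   [read_study()]).
#' @param alpha Interaction-removal threshold.
#' @param make_figures Write PNG figures.
#' @param seed Integer seed recorded in the run log (the analysis itself
#'   is deterministic given the inputs).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(surveys, landscapes, out_dir,
                            taxa = c("bee", "hoverfly"),
                            aggregation = "cell",
                            cover_covariate = "log_of_mean",
                            quantile_convention = "upper",
                            step_ratios = 1:3,
                            interpolation = "linear",
                            strict = TRUE,
                            alpha = 0.05,
                            make_figures = TRUE,
                            seed = 1L) {
  cfg <- list(
    surveys = surveys, landscapes = landscapes, out_dir = out_dir,
    taxa = taxa, aggregation = aggregation,
    cover_covariate = cover_covariate,
    quantile_convention = quantile_convention,
    step_ratios = step_ratios, interpolation = interpolation,
    strict = strict, alpha = alpha, make_figures = make_figures,
    seed = seed
  )
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  known <- c(
    "surveys", "landscapes", "out_dir", "taxa", "aggregation",
    "cover_covariate", "quantile_convention", "step_ratios",
    "interpolation", "strict", "alpha", "make_figures", "seed"
  )
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  missing <- setdiff(c("surveys", "landscapes", "out_dir"), names(cfg))
  if (length(missing) > 0) {
    stop("config must set: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  defaults <- list(
    taxa = c("bee", "hoverfly"), aggregation = "cell",
    cover_covariate = "log_of_mean", quantile_convention = "upper",
    step_ratios = 1:3, interpolation = "linear", strict = TRUE,
    alpha = 0.05, make_figures = TRUE, seed = 1L
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  check_enum <- function(value, allowed, nm) {
    if (!all(value %in% allowed)) {
      stop(
        "config `", nm, "`: unknown token '",
        paste(setdiff(value, allowed), collapse = "', '"),
        "' (allowed: ", paste(allowed, collapse = ", "), ")",
        call. = FALSE
      )
    }
  }
  check_enum(cfg$taxa, c("bee", "hoverfly"), "taxa")
  check_enum(cfg$aggregation, c("cell", "transect"), "aggregation")
  check_enum(cfg$cover_covariate, c("log_of_mean", "mean_of_log"), "cover_covariate")
  check_enum(cfg$quantile_convention, c("upper", "lower", "midpoint"), "quantile_convention")
  check_enum(cfg$interpolation, c("linear", "spline"), "interpolation")
  if (!all(cfg$step_ratios %in% 1:3)) {
    stop("config `step_ratios` must be within 1..3", call. = FALSE)
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("config `alpha` must be in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_pipeline_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes read -> aggregate -> model selection -> landscape
#' extrapolation -> trade-off analysis for each taxon, writing into
#' `config$out_dir`: `aggregated.csv`, `model_<taxon>.json`,
#' `matrix_<taxon>.csv` (long format), `thresholds.csv`, `scenarios.csv`,
#' figures (when `make_figures`) and a `run.log` with the package
#' version, config echo, input checksums and stage timings.  Any stage
#' failure aborts with the stage name; outputs and the log written so far
#' are kept.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  logf <- function(...) {
    cat(sprintf("[%s] ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      sprintf(...), "\n",
      sep = "", file = log_path, append = TRUE
    )
  }
  cat("", file = log_path)
  logf("pollscape %s", as.character(utils::packageVersion("pollscape")))
  cfg_echo <- config
  for (nm in names(cfg_echo)) {
    logf("config %s: %s", nm, paste(format(cfg_echo[[nm]]), collapse = ", "))
  }
  for (p in c(config$surveys, config$landscapes)) {
    if (file.exists(p)) logf("input %s md5 %s", p, unname(tools::md5sum(p)))
  }

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
    logf("stage %s ok (%.2fs)", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  data <- stage("read", read_study(config$surveys, config$landscapes,
    strict = config$strict
  ))
  obs <- stage("aggregate", {
    o <- aggregate_observations(data, level = config$aggregation)
    write_table(o, file.path(out, "aggregated.csv"))
    o
  })

  models <- list()
  for (taxon in config$taxa) {
    models[[taxon]] <- stage(paste0("select_model_", taxon), {
      sel <- select_model(obs, taxon,
        alpha = config$alpha,
        cover_covariate = config$cover_covariate
      )
      write_model_json(sel, file.path(out, paste0("model_", taxon, ".json")))
      sel$model
    })
  }

  quality <- stage("quality_grid", make_quality_grid(
    obs,
    convention = config$quantile_convention
  ))
  matrices <- list()
  for (taxon in config$taxa) {
    matrices[[taxon]] <- stage(paste0("extrapolate_", taxon), {
      pm <- suppressWarnings(
        build_population_matrix(models[[taxon]], quality = quality)
      )
      write_table(as_tibble(pm), file.path(out, paste0("matrix_", taxon, ".csv")))
      pm
    })
  }

  thresholds <- stage("thresholds", {
    rows <- list()
    for (taxon in config$taxa) {
      for (k in config$step_ratios) {
        rc <- ratio_curve(matrices[[taxon]], k_quality = k)
        thr <- vapply(
          rc$thresholds$quality_level,
          function(j) find_threshold(rc, j, method = config$interpolation),
          numeric(1)
        )
        rows[[length(rows) + 1L]] <- tibble::tibble(
          taxon = taxon, step_ratio = as.integer(k),
          quality_level = rc$thresholds$quality_level,
          threshold_snh_pct = thr
        )
      }
    }
    t <- dplyr::bind_rows(rows)
    write_table(t, file.path(out, "thresholds.csv"))
    t
  })

  stage("scenarios", {
    sc <- scenario_report(models, obs,
      step_ratios = config$step_ratios,
      quantile_convention = config$quantile_convention
    )
    write_table(sc, file.path(out, "scenarios.csv"))
    sc
  })

  if (isTRUE(config$make_figures)) {
    for (taxon in config$taxa) {
      stage(paste0("figures_", taxon), {
        plot_population_surface(
          matrices[[taxon]],
          file.path(out, paste0("population_", taxon, ".png"))
        )
        rc1 <- ratio_curve(matrices[[taxon]], k_quality = 1)
        plot_ratio_curves(
          rc1,
          file.path(out, paste0("ratios_", taxon, ".png"))
        )
      })
    }
  }
  logf("pipeline complete")
  invisible(out)
}

#' Write a selected model (or bare model) as JSON
#'
#' Serialises the model specification, coefficients, variance components,
#' log-likelihood, covariate ranges and — when given a full
#' [select_model()] result — the LRT and VIF tables.
#'
#' @param x A `model_selection` or `density_model`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(x, path) {
  if (inherits(x, "model_selection")) {
    model <- x$model
    extra <- list(
      lrt_table = x$lrt_table,
      vif = as.list(x$vif),
      interaction_retained = x$interaction_retained
    )
  } else if (inherits(x, "density_model")) {
    model <- x
    extra <- NULL
  } else {
    stop("`x` must be a model_selection or density_model", call. = FALSE)
  }
  payload <- c(
    list(
      spec = unclass(model$spec),
      coefficients = as.list(model$coefficients),
      var_landscape = model$var_landscape,
      var_round = model$var_round,
      var_resid = model$var_resid,
      loglik_ml = model$loglik_ml,
      converged = model$converged,
      n_obs = model$n_obs,
      objective = model$objective,
      cover_covariate = model$cover_covariate,
      ranges = model$ranges
    ),
    extra
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read a density model back from JSON
#'
#' Reconstructs a `density_model` usable by [predict_density()] and the
#' downstream extrapolation/trade-off functions.
#'
#' @param path A file written by [write_model_json()].
#' @return A `density_model`.
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- model_spec(
    taxon = p$spec$taxon,
    fixed_terms = if (length(p$spec$fixed_terms)) p$spec$fixed_terms else character(),
    response_transform = p$spec$response_transform
  )
  structure(
    list(
      spec = spec,
      coefficients = unlist(p$coefficients),
      var_landscape = p$var_landscape,
      var_round = p$var_round,
      var_resid = p$var_resid,
      loglik_ml = p$loglik_ml,
      converged = isTRUE(p$converged),
      n_obs = p$n_obs,
      vcov = NULL,
      objective = p$objective,
      cover_covariate = p$cover_covariate,
      ranges = p$ranges,
      messages = character()
    ),
    class = "density_model"
  )
}
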