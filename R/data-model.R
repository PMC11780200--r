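#' @title Survey and landscape data model
#' @description
#' A study dataset couples two tables: one row per transect visit
#' (`surveys`) and one row per landscape (`landscapes`).  All readers and
#' the synthetic generator funnel through [study_dataset()], so every
#' downstream function can assume the invariants below hold.
#'
#' Survey columns: `landscape_id`, `round` (integer, 1-based sampling
#' round), `transect_id`, `habitat_class` (`"herbaceous"` or `"woody"`),
#' `bee_count`, `hoverfly_count` (non-negative integers per 15-min visit),
#' `area_m2` (positive, 150 for a standard transect), `flower_cover_pct`
#' (total flower cover, percent of transect area; any strictly positive
#' value is at least 0.025, the field recording floor), `flower_richness`
#' (non-negative integer count of flowering species), `mfc_flowering`
#' (logical: was a mass-flowering crop in bloom in the landscape).
#'
#' Landscape columns: `landscape_id`, `snh_cover_pct` (percent seminatural
#' habitat cover in (0, 100]), `radius_m` (positive landscape radius,
#' 750 m in the study design).
#' @name data-model
NULL

SURVEY_COLS <- c(
  "landscape_id", "round", "transect_id", "habitat_class", "bee_count",
  "hoverfly_count", "area_m2", "flower_cover_pct", "flower_richness",
  "mfc_flowering"
)
LANDSCAPE_COLS <- c("landscape_id", "snh_cover_pct", "radius_m")
HABITAT_CLASSES <- c("herbaceous", "woody")

#' Flower-cover recording floor (percent)
#'
#' Field estimates of flower cover below 0.05% are recorded at a fixed
#' 0.025%; positive cover values below this floor cannot occur in a valid
#' dataset.
#' @export
FLOWER_COVER_FLOOR <- 0.025

#' Assemble and validate a study dataset
#'
#' @param surveys Data frame of transect visits (see [data-model]).
#' @param landscapes Data frame of landscape metadata.
#' @param strict If `TRUE` (default), positive flower cover below the
#'   0.025% recording floor is a validation error; if `FALSE` such values
#'   are floored to 0.025 with a warning (useful for external data whose
#'   recording convention differed).
#' @return An object of class `study_dataset`: a list with tibbles
#'   `surveys` and `landscapes` in canonical column order and types.
#' @examples
#' d <- simulate_study(default_truth(n_landscapes = 4, n_rounds = 2))$data
#' d
#' @export
study_dataset <- function(surveys, landscapes, strict = TRUE) {
  surveys <- tibble::as_tibble(surveys)
  landscapes <- tibble::as_tibble(landscapes)
  check_columns(surveys, SURVEY_COLS, "surveys")
  check_columns(landscapes, LANDSCAPE_COLS, "landscapes")

  surveys <- coerce_survey_types(surveys)
  landscapes <- coerce_landscape_types(landscapes)

  diag <- character()
  diag <- c(diag, validate_landscape_rows(landscapes))
  v <- validate_survey_rows(surveys, landscapes, strict = strict)
  diag <- c(diag, v$diagnostics)
  surveys <- v$surveys
  if (length(diag) > 0) {
    stop(validation_error(diag))
  }
  structure(
    list(
      surveys = surveys[, SURVEY_COLS],
      landscapes = landscapes[, LANDSCAPE_COLS]
    ),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(
    "<study_dataset> ", nrow(x$surveys), " transect visits in ",
    nrow(x$landscapes), " landscapes, rounds ",
    min(x$surveys$round), "-", max(x$surveys$round), "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a study dataset from delimited text files
#'
#' Both files are comma-separated UTF-8 with a mandatory header row and
#' `.` decimal separator.  Column order is free; column names are fixed
#' (see [data-model]).  Every malformed row yields one row-numbered
#' diagnostic and the whole read fails if any row is invalid, so a
#' returned dataset is always fully valid.
#'
#' @param survey_path,landscape_path Paths to `surveys.csv` and
#'   `landscapes.csv`.
#' @inheritParams study_dataset
#' @return A [study_dataset()].
#' @export
read_study <- function(survey_path, landscape_path, strict = TRUE) {
  for (p in c(survey_path, landscape_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  surveys <- readr::read_csv(
    survey_path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  )
  landscapes <- readr::read_csv(
    landscape_path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  )
  study_dataset(surveys, landscapes, strict = strict)
}

#' Write a table as comma-separated text
#'
#' Writes any non-empty data frame with a header row and full numeric
#' precision, so that `read_study()` of written survey/landscape tables
#' round-trips exactly.
#'
#' @param rows Data frame with at least one row.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("`rows` must be a data frame", call. = FALSE)
  if (nrow(rows) == 0) {
    stop("refusing to write an empty table to ", path, call. = FALSE)
  }
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' Write both tables of a study dataset
#'
#' @param data A [study_dataset()].
#' @param dir Output directory (created if needed); writes `surveys.csv`
#'   and `landscapes.csv`.
#' @return `dir`, invisibly.
#' @export
write_study <- function(data, dir) {
  stopifnot(inherits(data, "study_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(data$surveys, file.path(dir, "surveys.csv"))
  write_table(data$landscapes, file.path(dir, "landscapes.csv"))
  invisible(dir)
}

# ---- internal validation helpers -------------------------------------

validation_error <- function(diagnostics) {
  shown <- utils::head(diagnostics, 25)
  msg <- paste0(
    "invalid study data (", length(diagnostics), " problem",
    if (length(diagnostics) > 1) "s" else "", "):\n",
    paste0("  - ", shown, collapse = "\n"),
    if (length(diagnostics) > length(shown)) "\n  ..." else ""
  )
  structure(
    class = c("pollscape_validation_error", "error", "condition"),
    list(message = msg, call = NULL, diagnostics = diagnostics)
  )
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(
      "schema error in ", what, ": missing column(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(df)
}

parse_mfc <- function(x) {
  if (is.logical(x)) return(x)
  tok <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(tok))
  out[tok %in% c("true", "yes", "1", "t", "y")] <- TRUE
  out[tok %in% c("false", "no", "0", "f", "n")] <- FALSE
  out
}

coerce_survey_types <- function(s) {
  s$landscape_id <- as.character(s$landscape_id)
  s$transect_id <- as.character(s$transect_id)
  s$habitat_class <- tolower(as.character(s$habitat_class))
  for (col in c("round", "bee_count", "hoverfly_count", "flower_richness")) {
    v <- suppressWarnings(as.numeric(s[[col]]))
    s[[col]] <- ifelse(!is.na(v) & v == round(v), as.integer(round(v)), NA_integer_)
    s[[paste0(".raw_", col)]] <- v  # kept for diagnostics, stripped later
  }
  for (col in c("area_m2", "flower_cover_pct")) {
    s[[col]] <- suppressWarnings(as.numeric(s[[col]]))
  }
  s$.raw_mfc <- s$mfc_flowering
  s$mfc_flowering <- parse_mfc(s$mfc_flowering)
  s
}

coerce_landscape_types <- function(l) {
  l$landscape_id <- as.character(l$landscape_id)
  l$snh_cover_pct <- suppressWarnings(as.numeric(l$snh_cover_pct))
  l$radius_m <- suppressWarnings(as.numeric(l$radius_m))
  l
}

validate_landscape_rows <- function(l) {
  diag <- character()
  dup <- l$landscape_id[duplicated(l$landscape_id)]
  if (length(dup) > 0) {
    diag <- c(diag, paste0("landscapes: duplicated landscape_id ", unique(dup)))
  }
  for (i in seq_len(nrow(l))) {
    snh <- l$snh_cover_pct[i]
    if (is.na(snh) || snh <= 0 || snh > 100) {
      diag <- c(diag, sprintf(
        "landscapes row %d: snh_cover_pct must be in (0, 100], got %s",
        i, format(l$snh_cover_pct[i])
      ))
    }
    if (is.na(l$radius_m[i]) || l$radius_m[i] <= 0) {
      diag <- c(diag, sprintf(
        "landscapes row %d: radius_m must be > 0, got %s",
        i, format(l$radius_m[i])
      ))
    }
  }
  diag
}

validate_survey_rows <- function(s, landscapes, strict) {
  diag <- character()
  n_floored <- 0L
  for (i in seq_len(nrow(s))) {
    row_diag <- function(field, msg) {
      sprintf("surveys row %d: %s %s", i, field, msg)
    }
    for (col in c("round", "bee_count", "hoverfly_count", "flower_richness")) {
      raw <- s[[paste0(".raw_", col)]][i]
      if (is.na(s[[col]][i])) {
        diag <- c(diag, row_diag(col, "must be a non-negative integer"))
      } else if (s[[col]][i] < 0 || (col == "round" && s[[col]][i] < 1)) {
        diag <- c(diag, row_diag(
          col,
          sprintf("must be %s, got %s", if (col == "round") ">= 1" else ">= 0", format(raw))
        ))
      }
    }
    if (is.na(s$area_m2[i]) || s$area_m2[i] <= 0) {
      diag <- c(diag, row_diag("area_m2", "must be > 0"))
    }
    if (!s$habitat_class[i] %in% HABITAT_CLASSES) {
      diag <- c(diag, row_diag(
        "habitat_class",
        sprintf("unknown token '%s' (expected herbaceous/woody)", s$habitat_class[i])
      ))
    }
    fc <- s$flower_cover_pct[i]
    if (is.na(fc) || fc < 0 || fc > 100) {
      diag <- c(diag, row_diag("flower_cover_pct", "must be in [0, 100]"))
    } else if (fc > 0 && fc < FLOWER_COVER_FLOOR) {
      if (strict) {
        diag <- c(diag, row_diag(
          "flower_cover_pct",
          sprintf("positive value %s below the %s%% recording floor", format(fc), FLOWER_COVER_FLOOR)
        ))
      } else {
        s$flower_cover_pct[i] <- FLOWER_COVER_FLOOR
        n_floored <- n_floored + 1L
      }
    }
    if (is.na(s$mfc_flowering[i])) {
      diag <- c(diag, row_diag(
        "mfc_flowering",
        sprintf("unrecognised token '%s' (accepted: true/false, yes/no, 1/0)", format(s$.raw_mfc[i]))
      ))
    }
    if (!s$landscape_id[i] %in% landscapes$landscape_id) {
      diag <- c(diag, row_diag(
        "landscape_id",
        sprintf("'%s' has no matching landscape", s$landscape_id[i])
      ))
    }
  }
  orphan <- setdiff(landscapes$landscape_id, s$landscape_id)
  if (length(orphan) > 0) {
    diag <- c(diag, paste0(
      "landscapes without any survey: ", paste(orphan, collapse = ", ")
    ))
  }
  if (n_floored > 0) {
    warning(
      n_floored, " flower_cover_pct value(s) below ", FLOWER_COVER_FLOOR,
      "% floored to the recording floor",
      call. = FALSE
    )
  }
  s <- s[, !startsWith(names(s), ".raw_")]
  list(surveys = s, diagnostics = diag)
}
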