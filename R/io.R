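#' Default analysis configuration
#'
#' Returns the full set of configuration keys understood by the pipeline,
#' with their default values. [load_config()] starts from this list and
#' overlays whatever the configuration file provides.
#'
#' @details
#' Keys and defaults:
#' \describe{
#'   \item{threshold_k}{Multiplier applied to the DMSO-well response SD when
#'     deriving the per-endpoint noise threshold (default 3).}
#'   \item{min_threshold}{Lower bound, in % response units, on the noise
#'     threshold; guards degenerate (noise-free) plates (default 1).}
#'   \item{interference_tolerance}{Fold difference within which an active
#'     counter-screen POD renders a primary call inconclusive (default 3).}
#'   \item{aroer_dilution_factor}{Fold cutoff for the aromatase-inhibition /
#'     ER-antagonism POD comparison (default 3).}
#'   \item{imputation_pod}{POD in ug/mL assigned to inactive or inconclusive
#'     cells of the profile matrix (default 1000).}
#'   \item{perplexity}{t-SNE perplexity (default 30).}
#'   \item{tsne_iterations}{t-SNE iteration count (default 5000).}
#'   \item{seed}{Random seed for the simulator and the embedding (default 1).}
#'   \item{first_two_cols_empty}{Whether the plate layout declares columns
#'     1--2 empty (default TRUE).}
#'   \item{pattern_method}{Plate pattern correction, "none" or
#'     "median_polish" (default "none").}
#'   \item{z_active_only}{Whether Z-scoring of wAUC for substance ranking
#'     uses active cells only (default TRUE).}
#'   \item{min_group_size}{Minimum lots per botanical group for the
#'     within/between correlation curves (default 3).}
#' }
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    threshold_k = 3,
    min_threshold = 1,
    interference_tolerance = 3,
    aroer_dilution_factor = 3,
    imputation_pod = 1000,
    perplexity = 30,
    tsne_iterations = 5000,
    seed = 1,
    first_two_cols_empty = TRUE,
    pattern_method = "none",
    z_active_only = TRUE,
    min_group_size = 3
  )
}

#' Load a study configuration file
#'
#' Reads a YAML key--value configuration file and overlays it on
#' [default_config()]. Unknown keys are an error (listing the valid keys),
#' so typos never silently fall back to defaults.
#'
#' @param path Path to a YAML configuration file. An empty file yields all
#'   defaults.
#' @return Named list of configuration values.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  if (is.null(user)) {
    user <- list()
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop(
      "unknown configuration key(s): ", paste(unknown, collapse = ", "),
      "; valid keys are: ", paste(names(cfg), collapse = ", "),
      call. = FALSE
    )
  }
  cfg[names(user)] <- user
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num_pos <- c(
    "threshold_k", "min_threshold", "interference_tolerance",
    "aroer_dilution_factor", "imputation_pod", "perplexity"
  )
  for (key in num_pos) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("configuration key '", key, "' must be a positive number",
        call. = FALSE
      )
    }
  }
  if (cfg$tsne_iterations < 1) {
    stop("configuration key 'tsne_iterations' must be >= 1", call. = FALSE)
  }
  if (!cfg$pattern_method %in% c("none", "median_polish")) {
    stop("configuration key 'pattern_method' must be 'none' or 'median_polish'",
      call. = FALSE
    )
  }
  invisible(cfg)
}

#' Parse plate well labels
#'
#' Splits labels like `"A03"` or `"A3"` into a letter row (A--P) and a
#' 1-based column number (1--24), the industry 384-well convention.
#'
#' @param well Character vector of well labels.
#' @return Tibble with columns `row` (letter) and `col` (integer).
#' @export
parse_well <- function(well) {
  m <- regexec("^([A-Pa-p])([0-9]{1,2})$", well)
  parts <- regmatches(well, m)
  bad <- lengths(parts) != 3
  if (any(bad)) {
    stop("malformed well label(s): ",
      paste(utils::head(well[bad], 5), collapse = ", "),
      call. = FALSE
    )
  }
  row <- toupper(vapply(parts, `[`, character(1), 2))
  col <- as.integer(vapply(parts, `[`, character(1), 3))
  if (any(col < 1 | col > 24)) {
    stop("well column out of range 1-24", call. = FALSE)
  }
  tibble::tibble(row = row, col = col)
}

#' Read a plate-format screening table
#'
#' Reads a delimited table of raw well measurements (CSV canonical,
#' tab-delimited accepted). Each row becomes one well measurement with a
#' layout role; the role is inferred from the plate layout when the file
#' has no `role` column, but an explicit role column is never overridden.
#'
#' @param path Path to a CSV or TSV file. Required columns: `plate_id`,
#'   `well` (or `row` + `col`), `run_index`, `endpoint_id`, `raw_value`.
#'   Optional: `role`, `substance_id`, `lot_id`, `concentration`,
#'   `conc_unit` ("ug/mL" default; "mg/mL" values are converted to ug/mL
#'   on read).
#' @param layout Named list declaring control columns used for role
#'   inference when the file lacks a `role` column: `empty_cols`,
#'   `dmso_cols`, `positive_cols`.
#' @return Tibble of well measurements with columns `plate_id`, `row`,
#'   `col`, `role`, `substance_id`, `lot_id`, `concentration` (ug/mL),
#'   `run_index`, `endpoint_id`, `raw_value`.
#' @export
read_plate_table <- function(path,
                             layout = list(
                               empty_cols = 1:2, dmso_cols = 3,
                               positive_cols = 4
                             )) {
  if (!file.exists(path)) {
    stop("plate table not found: ", path, call. = FALSE)
  }
  delim <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  tbl <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE
  )
  required <- c("plate_id", "run_index", "endpoint_id", "raw_value")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("plate table format error: missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(c("row", "col") %in% names(tbl))) {
    if (!"well" %in% names(tbl)) {
      stop("plate table format error: missing required column(s): well",
        call. = FALSE
      )
    }
    rc <- parse_well(tbl$well)
    tbl$row <- rc$row
    tbl$col <- rc$col
    tbl$well <- NULL
  }
  for (opt in c("substance_id", "lot_id")) {
    if (!opt %in% names(tbl)) tbl[[opt]] <- NA_character_
  }
  if (!"concentration" %in% names(tbl)) tbl$concentration <- NA_real_
  if ("conc_unit" %in% names(tbl)) {
    mg <- !is.na(tbl$conc_unit) & tbl$conc_unit == "mg/mL"
    tbl$concentration[mg] <- tbl$concentration[mg] * 1000
    tbl$conc_unit <- NULL
  }
  if (!"role" %in% names(tbl)) {
    tbl$role <- dplyr::case_when(
      !is.na(tbl$substance_id) ~ "substance",
      tbl$col %in% layout$empty_cols ~ "empty",
      tbl$col %in% layout$positive_cols ~ "positive_control",
      TRUE ~ "dmso"
    )
  }
  validate_wells(tbl)
  dplyr::select(
    tbl, "plate_id", "row", "col", "role", "substance_id", "lot_id",
    "concentration", "run_index", "endpoint_id", "raw_value"
  )
}

validate_wells <- function(tbl) {
  roles <- c("substance", "dmso", "positive_control", "empty")
  if (!all(tbl$role %in% roles)) {
    stop("plate table format error: role must be one of ",
      paste(roles, collapse = ", "),
      call. = FALSE
    )
  }
  sub <- tbl$role == "substance"
  if (any(sub & (is.na(tbl$substance_id) | is.na(tbl$concentration)))) {
    stop(paste(
      "plate table format error: substance wells must carry",
      "substance_id and concentration"
    ), call. = FALSE)
  }
  if (any(sub & tbl$concentration <= 0, na.rm = TRUE)) {
    stop("plate table format error: concentrations must be positive",
      call. = FALSE
    )
  }
  if (any(!sub & (!is.na(tbl$substance_id) | !is.na(tbl$concentration)))) {
    stop(paste(
      "plate table format error: control/empty wells must not carry",
      "substance_id or concentration"
    ), call. = FALSE)
  }
  key <- paste(tbl$plate_id, tbl$row, tbl$col, tbl$endpoint_id, tbl$run_index)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("plate table integrity error: duplicate (plate, well, endpoint, ",
      "run) entries, e.g. ", dup,
      call. = FALSE
    )
  }
  invisible(tbl)
}

#' Write a result table as delimited text
#'
#' Writes any pipeline result table (well measurements, curves, metrics,
#' calls, rankings, ...) as CSV with a stable column order and empty cells
#' for absent values -- an absent POD is an empty cell, never 0. Numeric
#' values round-trip through [read_results_long()] to full double
#' precision.
#'
#' @param records Data frame of results.
#' @param path Output path.
#' @param allow_empty Write a header-only file when `records` has no rows.
#' @return `path`, invisibly.
#' @export
write_results_long <- function(records, path, allow_empty = FALSE) {
  if (!is.data.frame(records)) {
    stop("records must be a data frame", call. = FALSE)
  }
  if (nrow(records) == 0 && !allow_empty) {
    stop("refusing to write an empty table; pass allow_empty = TRUE",
      call. = FALSE
    )
  }
  readr::write_csv(records, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results_long()]
#'
#' @param path Path to a CSV result table.
#' @return Tibble with empty cells read back as `NA`.
#' @export
read_results_long <- function(path) {
  if (!file.exists(path)) {
    stop("result table not found: ", path, call. = FALSE)
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, na = "")
}
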