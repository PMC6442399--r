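#' Percent response relative to plate controls
#'
#' Normalizes a raw well read against the plate's solvent and positive
#' controls: `((raw - v_dmso) / (v_pos - v_dmso)) * 100`, where `v_dmso`
#' and `v_pos` are the median raw values of the DMSO-only and
#' positive-control wells. Adding a constant to every raw value on a
#' plate leaves all responses unchanged.
#'
#' @param raw Raw signal value(s).
#' @param v_dmso Median DMSO-well raw value.
#' @param v_pos Median positive-control raw value.
#' @return % response; 0 at the DMSO median, 100 at the positive-control
#'   median.
#' @export
percent_response <- function(raw, v_dmso, v_pos) {
  if (v_pos == v_dmso) {
    stop("degenerate plate: positive-control and DMSO medians are equal",
      call. = FALSE
    )
  }
  (raw - v_dmso) / (v_pos - v_dmso) * 100
}

#' Rescale a curve so its baseline is 0%
#'
#' Subtracts a baseline estimate -- by default the median response of the
#' two lowest concentrations -- from every point of a curve. Idempotent: a
#' curve whose baseline estimate is already 0 is returned unchanged.
#'
#' @param response Responses ordered by ascending concentration.
#' @param n_baseline Number of lowest-concentration points defining the
#'   baseline.
#' @return Rescaled responses.
#' @export
rescale_baseline <- function(response, n_baseline = 2) {
  n <- min(n_baseline, length(response))
  response - stats::median(response[seq_len(n)])
}

#' Correct additive plate patterns
#'
#' Pluggable spatial-artifact correction applied before normalization.
#' `"none"` is the identity. `"median_polish"` removes additive row and
#' column effects estimated from the wells expected to sit at baseline
#' (DMSO wells plus each substance's lowest-concentration well) and then
#' shifts the plate back so the DMSO median is preserved.
#'
#' @param wells Well measurements of one plate x endpoint x run.
#' @param method `"none"` or `"median_polish"`.
#' @return Corrected well measurements.
#' @export
pattern_correct <- function(wells, method = c("none", "median_polish")) {
  if (length(method) == 1 && !method %in% c("none", "median_polish")) {
    stop("unknown pattern correction method: ", method, call. = FALSE)
  }
  method <- match.arg(method)
  if (method == "none") {
    return(wells)
  }
  measurable <- wells$role != "empty"
  dmso <- wells$role == "dmso"
  lowest <- rep(FALSE, nrow(wells))
  sub <- which(wells$role == "substance")
  if (length(sub) > 0) {
    mins <- tapply(wells$concentration[sub], wells$substance_id[sub], min)
    lowest[sub] <- wells$concentration[sub] ==
      unname(mins[wells$substance_id[sub]])
  }
  ref <- dmso | lowest
  grand <- stats::median(wells$raw_value[ref])
  # Column effects first (the typical artifact is a column gradient),
  # then row effects on the column-corrected residuals.
  col_eff <- tapply(wells$raw_value[ref] - grand, wells$col[ref],
    stats::median
  )
  resid <- wells$raw_value[ref] - grand -
    col_eff[as.character(wells$col[ref])]
  row_eff <- tapply(resid, wells$row[ref], stats::median)
  re <- row_eff[wells$row]
  ce <- col_eff[as.character(wells$col)]
  re[is.na(re)] <- 0
  ce[is.na(ce)] <- 0
  before <- stats::median(wells$raw_value[dmso])
  wells$raw_value[measurable] <- wells$raw_value[measurable] -
    re[measurable] - ce[measurable]
  after <- stats::median(wells$raw_value[dmso])
  wells$raw_value[measurable] <- wells$raw_value[measurable] +
    (before - after)
  wells
}

#' Normalize raw plate reads into concentration-response curves
#'
#' For every plate x endpoint x run: applies the pattern-correction hook,
#' computes the control medians, converts substance wells to % response,
#' and assembles per substance x endpoint x run curves ordered by
#' ascending concentration with the baseline rescaled to 0%.
#' Decrease-direction endpoints are sign-flipped here so that downstream
#' filtering treats "effect" as a positive response; the original sign is
#' restored when curve metrics are reported.
#'
#' @param wells Well measurements (from [read_plate_table()] or
#'   [generate_study()]).
#' @param endpoints Endpoint annotation table with `endpoint_id` and
#'   `direction`.
#' @param pattern_method Passed to [pattern_correct()].
#' @return List with `curves` (long tibble: substance_id, endpoint_id,
#'   run_index, concentration, log10_concentration, response, direction)
#'   and `dmso` (per-well DMSO % responses per endpoint x run, the input
#'   to noise-threshold derivation).
#' @export
normalize_wells <- function(wells, endpoints, pattern_method = "none") {
  stopifnot(all(c("endpoint_id", "direction") %in% names(endpoints)))
  key <- paste(wells$plate_id, wells$endpoint_id, wells$run_index,
    sep = "\r"
  )
  idx_by_plate <- split(seq_len(nrow(wells)), key)
  pieces <- lapply(idx_by_plate, function(sel) {
    plate <- pattern_correct(wells[sel, ], pattern_method)
    dmso_raw <- plate$raw_value[plate$role == "dmso"]
    pos_raw <- plate$raw_value[plate$role == "positive_control"]
    if (length(dmso_raw) < 2 || length(pos_raw) < 2) {
      stop("plate ", plate$plate_id[1],
        ": need at least 2 DMSO and 2 positive-control wells",
        call. = FALSE
      )
    }
    v_dmso <- stats::median(dmso_raw)
    v_pos <- stats::median(pos_raw)
    sub <- plate[plate$role == "substance", ]
    sub$response <- percent_response(sub$raw_value, v_dmso, v_pos)
    list(
      curves = sub[, c(
        "substance_id", "endpoint_id", "run_index",
        "concentration", "response"
      )],
      dmso = tibble::tibble(
        plate_id = plate$plate_id[1],
        endpoint_id = plate$endpoint_id[1],
        run_index = plate$run_index[1],
        response = percent_response(dmso_raw, v_dmso, v_pos)
      )
    )
  })
  curves <- dplyr::bind_rows(lapply(pieces, `[[`, "curves"))
  dmso <- dplyr::bind_rows(lapply(pieces, `[[`, "dmso"))

  dir <- endpoints$direction[match(curves$endpoint_id, endpoints$endpoint_id)]
  if (anyNA(dir)) {
    stop("endpoint(s) missing from the endpoint table: ",
      paste(unique(curves$endpoint_id[is.na(dir)]), collapse = ", "),
      call. = FALSE
    )
  }
  curves$direction <- dir
  curves$response <- curves$response * ifelse(dir == "decrease", -1, 1)

  curves <- dplyr::arrange(
    curves, .data$substance_id, .data$endpoint_id, .data$run_index,
    .data$concentration
  )
  curves <- dplyr::group_by(
    curves, .data$substance_id, .data$endpoint_id, .data$run_index
  )
  curves <- dplyr::mutate(curves, response = rescale_baseline(.data$response))
  curves <- dplyr::ungroup(curves)
  curves$log10_concentration <- log10(curves$concentration)
  curves <- curves[, c(
    "substance_id", "endpoint_id", "run_index", "concentration",
    "log10_concentration", "response", "direction"
  )]
  list(curves = curves, dmso = dmso)
}
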