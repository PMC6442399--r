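median_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else stats::median(x)
}

add_flag <- function(flags, flag) {
  existing <- strsplit(flags, ";", fixed = TRUE)[[1]]
  paste(union(existing[nzchar(existing)], flag), collapse = ";")
}

has_flag <- function(flags, flag) {
  vapply(
    strsplit(flags, ";", fixed = TRUE),
    function(f) flag %in% f, logical(1)
  )
}

#' Call one substance x endpoint from its replicate curves
#'
#' Replicate-majority rule: a substance is active in an endpoint when
#' more than half of its replicate curves are significant (two of three
#' in the standard three-run design). The potency parameters (POD, EC50,
#' Emax) are summarized as the median over the runs where they are
#' present, and are only assigned for active calls; the median wAUC is
#' always reported.
#'
#' @param metrics Per-run curve metrics for one substance x endpoint
#'   (columns as produced by [fit_curves()]).
#' @return One-row tibble with the call label, run counts, medians and an
#'   empty flag field.
#' @export
call_endpoint <- function(metrics) {
  if (nrow(metrics) < 1) {
    stop("no curves to call", call. = FALSE)
  }
  if (length(unique(metrics$substance_id)) != 1 ||
    length(unique(metrics$endpoint_id)) != 1) {
    stop("integrity error: curves from mixed substance/endpoint",
      call. = FALSE
    )
  }
  n_runs <- nrow(metrics)
  n_sig <- sum(metrics$significant)
  active <- n_sig / n_runs > 0.5
  tibble::tibble(
    substance_id = metrics$substance_id[1],
    endpoint_id = metrics$endpoint_id[1],
    label = if (active) "active" else "inactive",
    n_significant = n_sig,
    n_runs = n_runs,
    median_pod = if (active) median_or_na(metrics$pod) else NA_real_,
    median_ec50 = if (active) median_or_na(metrics$ec50) else NA_real_,
    median_emax = if (active) median_or_na(metrics$emax) else NA_real_,
    median_wauc = stats::median(metrics$wauc),
    flags = ""
  )
}

#' Call every substance x endpoint of a study
#'
#' @param metrics Curve metrics table from [fit_curves()].
#' @return Tibble of [call_endpoint()] rows, one per substance x
#'   endpoint.
#' @export
call_study <- function(metrics) {
  key <- paste(metrics$substance_id, metrics$endpoint_id, sep = "\r")
  calls <- lapply(
    split(seq_len(nrow(metrics)), key),
    function(sel) call_endpoint(metrics[sel, ])
  )
  calls <- dplyr::bind_rows(calls)
  dplyr::arrange(calls, .data$substance_id, .data$endpoint_id)
}

#' Downgrade actives confounded by counter-screen interference
#'
#' An active primary call whose paired counter screen is also active at a
#' comparable or greater potency (counter POD within `tolerance`-fold of
#' the primary POD) is relabeled inconclusive with an `interference`
#' flag; its potency medians are withdrawn. Inactive calls are never
#' relabeled, and the operation is idempotent.
#'
#' @param calls Call table from [call_study()] covering primary and
#'   counter-screen endpoints.
#' @param endpoints Endpoint table with `is_counter_screen` and
#'   `paired_primary`.
#' @param tolerance Fold cutoff (default 3).
#' @return The call table with interference applied.
#' @export
flag_interference <- function(calls, endpoints, tolerance = 3) {
  counters <- endpoints[endpoints$is_counter_screen, ]
  if (nrow(counters) == 0) {
    return(calls)
  }
  if (anyNA(counters$paired_primary)) {
    stop("counter screens must declare paired_primary", call. = FALSE)
  }
  for (i in seq_len(nrow(counters))) {
    cs <- counters$endpoint_id[i]
    primary <- counters$paired_primary[i]
    cc <- calls[calls$endpoint_id == cs & calls$label == "active", ]
    if (nrow(cc) == 0) next
    hit <- calls$endpoint_id == primary &
      calls$label == "active" &
      calls$substance_id %in% cc$substance_id
    pod_counter <- cc$median_pod[match(
      calls$substance_id[hit],
      cc$substance_id
    )]
    confounded <- which(hit)[
      !is.na(pod_counter) & !is.na(calls$median_pod[hit]) &
        pod_counter <= tolerance * calls$median_pod[hit]
    ]
    if (length(confounded) > 0) {
      calls$label[confounded] <- "inconclusive"
      calls$flags[confounded] <- vapply(
        calls$flags[confounded], add_flag, character(1),
        flag = "interference"
      )
      calls$median_pod[confounded] <- NA_real_
      calls$median_ec50[confounded] <- NA_real_
      calls$median_emax[confounded] <- NA_real_
    }
  }
  calls
}

#' Summarize real-time cytotoxicity calls across time points
#'
#' For a real-time assay family measured at several time points, the
#' total activity is the sum of the per-timepoint median wAUCs and the
#' potency is represented by the most potent (minimum) POD among the
#' active time points; the summary is active if any time point is
#' active.
#'
#' @param calls Call rows for one substance across the time points of
#'   one real-time endpoint family.
#' @param family_id Endpoint id for the summary row (default: first
#'   input endpoint id).
#' @return One-row summary call.
#' @export
integrate_cytotox <- function(calls, family_id = NULL) {
  if (nrow(calls) == 0) {
    stop("no time-point calls to integrate", call. = FALSE)
  }
  if (length(unique(calls$substance_id)) != 1) {
    stop("integrity error: time-point calls from mixed substances",
      call. = FALSE
    )
  }
  if (is.null(family_id)) family_id <- calls$endpoint_id[1]
  active_rows <- calls[calls$label == "active", ]
  any_active <- nrow(active_rows) > 0
  pod <- if (any_active) {
    min(active_rows$median_pod, na.rm = TRUE)
  } else {
    NA_real_
  }
  best <- if (any_active) {
    active_rows[which.min(active_rows$median_pod), ]
  } else {
    calls[1, ]
  }
  tibble::tibble(
    substance_id = calls$substance_id[1],
    endpoint_id = family_id,
    label = if (any_active) "active" else "inactive",
    n_significant = max(calls$n_significant),
    n_runs = calls$n_runs[1],
    median_pod = pod,
    median_ec50 = if (any_active) best$median_ec50 else NA_real_,
    median_emax = if (any_active) best$median_emax else NA_real_,
    median_wauc = sum(calls$median_wauc),
    flags = ""
  )
}

#' Flag aromatase-inhibition calls confounded by ER antagonism
#'
#' In the aromatase triscreen, apparent aromatase inhibition can be
#' driven by estrogen-receptor antagonism. When both effects are active
#' and the ER-antagonism POD lies within `dilution_factor`-fold of the
#' aromatase POD, the aromatase call gains an `aroer_confounded` flag;
#' otherwise it is returned unchanged. Idempotent; never changes
#' inactive calls.
#'
#' @param aromatase_call One-row aromatase-inhibition call.
#' @param er_antagonism_call One-row ER-antagonism call for the same
#'   substance.
#' @param dilution_factor Fold cutoff (default 3).
#' @return The (possibly flagged) aromatase call.
#' @export
flag_aroer <- function(aromatase_call, er_antagonism_call,
                       dilution_factor = 3) {
  if (aromatase_call$substance_id != er_antagonism_call$substance_id) {
    stop("integrity error: calls from different substances", call. = FALSE)
  }
  if (aromatase_call$label == "active" &&
    er_antagonism_call$label == "active" &&
    !is.na(er_antagonism_call$median_pod) &&
    !is.na(aromatase_call$median_pod) &&
    er_antagonism_call$median_pod <=
      dilution_factor * aromatase_call$median_pod) {
    aromatase_call$flags <- add_flag(
      aromatase_call$flags,
      "aroer_confounded"
    )
  }
  aromatase_call
}
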