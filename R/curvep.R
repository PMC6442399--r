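#' Derive the per-endpoint noise threshold
#'
#' The noise level combines the spread of the solvent controls with the
#' baseline spread of the substance data themselves:
#' `value = max(k * SD(dmso responses), data_floor, min_value)`, where
#' `data_floor` is the 95th percentile of |response| at the two lowest
#' tested concentrations pooled across all substance curves. `min_value`
#' guards the degenerate case of noise-free plates (constant controls and
#' exactly-zero baselines), where both terms vanish.
#'
#' @param dmso_responses DMSO-well % responses for the endpoint (>= 8
#'   values).
#' @param baseline_responses % responses at the two lowest concentrations
#'   pooled across the endpoint's substance curves.
#' @param k SD multiplier (default 3).
#' @param min_value Lower bound on the threshold, % response units.
#' @return List with `value`, `sd_dmso`, `k` and `data_floor`.
#' @export
derive_threshold <- function(dmso_responses, baseline_responses, k = 3,
                             min_value = 1) {
  if (length(dmso_responses) < 8) {
    stop("insufficient controls: need >= 8 DMSO response values",
      call. = FALSE
    )
  }
  if (k <= 0 || min_value <= 0) {
    stop("threshold multiplier and lower bound must be positive",
      call. = FALSE
    )
  }
  sd_dmso <- stats::sd(dmso_responses)
  data_floor <- if (length(baseline_responses) > 0) {
    unname(stats::quantile(abs(baseline_responses), 0.95, names = FALSE))
  } else {
    0
  }
  list(
    value = max(k * sd_dmso, data_floor, min_value),
    sd_dmso = sd_dmso, k = k, data_floor = data_floor
  )
}

threshold_value <- function(threshold) {
  if (is.list(threshold)) threshold$value else threshold
}

#' Noise-filter a concentration-response curve
#'
#' Three-stage filter applied to the baseline-rescaled responses of one
#' curve (effect direction already positive):
#' 1. *Spike removal*: any interior point that differs from both
#'    neighbours by more than the threshold, with opposite-signed jumps,
#'    is replaced by the mean of its neighbours, iterated to a fixpoint.
#' 2. *Sub-threshold zeroing*: responses with |r| < threshold are set to
#'    0.
#' 3. *Weak monotone envelope*: after the running maximum, a drop smaller
#'    than the threshold is clipped back to the running maximum; a larger
#'    drop zeroes the remainder of the curve (loss of response beyond one
#'    threshold is treated as noise beyond recovery).
#'
#' @param response Responses ordered by ascending concentration.
#' @param threshold Noise threshold (a [derive_threshold()] result or a
#'   positive number).
#' @return List with `filtered` (the final responses) and `despiked` (the
#'   responses after stage 1 only, used for between-grid POD
#'   interpolation).
#' @export
filter_curve <- function(response, threshold) {
  tv <- threshold_value(threshold)
  stopifnot(tv > 0, length(response) >= 1)
  r <- response
  n <- length(r)
  if (n >= 3) {
    for (pass in seq_len(100)) {
      changed <- FALSE
      for (i in 2:(n - 1)) {
        d_in <- r[i] - r[i - 1]
        d_out <- r[i + 1] - r[i]
        if (abs(d_in) > tv && abs(d_out) > tv && d_in * d_out < 0) {
          r[i] <- (r[i - 1] + r[i + 1]) / 2
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  despiked <- r
  f <- r
  f[abs(f) < tv] <- 0
  if (n >= 2) {
    runmax <- f[1]
    for (i in 2:n) {
      if (f[i] >= runmax) {
        runmax <- f[i]
      } else if (runmax - f[i] < tv) {
        f[i] <- runmax
      } else {
        f[i:n] <- 0
        break
      }
    }
  }
  list(filtered = f, despiked = despiked)
}

#' Weighted area-under-curve of a filtered curve
#'
#' Trapezoidal integral of the filtered response over log10
#' concentration, normalized by `100 * (log10 c_max - log10 c_min)` so
#' that a full-range 100% effect scores 1 and an all-zero filtered curve
#' scores exactly 0. The sign of the endpoint's direction of effect is
#' restored via `direction_sign`.
#'
#' @param log10_conc Ascending log10 concentrations (>= 2 points).
#' @param filtered Filtered responses from [filter_curve()].
#' @param direction_sign +1 for increase endpoints, -1 for decrease.
#' @return Signed dimensionless wAUC in `[-1, 1]` for responses within
#'   `[-100, 100]`.
#' @export
compute_wauc <- function(log10_conc, filtered, direction_sign = 1) {
  n <- length(log10_conc)
  if (n < 2) {
    stop("wAUC needs at least 2 concentration points", call. = FALSE)
  }
  stopifnot(length(filtered) == n, !is.unsorted(log10_conc, strictly = TRUE))
  if (all(filtered == 0)) {
    return(0)
  }
  dx <- diff(log10_conc)
  area <- sum(dx * (filtered[-n] + filtered[-1]) / 2)
  direction_sign * area / (100 * (log10_conc[n] - log10_conc[1]))
}

#' Point-of-departure of a filtered curve
#'
#' The concentration at which the response is equivalent to the noise
#' threshold. Absent when no filtered |response| reaches the threshold;
#' otherwise located by linear interpolation in log10 concentration on
#' the pre-zeroing (despiked) magnitudes, between the last sub-threshold
#' point and the first crossing point, so a curve crossing between grid
#' points gets a between-grid POD. A first point already above threshold
#' returns the lowest tested concentration; flat segments at exactly the
#' threshold resolve to the lowest qualifying concentration.
#'
#' @param log10_conc Ascending log10 concentrations.
#' @param despiked,filtered Components of a [filter_curve()] result.
#' @param threshold Noise threshold.
#' @return POD in ug/mL, or `NA` when the curve never reaches the
#'   threshold.
#' @export
compute_pod <- function(log10_conc, despiked, filtered, threshold) {
  tv <- threshold_value(threshold)
  if (!any(abs(filtered) >= tv)) {
    return(NA_real_)
  }
  m <- abs(despiked)
  idx <- which(m >= tv)[1]
  if (is.na(idx)) {
    # Clipping can restore a despiked value that zeroing removed; fall
    # back to the filtered magnitudes in that corner case.
    m <- abs(filtered)
    idx <- which(m >= tv)[1]
  }
  if (idx == 1) {
    return(10^log10_conc[1])
  }
  x0 <- log10_conc[idx - 1]
  x1 <- log10_conc[idx]
  y0 <- m[idx - 1]
  y1 <- m[idx]
  xp <- x0 + (tv - y0) / (y1 - y0) * (x1 - x0)
  10^xp
}

#' EC50 and Emax of a filtered curve
#'
#' `emax` is the response of maximal magnitude; `ec50` is the
#' concentration at which the response first reaches half of `emax`,
#' located by linear interpolation in log10 concentration. Both are
#' absent for an all-zero filtered curve.
#'
#' @param log10_conc Ascending log10 concentrations.
#' @param filtered Filtered responses from [filter_curve()].
#' @param direction_sign +1 or -1; restores the reported sign of `emax`.
#' @return List with `ec50` (ug/mL or `NA`) and `emax` (% response or
#'   `NA`).
#' @export
compute_ec50_emax <- function(log10_conc, filtered, direction_sign = 1) {
  if (all(filtered == 0)) {
    return(list(ec50 = NA_real_, emax = NA_real_))
  }
  imax <- which.max(abs(filtered))
  emax <- filtered[imax]
  half <- emax / 2
  reaches <- if (emax > 0) filtered >= half else filtered <= half
  idx <- which(reaches)[1]
  ec50 <- if (idx == 1) {
    10^log10_conc[1]
  } else {
    x0 <- log10_conc[idx - 1]
    x1 <- log10_conc[idx]
    y0 <- filtered[idx - 1]
    y1 <- filtered[idx]
    10^(x0 + (half - y0) / (y1 - y0) * (x1 - x0))
  }
  list(ec50 = ec50, emax = direction_sign * emax)
}

#' Filter one curve and extract its four activity parameters
#'
#' Chains [filter_curve()], [compute_wauc()], [compute_pod()] and
#' [compute_ec50_emax()]. A curve is significant exactly when its
#' |wAUC| > 0, which by construction coincides with a POD being present.
#'
#' @param log10_conc Ascending log10 concentrations.
#' @param response Baseline-rescaled responses (effect direction
#'   positive).
#' @param threshold Noise threshold.
#' @param direction `"increase"` or `"decrease"`; restores the reported
#'   sign of wAUC and Emax.
#' @return One-row tibble with `wauc`, `pod`, `ec50`, `emax`,
#'   `significant`.
#' @export
process_curve <- function(log10_conc, response, threshold,
                          direction = "increase") {
  sign <- if (identical(direction, "decrease")) -1 else 1
  flt <- filter_curve(response, threshold)
  wauc <- compute_wauc(log10_conc, flt$filtered, sign)
  pod <- compute_pod(log10_conc, flt$despiked, flt$filtered, threshold)
  ce <- compute_ec50_emax(log10_conc, flt$filtered, sign)
  tibble::tibble(
    wauc = wauc, pod = pod, ec50 = ce$ec50, emax = ce$emax,
    significant = abs(wauc) > 0
  )
}

#' Noise-filter all curves of a normalized study
#'
#' Derives one noise threshold per endpoint from the pooled DMSO
#' responses and the substances' baseline responses, then runs
#' [process_curve()] on every substance x endpoint x run curve. Curves
#' with fewer than 4 points are kept but marked non-significant (wAUC 0,
#' no potency parameters) rather than dropped, which is conservative
#' toward inactivity.
#'
#' @param normalized Result of [normalize_wells()].
#' @param k Threshold SD multiplier.
#' @param min_threshold Threshold lower bound, % response units.
#' @return List with `metrics` (per-curve [process_curve()] rows keyed by
#'   substance, endpoint and run) and `thresholds` (per-endpoint noise
#'   thresholds).
#' @export
fit_curves <- function(normalized, k = 3, min_threshold = 1) {
  curves <- normalized$curves
  dmso <- normalized$dmso

  thresholds <- lapply(unique(curves$endpoint_id), function(ep) {
    cv <- curves[curves$endpoint_id == ep, ]
    two_lowest <- dplyr::group_by(
      cv, .data$substance_id, .data$run_index
    )
    two_lowest <- dplyr::slice_min(two_lowest, .data$concentration,
      n = 2, with_ties = FALSE
    )
    thr <- derive_threshold(
      dmso$response[dmso$endpoint_id == ep],
      two_lowest$response,
      k = k, min_value = min_threshold
    )
    tibble::tibble(
      endpoint_id = ep, threshold = thr$value, sd_dmso = thr$sd_dmso,
      k = k, data_floor = thr$data_floor
    )
  })
  thresholds <- dplyr::bind_rows(thresholds)

  thr_of <- stats::setNames(thresholds$threshold, thresholds$endpoint_id)
  key <- paste(curves$substance_id, curves$endpoint_id, curves$run_index,
    sep = "\r"
  )
  idx_by_curve <- split(seq_len(nrow(curves)), key)
  rows <- lapply(idx_by_curve, function(sel) {
    cv <- curves[sel, ]
    head <- cv[1, c("substance_id", "endpoint_id", "run_index")]
    if (nrow(cv) < 4) {
      return(dplyr::bind_cols(head, tibble::tibble(
        wauc = 0, pod = NA_real_, ec50 = NA_real_, emax = NA_real_,
        significant = FALSE
      )))
    }
    dplyr::bind_cols(head, process_curve(
      cv$log10_concentration, cv$response,
      unname(thr_of[head$endpoint_id]),
      direction = cv$direction[1]
    ))
  })
  metrics <- dplyr::bind_rows(rows)
  metrics <- dplyr::arrange(
    metrics, .data$substance_id, .data$endpoint_id, .data$run_index
  )
  list(metrics = metrics, thresholds = thresholds)
}
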