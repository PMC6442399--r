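#' Describe a simulated qHTS study
#'
#' Bundles and validates the parameters of a synthetic screening study:
#' how many botanical groups, lots and purported active constituents are
#' screened, across how many endpoints, with what titration design and
#' noise model. The defaults emulate the screening design the pipeline
#' targets: 384-well plates with the first two columns empty, a 15-point
#' third-log dilution series, three replicate runs, and ~20 endpoints with
#' direction labels.
#'
#' @param n_groups Number of botanical groups.
#' @param lots_per_group Procured lots (test samples) per group.
#' @param constituents_per_group Purported active single-chemical
#'   constituents per group. Constituents carry amplified truths relative
#'   to their parent extracts: larger maximal response and lower EC50.
#' @param n_endpoints Number of primary assay endpoints.
#' @param n_counter_screens Counter-screen readouts, each paired with a
#'   primary endpoint.
#' @param dilution_points Concentrations per titration series (>= 4).
#' @param dilution_step Fold dilution between adjacent concentrations.
#' @param top_concentration Highest tested concentration, ug/mL.
#' @param runs Replicate runs per substance x endpoint.
#' @param noise_sd Additive Gaussian noise SD on the % response scale.
#' @param dmso_signal_mean,dmso_signal_sd DMSO-well raw signal mean/SD.
#'   The SD defaults to `noise_sd` converted to signal units so the
#'   derived noise threshold is coherent with the configured noise.
#' @param positive_signal_mean,positive_signal_sd Positive-control raw
#'   signal mean/SD (SD defaults as for DMSO).
#' @param plate_pattern_amplitude Amplitude, in signal units, of a smooth
#'   column gradient added to every non-empty well; 0 disables it.
#' @param lot_variability Relative jitter of lot truths around the group
#'   truth (SD of a multiplicative factor on top, additive on log10 EC50).
#' @param constituent_top_factor,constituent_ec50_factor Multipliers
#'   mapping a parent-extract truth to its constituent truth.
#' @param active_rate Probability that a group x endpoint pair is truly
#'   active; counter screens use a third of this rate.
#' @param top_range Range of |Emax_true| (% response) for active truths.
#' @param hill_range Range of the Hill coefficient for active truths.
#' @param seed Random seed; identical seeds reproduce the study
#'   bit-for-bit.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_groups = 19,
                              lots_per_group = 4,
                              constituents_per_group = 1,
                              n_endpoints = 20,
                              n_counter_screens = 2,
                              dilution_points = 15,
                              dilution_step = 10^(1 / 3),
                              top_concentration = 100,
                              runs = 3,
                              noise_sd = 5,
                              dmso_signal_mean = 1000,
                              dmso_signal_sd = NULL,
                              positive_signal_mean = 5000,
                              positive_signal_sd = NULL,
                              plate_pattern_amplitude = 80,
                              lot_variability = 0.1,
                              constituent_top_factor = 1.3,
                              constituent_ec50_factor = 0.3,
                              active_rate = 0.3,
                              top_range = c(40, 100),
                              hill_range = c(1, 3),
                              seed = 1) {
  span <- positive_signal_mean - dmso_signal_mean
  if (span == 0) {
    stop("positive_signal_mean must differ from dmso_signal_mean",
      call. = FALSE
    )
  }
  if (is.null(dmso_signal_sd)) dmso_signal_sd <- noise_sd / 100 * abs(span)
  if (is.null(positive_signal_sd)) {
    positive_signal_sd <- noise_sd / 100 * abs(span)
  }
  design <- list(
    n_groups = n_groups, lots_per_group = lots_per_group,
    constituents_per_group = constituents_per_group,
    n_endpoints = n_endpoints, n_counter_screens = n_counter_screens,
    dilution_points = dilution_points, dilution_step = dilution_step,
    top_concentration = top_concentration, runs = runs,
    noise_sd = noise_sd,
    dmso_signal_mean = dmso_signal_mean, dmso_signal_sd = dmso_signal_sd,
    positive_signal_mean = positive_signal_mean,
    positive_signal_sd = positive_signal_sd,
    plate_pattern_amplitude = plate_pattern_amplitude,
    lot_variability = lot_variability,
    constituent_top_factor = constituent_top_factor,
    constituent_ec50_factor = constituent_ec50_factor,
    active_rate = active_rate, top_range = top_range,
    hill_range = hill_range, seed = seed
  )
  stopifnot(
    design$dilution_points >= 4, design$dilution_points <= 15,
    design$runs >= 1,
    design$noise_sd >= 0, design$dmso_signal_sd >= 0,
    design$positive_signal_sd >= 0, design$dilution_step > 1,
    design$top_concentration > 0, design$n_groups >= 1,
    design$n_endpoints >= 1, design$lot_variability >= 0,
    design$n_counter_screens <= design$n_endpoints
  )
  class(design) <- "simulation_design"
  design
}

#' Tested concentration series of a design
#'
#' @param design A [simulation_design()].
#' @return Ascending concentrations in ug/mL, ending at
#'   `top_concentration`.
#' @export
design_concentrations <- function(design) {
  design$top_concentration /
    design$dilution_step^((design$dilution_points - 1):0)
}

#' Hill concentration-response model
#'
#' The sigmoidal ground truth used by the simulator:
#' `top * c^h / (ec50^h + c^h)`. At `c = ec50` the response is half of
#' `top`; an inactive truth (`top = 0`) responds 0 at every concentration.
#'
#' @param concentration Concentrations in ug/mL, all > 0.
#' @param top Maximal response in % (signed; negative for
#'   decrease-direction endpoints).
#' @param ec50 Half-maximal concentration, ug/mL.
#' @param hill Hill coefficient, > 0.
#' @return % response at each concentration.
#' @export
hill_response <- function(concentration, top, ec50, hill = 1) {
  if (any(concentration <= 0)) {
    stop("concentration must be positive", call. = FALSE)
  }
  if (length(top) == 1 && top == 0) {
    return(rep(0, length(concentration)))
  }
  top * concentration^hill / (ec50^hill + concentration^hill)
}

# Smooth column gradient in signal units; zero amplitude disables it.
plate_pattern <- function(col, amplitude) {
  amplitude * sin(pi * (col - 1) / 23)
}

#' Simulate a complete screening study
#'
#' Generates raw 384-well plate reads with known ground truth. Each plate
#' serves one endpoint x run: columns 1--2 are empty, column 3 holds 16
#' DMSO wells, column 4 holds 16 positive-control wells, and columns
#' 5--24 each hold one substance's dilution series down rows A--O
#' (ascending concentration), with row P unused. Substance wells read
#'
#' `raw = dmso_mean + (pos_mean - dmso_mean) * (hill + noise) / 100 + pattern`
#'
#' so that control-based normalization recovers `hill + noise` exactly.
#' Lots within a group share the group truth jittered by
#' `lot_variability`; constituents carry amplified truths (larger |top|,
#' lower EC50) than their parent extracts.
#'
#' @param design A [simulation_design()].
#' @return List with elements `wells` (raw well measurements), `truths`
#'   (per substance x endpoint Hill ground truth), `substances`
#'   (substance annotations: group, formulation, excluded flag) and
#'   `endpoints` (endpoint annotations: effect category, direction,
#'   counter-screen pairing).
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  concs <- design_concentrations(design)
  lcon <- log10(concs)

  endpoints <- simulate_endpoints(design)
  substances <- simulate_substances(design)
  truths <- simulate_truths(design, substances, endpoints, lcon)

  wells <- simulate_wells(design, truths, substances, endpoints)
  list(
    wells = wells, truths = truths, substances = substances,
    endpoints = endpoints
  )
}

#' Simulate raw plate reads from given ground-truth tables
#'
#' The plate-read half of [generate_study()], exposed separately so that
#' studies can be re-simulated after editing the truth table (e.g. to
#' plant a designated activity pattern). Draws fresh measurement noise
#' from the current RNG state; seed beforehand for reproducibility.
#'
#' @param design A [simulation_design()].
#' @param truths,substances,endpoints Tables as produced by
#'   [generate_study()] (possibly modified).
#' @return Tibble of raw well measurements.
#' @export
simulate_wells <- function(design, truths, substances, endpoints) {
  concs <- design_concentrations(design)
  sub_ids <- substances$substance_id
  n_sub <- length(sub_ids)
  per_plate <- 20L
  n_plates <- ceiling(n_sub / per_plate)
  plate_of <- rep(seq_len(n_plates), each = per_plate)[seq_len(n_sub)]
  col_of <- rep(5:24, times = n_plates)[seq_len(n_sub)]
  span <- design$positive_signal_mean - design$dmso_signal_mean

  grid <- tidyr::expand_grid(
    endpoint_id = endpoints$endpoint_id,
    run_index = seq_len(design$runs),
    plate = seq_len(n_plates)
  )
  plates <- lapply(seq_len(nrow(grid)), function(i) {
    ep <- grid$endpoint_id[i]
    run <- grid$run_index[i]
    pl <- grid$plate[i]
    plate_id <- sprintf("P%02d_%s_R%d", pl, ep, run)
    on_plate <- which(plate_of == pl)

    empty <- tidyr::expand_grid(row = LETTERS[1:16], col = 1:2)
    empty$role <- "empty"
    empty$raw_value <- NA_real_

    dmso <- tibble::tibble(
      row = LETTERS[1:16], col = 3L, role = "dmso",
      raw_value = design$dmso_signal_mean +
        stats::rnorm(16, 0, design$dmso_signal_sd) +
        plate_pattern(3, design$plate_pattern_amplitude)
    )
    pos <- tibble::tibble(
      row = LETTERS[1:16], col = 4L, role = "positive_control",
      raw_value = design$positive_signal_mean +
        stats::rnorm(16, 0, design$positive_signal_sd) +
        plate_pattern(4, design$plate_pattern_amplitude)
    )
    ctl <- dplyr::bind_rows(empty, dmso, pos)
    ctl$substance_id <- NA_character_
    ctl$lot_id <- NA_character_
    ctl$concentration <- NA_real_

    np <- design$dilution_points
    sub <- tibble::tibble(
      substance_id = rep(sub_ids[on_plate], each = np),
      col = rep(col_of[on_plate], each = np),
      row = rep(LETTERS[seq_len(np)], times = length(on_plate)),
      concentration = rep(concs, times = length(on_plate))
    )
    tr <- truths[truths$endpoint_id == ep, ]
    idx <- match(sub$substance_id, tr$substance_id)
    resp <- ifelse(
      tr$active_true[idx],
      hill_response(
        sub$concentration,
        ifelse(tr$active_true[idx], tr$top[idx], 0),
        ifelse(tr$active_true[idx], tr$ec50_true[idx], 1),
        ifelse(tr$active_true[idx], tr$hill_coefficient[idx], 1)
      ),
      0
    )
    noise <- stats::rnorm(nrow(sub), 0, design$noise_sd)
    sub$raw_value <- design$dmso_signal_mean +
      span * (resp + noise) / 100 +
      plate_pattern(sub$col, design$plate_pattern_amplitude)
    sub$role <- "substance"
    sub$lot_id <- sub$substance_id
    unused <- dplyr::bind_rows(
      tidyr::expand_grid(row = LETTERS[(np + 1):16], col = col_of[on_plate]),
      tidyr::expand_grid(row = LETTERS[1:16], col = setdiff(
        5:24,
        col_of[on_plate]
      ))
    )
    if (nrow(unused) > 0) {
      unused$role <- "empty"
      unused$raw_value <- NA_real_
      unused$substance_id <- NA_character_
      unused$lot_id <- NA_character_
      unused$concentration <- NA_real_
    }
    out <- dplyr::bind_rows(ctl, sub, unused)
    out$plate_id <- plate_id
    out$run_index <- run
    out$endpoint_id <- ep
    out
  })
  wells <- dplyr::bind_rows(plates)
  dplyr::select(
    wells, "plate_id", "row", "col", "role", "substance_id", "lot_id",
    "concentration", "run_index", "endpoint_id", "raw_value"
  )
}

simulate_endpoints <- function(design) {
  n <- design$n_endpoints
  cats <- c(
    "stress response", "nuclear receptor", "genotoxicity",
    "cell viability", "other"
  )
  primary <- tibble::tibble(
    endpoint_id = sprintf("E%02d", seq_len(n)),
    effect_category = rep_len(cats, n),
    direction = rep_len(c("increase", "decrease"), n),
    is_counter_screen = FALSE,
    paired_primary = NA_character_
  )
  if (design$n_counter_screens > 0) {
    k <- design$n_counter_screens
    counter <- tibble::tibble(
      endpoint_id = sprintf("C%02d", seq_len(k)),
      effect_category = "cell viability",
      direction = "increase",
      is_counter_screen = TRUE,
      paired_primary = primary$endpoint_id[seq_len(k)]
    )
    return(dplyr::bind_rows(primary, counter))
  }
  primary
}

simulate_substances <- function(design) {
  groups <- sprintf("G%02d", seq_len(design$n_groups))
  lots <- tidyr::expand_grid(
    group = groups,
    lot = seq_len(design$lots_per_group)
  )
  lots <- tibble::tibble(
    substance_id = sprintf("%s_L%d", lots$group, lots$lot),
    group = lots$group, formulation = "extract", excluded = FALSE
  )
  if (design$constituents_per_group > 0) {
    cons <- tidyr::expand_grid(
      group = groups,
      k = seq_len(design$constituents_per_group)
    )
    cons <- tibble::tibble(
      substance_id = sprintf("%s_C%d", cons$group, cons$k),
      group = cons$group, formulation = "constituent", excluded = FALSE
    )
    return(dplyr::bind_rows(lots, cons))
  }
  lots
}

simulate_truths <- function(design, substances, endpoints, lcon) {
  lmin <- min(lcon)
  lmax <- max(lcon)
  # Group-level EC50s sit in the central part of the tested range so the
  # analytic POD stays on-grid even after lot jitter.
  base <- tidyr::expand_grid(
    group = unique(substances$group),
    endpoint_id = endpoints$endpoint_id
  )
  rate <- ifelse(
    endpoints$is_counter_screen[match(
      base$endpoint_id,
      endpoints$endpoint_id
    )],
    design$active_rate / 3, design$active_rate
  )
  dirsign <- ifelse(
    endpoints$direction[match(base$endpoint_id, endpoints$endpoint_id)] ==
      "decrease", -1, 1
  )
  nb <- nrow(base)
  base$active <- stats::runif(nb) < rate
  base$top <- ifelse(
    base$active,
    dirsign * stats::runif(nb, design$top_range[1], design$top_range[2]),
    0
  )
  base$lec50 <- ifelse(
    base$active,
    stats::runif(nb, lmin + 1.5, lmax - 0.5),
    NA_real_
  )
  base$hill <- ifelse(
    base$active,
    stats::runif(nb, design$hill_range[1], design$hill_range[2]),
    NA_real_
  )

  tr <- tidyr::expand_grid(
    substance_id = substances$substance_id,
    endpoint_id = endpoints$endpoint_id
  )
  tr$group <- substances$group[match(tr$substance_id, substances$substance_id)]
  tr$formulation <- substances$formulation[
    match(tr$substance_id, substances$substance_id)
  ]
  bi <- match(paste(tr$group, tr$endpoint_id), paste(base$group, base$endpoint_id))
  tr$active_true <- base$active[bi]
  nt <- nrow(tr)
  top_jit <- 1 + stats::rnorm(nt, 0, design$lot_variability)
  lec_jit <- stats::rnorm(nt, 0, design$lot_variability)
  tr$top <- base$top[bi] * top_jit
  tr$lec50 <- base$lec50[bi] + lec_jit
  is_con <- tr$formulation == "constituent"
  tr$top[is_con] <- base$top[bi][is_con] * design$constituent_top_factor
  tr$lec50[is_con] <- base$lec50[bi][is_con] +
    log10(design$constituent_ec50_factor)
  tr$top <- pmax(pmin(tr$top, 150), -150)
  tr$lec50 <- pmax(pmin(tr$lec50, lmax), lmin)
  tr$top[!tr$active_true] <- 0
  tr$lec50[!tr$active_true] <- NA_real_
  tr$hill_coefficient <- base$hill[bi]
  tr$hill_coefficient[!tr$active_true] <- NA_real_
  tibble::tibble(
    substance_id = tr$substance_id,
    endpoint_id = tr$endpoint_id,
    top = tr$top,
    ec50_true = 10^tr$lec50,
    hill_coefficient = tr$hill_coefficient,
    active_true = tr$active_true
  )
}

#' Expected activity calls and analytic PODs from ground truth
#'
#' The oracle counterpart of the pipeline's calls: a truth is expected
#' active when it is truly active and its maximal response exceeds the
#' noise threshold; its analytic POD is the concentration at which the
#' noiseless Hill response equals the threshold,
#' `ec50 * (T / (|top| - T))^(1/h)`.
#'
#' @param truths Truth table from [generate_study()].
#' @param design The generating [simulation_design()].
#' @param threshold Noise threshold in % response units (may be a named
#'   vector keyed by endpoint_id).
#' @return Tibble with `expected_label` and `pod_true` (ug/mL, `NA` when
#'   the truth never crosses the threshold).
#' @export
truth_calls <- function(truths, design, threshold) {
  thr <- if (!is.null(names(threshold))) {
    unname(threshold[truths$endpoint_id])
  } else {
    rep_len(threshold, nrow(truths))
  }
  mag <- abs(truths$top)
  crosses <- truths$active_true & mag > thr
  pod <- ifelse(
    crosses,
    truths$ec50_true * (thr / (mag - thr))^(1 / truths$hill_coefficient),
    NA_real_
  )
  concs <- design_concentrations(design)
  pod <- pmin(pmax(pod, min(concs)), max(concs))
  tibble::tibble(
    substance_id = truths$substance_id,
    endpoint_id = truths$endpoint_id,
    expected_label = ifelse(crosses, "active", "inactive"),
    pod_true = pod
  )
}
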