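# Small simulated studies shared across test files.

tiny_design <- function(..., seed = 42) {
  simulation_design(
    n_groups = 3, lots_per_group = 3, constituents_per_group = 1,
    n_endpoints = 4, n_counter_screens = 1, seed = seed, ...
  )
}

noiseless_design <- function(..., plate_pattern_amplitude = 0, seed = 42) {
  tiny_design(
    noise_sd = 0, dmso_signal_sd = 0, positive_signal_sd = 0,
    plate_pattern_amplitude = plate_pattern_amplitude, seed = seed, ...
  )
}

# A bare curve tibble in the shape normalize_wells() emits.
make_curve <- function(log10_conc, response, substance = "S1",
                       endpoint = "E01", run = 1,
                       direction = "increase") {
  tibble::tibble(
    substance_id = substance, endpoint_id = endpoint, run_index = run,
    concentration = 10^log10_conc, log10_concentration = log10_conc,
    response = response, direction = direction
  )
}

# One-row curve-metrics record, defaulting to a significant curve.
make_metric <- function(substance = "S1", endpoint = "E01", run = 1,
                        wauc = 0.2, pod = 10, ec50 = 20, emax = 50,
                        significant = TRUE) {
  tibble::tibble(
    substance_id = substance, endpoint_id = endpoint, run_index = run,
    wauc = wauc, pod = pod, ec50 = ec50, emax = emax,
    significant = significant
  )
}

# One-row endpoint call.
make_call <- function(substance = "S1", endpoint = "E01",
                      label = "active", pod = 10, wauc = 0.2,
                      n_significant = 3, n_runs = 3) {
  tibble::tibble(
    substance_id = substance, endpoint_id = endpoint, label = label,
    n_significant = n_significant, n_runs = n_runs,
    median_pod = if (label == "active") pod else NA_real_,
    median_ec50 = NA_real_, median_emax = NA_real_,
    median_wauc = wauc, flags = ""
  )
}
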