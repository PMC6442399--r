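#' Run the full qHTS analysis pipeline
#'
#' Convenience wrapper chaining every stage on a set of raw well
#' measurements: pattern correction and normalization, noise filtering
#' and curve metrics, replicate-majority activity calls with
#' counter-screen interference, profile matrices, hierarchical
#' clustering orders, pairwise correlation, group correlation curves,
#' endpoint enrichment, the three substance rankings, and the t-SNE
#' embedding.
#'
#' @param wells Raw well measurements ([read_plate_table()] or
#'   [generate_study()]`$wells`).
#' @param substances Substance annotation table.
#' @param endpoints Endpoint annotation table.
#' @param config Configuration list ([default_config()] /
#'   [load_config()]).
#' @return List with `normalized`, `metrics`, `thresholds`, `calls`,
#'   `matrices`, `cluster`, `correlation`, `group_curves`, `enrichment`,
#'   `rankings`, `embedding`.
#' @export
run_pipeline <- function(wells, substances, endpoints,
                         config = default_config()) {
  validate_config(config)
  normalized <- normalize_wells(wells, endpoints,
    pattern_method = config$pattern_method
  )
  fit <- fit_curves(normalized,
    k = config$threshold_k,
    min_threshold = config$min_threshold
  )
  calls <- call_study(fit$metrics)
  calls <- flag_interference(calls, endpoints,
    tolerance = config$interference_tolerance
  )
  matrices <- build_matrices(calls, substances, endpoints,
    imputation_pod = config$imputation_pod
  )
  cluster <- cluster_orders(matrices$log10_pod)
  correlation <- pairwise_correlation(matrices)
  fine <- NULL
  if ("formulation" %in% names(substances) &&
    length(unique(substances$formulation)) > 1) {
    fine <- stats::setNames(
      paste(substances$group, substances$formulation, sep = "/"),
      substances$substance_id
    )
  }
  enrichment <- endpoint_enrichment(matrices, matrices$groups, fine)
  rankings <- rank_substances(matrices, calls,
    z_active_only = config$z_active_only
  )
  group_curves <- group_correlation_curves(
    correlation, matrices$groups, rankings,
    min_group_size = config$min_group_size
  )
  embedding <- embed_2d(matrices,
    perplexity = config$perplexity,
    iterations = config$tsne_iterations,
    seed = config$seed
  )
  list(
    normalized = normalized, metrics = fit$metrics,
    thresholds = fit$thresholds, calls = calls, matrices = matrices,
    cluster = cluster, correlation = correlation,
    group_curves = group_curves, enrichment = enrichment,
    rankings = rankings, embedding = embedding
  )
}
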