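# botanitox

Quantitative high-throughput screening (qHTS) analysis for botanical and
dietary-supplement substances.

Botanical supplements are complex mixtures procured as distinct lots, and
their purported active constituents are single chemicals; both can be
screened across full concentration series in 384-well cell-based assays.
`botanitox` turns the raw plate reads of such a screen into activity
calls and bioactivity profiles:

1. **Normalization** — each well is expressed as percent response
   relative to the plate controls,
   `%Response = (V_substance − V_DMSO) / (V_pos − V_DMSO) × 100`,
   where `V_DMSO` and `V_pos` are the median raw values of the
   DMSO-only and positive-control wells; curve baselines are rescaled to
   0% and an optional additive pattern correction (`median_polish`) can
   remove smooth row/column artifacts.
2. **Noise filtering and curve metrics** — a per-endpoint noise
   threshold `T = max(k·SD_DMSO, data floor)` (default `k = 3`) drives a
   three-stage curve filter (spike removal, sub-threshold zeroing, weak
   monotone envelope). Each filtered curve is summarized by four
   activity parameters: the weighted area-under-curve
   `wAUC = ∫ r d(log10 c) / (100 · Δlog10 c)` (total activity, 0 exactly
   for curves with no above-threshold response), the point-of-departure
   POD (concentration where the response equals `T`), EC50 and Emax.
3. **Activity calls** — a substance × endpoint is *active* when more
   than half of its replicate curves are significant (two of three in
   the standard design); potency parameters are medians across runs and
   are only assigned to actives. Actives confounded by a paired counter
   screen become *inconclusive*; real-time cytotoxicity time points are
   integrated (summed wAUC, most potent POD), and aromatase-inhibition
   calls confounded by ER antagonism are flagged.
4. **Profiling** — substances × endpoints matrices of log10 POD
   (inactive/inconclusive cells imputed at 1000 µg/mL) and wAUC feed
   hierarchical clustering (Euclidean distance, average linkage),
   pairwise Spearman correlation with qHTS assignment rules (negative →
   0; undefined with both substances all-zero → 1, otherwise → 0),
   one-way ANOVA F enrichment of endpoints over botanical groups (and
   the F-ratio of fine vs coarse groupings), three substance-ranking
   scenarios (number of actives, most potent POD, sum of Z-scaled
   wAUC), and a seeded t-SNE embedding of activity profiles.

A plate-level simulator (`simulation_design()`, `generate_study()`)
produces raw reads with known Hill-model ground truth — 384-well plates
with the first two columns empty, DMSO and positive-control columns,
15-point third-log titrations, three runs, lot-to-lot jitter within
botanical groups and amplified constituent truths — so the entire
pipeline is testable without external screening data.

## Worked example

```r
library(botanitox)

design <- simulation_design(n_groups = 4, lots_per_group = 3,
                            constituents_per_group = 1,
                            n_endpoints = 6, n_counter_screens = 1,
                            seed = 2024)
study <- generate_study(design)

norm  <- normalize_wells(study$wells, study$endpoints)
fit   <- fit_curves(norm, k = 3)
calls <- flag_interference(call_study(fit$metrics), study$endpoints)
table(calls$label)
#>   active inactive
#>       29       83

mat <- build_matrices(calls, study$substances, study$endpoints)
rank_substances(mat, calls, scheme = "sum_z_wauc")[1:5, c(
  "substance_id", "n_active", "min_pod", "sum_z_wauc", "rank")]
#>   substance_id n_active min_pod sum_z_wauc  rank
#> 1 G04_C1              2  0.0109      3.38      1
#> 2 G03_C1              3  0.0641      1.07      2
#> 3 G02_C1              1  0.345       0.777     3
#> 4 G03_L1              3  0.234       0.732     4
#> 5 G03_L3              3  0.191       0.369     5

endpoint_enrichment(mat, mat$groups)[1:3, c("endpoint_id", "f_value_1", "rank")]
#>   endpoint_id f_value_1  rank
#> 1 E01              774.     1
#> 2 E05              361.     2
#> 3 E06              279.     3
```

Of the 112 substance × endpoint pairs, 29 are called active. The
purported active constituents (`*_C1`) outrank their parent-extract lots
in the summed Z-scaled wAUC ranking because the simulator gives them
larger maximal responses and lower EC50s, and the endpoint whose
activity is most consistent within botanical groups (`E01`) tops the
F-value ranking.

A command-line wrapper mirrors the same stages:

```sh
Rscript exec/botanitox simulate --out plates.csv --truth truth.csv --seed 3
Rscript exec/botanitox fit --in plates.csv --endpoints plates_endpoints.csv --out metrics.csv
```

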