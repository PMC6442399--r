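---
title: "Methods: qHTS concentration-response analysis in botanitox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qHTS concentration-response analysis in botanitox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(botanitox)
```

## The analysis model

`botanitox` analyses quantitative high-throughput screening (qHTS) data:
substances tested as full concentration series, in replicate, across a
panel of cell-based assay endpoints on 384-well plates. The pipeline
makes three structural assumptions:

* every plate carries enough solvent (DMSO) and positive-control wells
  to define a response scale — percent response is
  `(V − V_DMSO) / (V_pos − V_DMSO) × 100` with the control *medians*,
  which makes normalization robust to a few aberrant control wells and
  invariant to any additive offset applied to the whole plate;
* a true concentration-response is monotone in the direction of the
  endpoint's effect, so departures from monotonicity at the
  noise-threshold scale are treated as noise;
* activity is a property of the substance × endpoint pair supported by
  replication: a single significant curve out of three is not evidence
  of activity.

Decrease-direction endpoints are sign-flipped at normalization time so
that all downstream filtering handles "effect" as positive response;
the native sign is restored on the reported wAUC and Emax. This keeps a
single code path for both directions.

### Baseline rescaling

The percent response is rescaled so the curve baseline sits at 0%. The
estimator is the median response of the two lowest concentrations,
applied per curve. Per-curve (rather than per-plate) rescaling was
chosen because it also absorbs any additive artifact that is constant
along a titration series — with the simulator's one-substance-per-column
layout, a pure column gradient is removed entirely by this step. The
estimator is idempotent, so rescaling an already-rescaled curve is a
no-op. Its cost is a small bias when a substance is already active at
the two lowest tested concentrations; such potent responses still cross
the threshold and return the lowest tested concentration as their POD.

### The noise threshold

Each endpoint receives one threshold in % response units:

    T = max(k · SD(DMSO responses), data floor, lower bound)

with `k = 3` by default, the data floor being the 95th percentile of
|response| at the two lowest concentrations pooled across all substance
curves of the endpoint, and a configurable lower bound (default 1%)
that keeps `T` positive on degenerate noise-free data. Combining the
control SD with the substances' own baseline spread guards against
plates whose controls happen to be quieter than the substance wells.
How exactly to combine the two sources is an open design choice; the
max-with-floor rule was picked because it is monotone in both inputs
and never lowers the threshold below what either source alone would
justify.

### Curve filtering and the four activity parameters

The filter runs three stages on each curve:

1. **Spike removal** — an interior point that differs from both
   neighbours by more than `T`, with opposite-signed jumps, is replaced
   by its neighbours' mean, iterated to a fixpoint. Isolated dispenser
   or read artifacts vanish; genuine two-point responses survive.
2. **Sub-threshold zeroing** — responses with `|r| < T` become 0, so
   curves that never leave the noise band are exactly zero afterwards.
3. **Weak monotone envelope** — after the running maximum, a drop
   smaller than `T` is clipped back to the maximum (plateau noise),
   while a larger drop zeroes the rest of the curve: a lost response at
   high concentration (e.g. cytotoxicity masking, compound
   precipitation) is treated as unrecoverable signal, not as activity.

The four per-curve parameters are then:

* `wAUC` — trapezoidal integral of the filtered response over log10
  concentration, normalized by `100 · (log10 c_max − log10 c_min)`, so a
  full-range 100% effect scores 1 and an all-zero filtered curve scores
  exactly 0. A curve is *significant* iff `|wAUC| > 0`, which by
  construction coincides with a POD being assignable.
* `POD` — the concentration where the response equals `T`, interpolated
  linearly in log10 concentration on the *pre-zeroing* magnitudes, so a
  crossing between grid points yields a between-grid POD; ties and flat
  segments at exactly `T` resolve to the lowest qualifying
  concentration, and a first point already above `T` returns the lowest
  tested concentration.
* `EC50` / `Emax` — maximal-magnitude response and the interpolated
  concentration of its half, from the filtered curve.

One caveat worth stating: the threshold is *not* globally monotone on
arbitrary curves. Because a drop smaller than `T` is clipped while a
larger one truncates the tail, a higher threshold can tolerate a dip
that a lower threshold treats as loss of response, and `|wAUC|` can
locally increase with `T` on noisy non-monotone curves. On monotone
(effect-direction) curves — the family the filter is designed for —
raising `T` never increases `|wAUC|` and never lowers the POD, and the
test suite asserts exactly that.

### Calls, interference and integration

The replicate-majority rule (`> 50%` of curves significant) assigns
active/inactive; median potency parameters are computed over the runs
where each parameter is present, with an even count resolved by the
midpoint mean. Curves with fewer than 4 points count as non-significant
rather than shrinking the denominator — conservative toward inactivity.

Two potency comparisons use a fold cutoff that the screen itself does
not pin down numerically; both default to 3-fold, about one half-log
dilution step, and are configuration keys:

* **counter-screen interference** — an active primary call whose paired
  counter screen is active with `POD_counter ≤ 3 × POD_primary` becomes
  *inconclusive* (flag `interference`) and its potency medians are
  withdrawn;
* **aromatase / ER antagonism** — when both effects are active and the
  ER-antagonism POD is within 3-fold of the aromatase POD, the
  aromatase call is flagged `aroer_confounded` (label unchanged — the
  flag marks ambiguity of mechanism, not of activity).

Real-time cytotoxicity time points are integrated by summing the
per-timepoint median wAUCs and representing potency by the most potent
POD among active time points.

## Profiling choices

* The log10 POD matrix covers primary endpoints only; correlation and
  embedding use the wAUC matrix over *all* readouts including counter
  screens, which carries both potency and efficacy information at the
  highest granularity.
* Inactive and inconclusive cells are imputed at 1000 µg/mL
  (log10 = 3), one dilution step above the default 100 µg/mL top tested
  concentration: imputed cells are distinguishable from any measurable
  POD yet finite for distance computations.
* Spearman correlation uses average ranks on ties; undefined
  correlations (a constant vector) are assigned 1 only when both
  substances are all-zero, 0 otherwise; negative correlations are set
  to 0. The correlation of two fully inactive substances is thereby a
  deliberate statement that "inactive everywhere" is a shared profile.
* Between-group correlation curves compare each group member with the
  *most active lot* of every other group — most active by number of
  active primary endpoints, ties by larger total |wAUC|, then
  lexicographic id. Both the per-other-group values and the pooled
  cumulative distribution can be read from the output, which keys every
  value by the comparator group.
* ANOVA enrichment computes the classical F from sums of squares so the
  degenerate cases have defined behaviour: zero within-group variance
  with real separation reports `+Inf` and ranks first; a constant
  endpoint is flagged degenerate and ranks last. On non-degenerate
  layouts the statistic agrees with `stats::oneway.test(var.equal =
  TRUE)` to ≤ 1e−10 (tested on random layouts).
* Z-scoring of wAUC for the ranking uses active cells only, matching a
  summation "from the active responses"; a configuration switch
  (`z_active_only`) restores all-cells scaling. Endpoints with fewer
  than two contributing cells or zero variance contribute 0 and are
  marked degenerate. Ranks are dense and ties share a rank, so
  re-running a study yields stable orderings.
* The t-SNE embedding precomputes the Euclidean distance matrix on wAUC
  rows and runs the exact (theta = 0) algorithm with perplexity 30 and
  5000 iterations by default, without PCA preselection; the seed fixes
  the initialization, making coordinates reproducible bit-for-bit. For
  substance sets smaller than `3 · perplexity + 2` the perplexity is
  reduced with a warning rather than erroring, since small pilot panels
  are common.

## What the simulator emulates — and what it does not

`generate_study()` produces raw reads, not responses, so the whole
pipeline including normalization is exercised. Per endpoint × run it
lays out 384-well plates with columns 1–2 empty, 16 DMSO wells (column
3), 16 positive-control wells (column 4), and one substance per
remaining column with a 15-point, third-log dilution series (default
top concentration 100 µg/mL — a typical extract-equivalent screening
range; the true range of any given screen is a free parameter). Truths
are Hill curves `top · c^h / (ec50^h + c^h)` shared within a botanical
group, jittered per lot (±10% on top, ±0.1 on log10 EC50 by default),
with constituents amplified (1.3× top, 0.3× EC50) to emulate purported
active single chemicals outperforming their parent extracts. Noise is
additive Gaussian on the % response scale *before* back-conversion to
raw signal, which keeps the configured threshold interpretable in
response units; control-well SDs default to the same noise level
converted to signal units so `3 · SD(DMSO)` is coherent with the
configured noise. A low-amplitude smooth column gradient (default 80
signal units, 2% of the control span) gives the pattern-correction hook
something to remove; amplitude 0 disables it.

Real screening data differ in ways the simulator does not model:
non-Gaussian and heteroscedastic noise, edge effects and evaporation
gradients that are not additive, autofluorescent or assay-interfering
chemistry beyond a boolean counter-screen flag, solubility-driven
truncation of titrations, and mixture truths that are not Hill-shaped.
Passing tests therefore demonstrate the *algorithmic* correctness of
the pipeline under its stated model, not robustness to every real-world
artifact.

## Problem sizes and tolerances used by the test suite

The suite favours a few deep, parameterised checks: 1000 random curves
for the wAUC-oracle comparison (≤ 1e−12 against an independent
trapezoid), 100 random layouts for the ANOVA reference comparison
(≤ 1e−10), a 200-substance × 4-endpoint × 3-run noisy study for
activity/POD recovery (sensitivity ≥ 95%, false-positive rate ≤ 5%,
median |log10 POD error| within one dilution step), and small 3–5 group
studies elsewhere. Zero-noise identities are asserted at 1e−9 absolute;
exact rule constants (imputation at log10 1000 = 3, both-zero
correlation 1, negative correlation 0, sub-threshold wAUC 0) are
asserted identically, with no tolerance.

## Known limitations

* The curve filter is a documented stand-in for noise-filtering
  algorithms of the CurveP family, whose exact weighting is defined by
  reference in the literature; it preserves the stated behavioural
  contract (zero iff no above-threshold response, monotone on monotone
  curves) rather than reproducing any specific implementation.
* No nonlinear Hill fitting, benchmark-dose modeling, or confidence
  intervals on POD: the parameters are interpolation-based by design.
* The pattern-correction hook implements only additive column-then-row
  median effects; multiplicative or spatially smooth-nonlinear plate
  artifacts are out of scope.
* Whether the original analyses rescaled baselines per curve or per
  plate is not documented; per-curve is implemented (see above).
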