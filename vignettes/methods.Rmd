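---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery
it implements: the assumptions behind each stage, the tunable parameters
and their defaults, what the synthetic generator does and does not
emulate, and where the design was genuinely open, what was decided and
why.

## The screening problem

Fluorescent-cell-barcoded (FCB) phospho-flow screens treat cells in
multi-well plates (compounds, DMSO vehicle wells, control drugs), label
each well's cells with a unique combination of two dye intensity levels,
pool everything into a single cytometry tube, stain with a panel of
phospho-specific antibodies, and acquire one file per tube. Analysis
must undo the pooling (debarcoding), normalise intensities, and then
quantify per-compound bioactivity at the single-cell level: fold
changes against vehicle, hit calling, embedding-based comparisons of
treated versus vehicle cells, enrichment labels for rare
subpopulations, cell-type selectivity, and dose-response potency.

`cytosar` implements this pipeline with every stage testable against a
ground-truth-labeled synthetic plate generator.

## Arcsinh scaling

All functional intensities are analysed on the hyperbolic-arcsine scale
`asinh(x / cofactor)`: linear near zero (accommodating negative
compensated values), logarithmic for large `x`. The cofactor (units of
raw intensity) sets the transition point. Defaults follow standard
practice for the two instrument generations the defaults emulate: 150
for the four-readout diversity screen profile, and 6000 for the
11-readout deep-characterisation panel with per-marker overrides
(Ki67 and p-STAT5: 25000; p-S6 both sites, p-LCK, p-STAT3, p-HH3,
p-4EBP1: 12000). Scaling is an explicit, recorded stage — never hidden
in I/O — so cofactors stay auditable, and the transform is exactly
invertible (`sinh(x) * cofactor`, round trip to 1e-9 relative error).

Fold changes are differences of scaled medians:
`delta = median(asinh(treated/c)) - median(asinh(vehicle/c))`. This is
the standard log-like "arcsinh ratio": 0 means no change, and on the
logarithmic part of the scale +1 is about an e-fold increase. A literal
ratio-inside-arcsinh variant (`asinh` of the raw median ratio) is
available behind `mode = "arcsinh_ratio"` for comparison, but the
difference form is the default because it is the only reading for which
"no change" maps to exactly 0 for all intensity levels.

## Synthetic plates: what is emulated

`generate_well_events()` draws each marker's scaled intensity from a
Gaussian on arcsinh scale (location/spread per marker; default location
1.5, spread 0.4) and maps it back to raw intensity through the inverse
arcsinh. Arcsinh-normality is the standard generative assumption for
fluorescence and makes the generator's shift parameters directly
interpretable in the same units as the pipeline's fold changes.
Treatment is a per-marker signed shift; a configurable fraction of
cells (default 3% for the built-in RP signature) is instead routed to a
hyper-activated "island" with its own shifts, flagged in a
`ground_truth` channel that analysis stages never consume.

Scatter channels are correlated log-normals with a configurable doublet
fraction (doublets double the area channels at unchanged height, so the
FSC-H/FSC-A singlet gate removes them); uptake and viability dyes are
unimodal log-normals with a configurable dead-cell fraction. Barcoding
appends two dye channels drawn around the well's level centers (default
8 x 6 grid, centers 0.55 arcsinh units apart with level spread 0.08 —
about 7 spreads of separation, emulating a well-titrated dye series),
optionally mixed by a known 2 x 2 spillover matrix (default identity;
instrument-side compensation is out of scope).

Not emulated: spectral (multi-detector) signal formation and unmixing,
cell-cycle or kinetic signalling structure, marker-marker correlations
within a well, heavy-tailed outliers, and acquisition drift. Passing
tests therefore demonstrate algorithmic correctness under a clean,
well-specified null — not robustness to every artefact of real
cytometry data.

## Debarcoding

Each dye is fitted independently with a one-dimensional Gaussian
mixture (as many components as the scheme has levels) on the
arcsinh-scaled dye intensity. The grid design factorises, and 1-D fits
are far more robust than a joint 2-D mixture at small per-well counts.
The EM is initialised deterministically at evenly spaced sample
quantiles — component `i` of `L` at the `(i - 0.5)/L` quantile, equal
weights, common spread — making fits reproducible and order-invariant
without a random restart. A fitted component weight below `0.1/L`
signals a starved level and raises a diagnostic naming the dye.

Events are assigned to the level pair maximising the product of per-dye
posterior responsibilities; that product is the confidence. The default
confidence threshold is 0.9 (a package choice; published debarcoding
tools do not state one), and unassigned events are excluded from all
downstream statistics, mirroring the role of the barcode-uptake QC
gate. On the default scheme the accuracy contract is >= 99% correct
among confident events with <= 5% unassigned.

## QC gating

The four standard gates are implemented as parameterised rules rather
than manual polygons (which are irreproducible): singlets as a bound on
the FSC-H/FSC-A ratio (default 0.70-1.30 around the singlet ratio;
the ratio bound is configurable since instruments differ), intact cells
as an FSC-A x SSC-A rectangle, uptake and viability as thresholds.
Gates apply in order; the retention report reconciles exactly
(`kept + removed = in`, each gate's input is the previous gate's
output). A gate that removes every remaining event warns rather than
fails, since an empty well is a legitimate (if alarming) screen
outcome.

Percentiles everywhere use linear interpolation between closest ranks
(`quantile type 7`), pinned so order-statistic tests are exact.

## KNN enrichment and the degree of difference

Treated and vehicle cells are equally subsampled (exact equal counts
per group, without replacement), jointly embedded in 2-D, and each
cell's neighbourhood is scored: `fraction_from_test` = proportion of
its `k = 60` nearest neighbours (self excluded) carrying the test
label. Cells at or above 0.95 are "red" (enriched under treatment), at
or below 0.05 "blue" (enriched in vehicle). The degree of difference is
`(red + blue) / total` — exactly 0 when the two conditions interleave,
approaching 1 when they fully separate. The 0.95/0.05 cutoffs follow
the published KNN-enrichment convention and are config-exposed; the
statistic is monotone in them, so tests pin the defaults.

The default embedding backend is Barnes-Hut t-SNE at perplexity 60 with
1000 iterations (the backend's standard setting; only neighbourhood
structure matters downstream, so extra iterations buy visual polish,
not statistical power). A UMAP backend is selectable. Embeddings are
stochastic; all comparisons that consume one use a fixed seed and the
same backend throughout.

Island gates are polygon vertex lists (even-odd ray casting with a
half-open edge convention: lower/left boundaries inside, upper/right
outside, so tiling gates count each cell once). A convenience auto-gate
takes the connected red-hotspot region (single linkage at 1/30 of the
embedding range) with the highest mean of a named marker and returns
its convex hull — replacing the manual gate with a reproducible rule.

## Marker Enrichment Modeling

For a population against a reference, per marker:

    raw = |MAG_pop - MAG_ref| + IQR_ref / IQR_pop - 1

negated when `MAG_pop < MAG_ref`, where MAG is the arcsinh-scale median
and IQR the interquartile range. Besides a comparison-population
reference, the statistical-null reference sets `MAG_ref = 0` for every
marker and a common `IQR_ref` equal to the median of the candidate
population's per-marker IQRs — a null hypothesis standing in when no
natural comparison population exists.

Markers whose population magnitude is 0 (absolute tolerance 1e-12, for
float medians) score raw 0: the IQR term is zeroed because a marker
with no signal is not enriched however tight its spread, and the
alternative reading (raw = -1) would brand every unshifted marker as
de-enriched. Degenerate population IQRs are floored at 0.5 arcsinh
units (flagged, configurable) to prevent division blow-ups. Scaled
scores are `10 * raw / max(|raw|)` within the analysis at hand — the
within-analysis maximum is what makes "+10" mean "most enriched marker
of this population" — with the normalisation ordered so the extreme
marker lands on exactly 10 in floating point. Labels render as
`"gH2AX+10, p-4EBP1+7"`: integer-rounded scores at or above the display
threshold (default 5), descending, alphabetical within ties.

## Hit selection and screening statistics

The bioactivity threshold is `vehicle median + 3 x IQR` over
vehicle-well fold-change values, pooled across readouts by default
(one threshold line for the screen, matching how a single cutoff is
drawn across all readouts); a per-readout mode is provided. Requiring
the vehicle spread rather than a fixed cutoff adapts the threshold to
assay noise. A compound is a hit on any readout exceeding the
threshold.

Percent-positive gating is vehicle-referenced by default: the cutoff is
the vehicle's 99th percentile on the gated channel, so vehicles sit
near 1% positive by construction, and the downstream classification
threshold (15% positive) separates genuine induction from tail noise.
Cell-type selectivity is `log2((pct_A + eps)/(pct_B + eps))` with a
0.1-percentage-point pseudo-count guarding empty denominators.

The rank-sum comparison of island occupancy between subclasses uses the
two-sided Wilcoxon test: exact enumeration when the combined sample is
at most 12 without ties, otherwise the tie- and continuity-corrected
normal approximation; the all-tied degenerate case returns p = 1. No
multiple-testing correction is applied — the pipeline reports a single
planned comparison — and users running many such tests should adjust
accordingly.

## Dose-response

The 4PL log-logistic curve is `f(x) = c + (d - c)/(1 + (x/e)^b)` with
hill slope `b`, asymptotes `c <= d` (percent), and EC50 `e` in dose
units. This parameterisation evaluates dose 0 as the asymptote limit,
so the zero-dose control enters the fit without a log singularity
(rising activation curves have `b < 0` in this form). Fitting is
Levenberg-Marquardt least squares on `(b, c, d, log e)` — the log
keeps the EC50 positive — started from the response range and the dose
nearest half-response, with the fit canonicalised afterwards so
`c <= d`. The fit is invariant to dose-unit rescaling (doses x1000
give EC50 x1000 with the other parameters unchanged).

## Determinism and problem sizes

Every stochastic stage takes an explicit seed and restores the global
RNG state afterwards; a fixed seed gives bit-identical generator output
and identical embeddings, and `run_pipeline()` derives all stage seeds
from the single config seed, so a manifest reproduces every number.

Test and verification sizes are chosen to make Monte-Carlo error
negligible relative to each tolerance while keeping the default suite
quick: 10,000 cells per side (the study-scale condition) for the
vehicle-vs-vehicle null, repeated over five seeds; 100,000 cells for
binomial recovery of the 3% island fraction; 10,000 cells per dose for
EC50 recovery under sampling noise; a few hundred cells per well for
end-to-end pipeline runs, where only structural properties are
asserted. Oracle-equivalence checks (brute-force KNN, permutation
rank-sum, direct-formula MEM) run on instances small enough to
enumerate exactly.

## Known limitations

- Debarcoding assumes the two dyes factorise; strongly correlated dye
  uptake or heavy spillover would need the joint model this package
  deliberately avoids.
- The auto island gate assumes the island is a connected red-hotspot
  region; fragmented islands need a hand-drawn polygon.
- t-SNE coordinates are not comparable across runs or seeds; all
  quantitative comparisons must share one embedding.
- The generator's clean arcsinh-normal wells make separation tasks
  easier than real data; accuracy contracts (debarcoding, hotspot
  nulls) are statements about these conditions.
- The 4PL fit reports a convergence flag but no profile confidence
  intervals; potency comparisons near the dose-range edge deserve
  re-fitting with a wider design.
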