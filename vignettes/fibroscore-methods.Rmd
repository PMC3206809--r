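---
title: "Methods: from per-cell screens to an in-vivo-anchored efficacy score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from per-cell screens to an in-vivo-anchored efficacy score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroscore)
```

## Overview

`fibroscore` turns a per-cell high-content screen of activated hepatic
stellate cells (HSCs) into a single in vitro efficacy predictor per drug,
and anchors that predictor to in vivo histology. The pipeline has four
statistical stages, each of which this vignette describes together with its
assumptions, tunable parameters and numerical edge cases:

1. **KR values** — per (drug, marker, feature, concentration) effect sizes
   in [−1, 1] against the drug-free control;
2. **SAUC** — per (drug, marker) direction-corrected areas under the
   KR–concentration curve;
3. **E_in vivo and E_predict** — the severity-weighted in vivo index from
   histological scores, and the weighted SAUC combination whose integer
   weights are optimised against it;
4. **IVIVC and profiling** — the linear in vitro–in vivo regression,
   score prediction, and robustness/saturation/PCA analyses.

## Stage 1: KR values

For each condition the per-cell distribution of a feature is compared with
the same drug's concentration-0 control.

**Unimodal features** get a signed two-sample Kolmogorov–Smirnov score: the
magnitude is `D = max |ECDF_treated − ECDF_control|`, evaluated over all
pooled values so that ties are handled exactly, and the sign is the sign of
the median difference. Only the D statistic is used, never the KS p-value:
KR is an effect size, not a test. Tie-breaks: when the medians are exactly
equal the sign is taken from the mean difference; if that is also zero, or
when D = 0 (identical samples), the score is 0. The score is antisymmetric
whenever the medians differ.

**Bimodal features** (distinct positive/negative cell populations, e.g.
BrdU incorporation) get the difference of positive fractions
`p_treated − p_control`, with a cell counted positive above a threshold
placed at the midpoint between the two control mode locations. A threshold
outside the observed range produces a warning, not an error — the score is
still defined.

**Modality classification** is decided once per (marker, feature) on the
control cells of all drugs pooled (at least 50 cells required; in practice
several hundred, since a misclassification rate of a few percent is
observable on pure Gaussian samples below ~100 cells). The rule fits 1- and
2-component Gaussian mixtures (equal- and free-variance) and picks the
component count by BIC, then declares the feature bimodal only if the
fitted 2-component density actually has two modes on a fine grid. The
second condition is what downstream code needs: a usable positive/negative
threshold exists only between two real modes, so a mixture whose components
sit closer than the bimodality limit (≈2σ for equal weights) is treated as
unimodal. The fit is deterministic for a given sample: for large samples
mclust is initialised from an evenly spaced subset of the sorted values
(2000 points), involving no random numbers. A dip-statistic test would be a
reasonable alternative rule; the mixture-based rule was chosen because it
yields the threshold as a by-product and is decisive on the borderline
cases above by construction.

## Stage 2: SAUC

Each feature's KR series is integrated by the trapezoidal rule over a
concentration axis normalised to [0, 1], and the per-feature areas are
summed within a marker and multiplied by the marker's anti-fibrotic
direction (+1/−1) and a cosmetic `scale` (default 1000, placing scores on
the order of magnitude of published predictor values).

*Axis modes.* The default axis is the dilution-step **index** (0 … n−1,
normalised): drugs are screened with different maximum concentrations
anchored at their potencies, so an index axis makes SAUC comparable across
drugs. `log2` (exact 2-fold steps, control one step below the lowest dose)
and `raw_um` axes are provided; the raw axis compresses the low doses and
so up-weights the top of the series. The chosen mode is recorded on the
result.

*Control anchoring.* KR of the control against itself is 0 by definition,
so a series lacking a concentration-0 point is anchored at (0, 0). A series
that already spans the whole axis is integrated as given — hence a series
constant at 1 scores exactly 1. At least two points are required; a single
point has no area and is an error.

*Directions.* The direction table is data, not code
(`inst/extdata/marker_directions.csv`), because direction assignments are a
biological judgement: apoptosis markers (caspase 3) rise under effective
treatment while proliferation (BrdU), contractility (F-actin),
mitochondrial membrane potential, collagen III, TIMP-1, DHE, Smad3 and
pCREB fall, and MMP-2 (matrix-degrading) rises. All defaults are
user-overridable; per-feature directions inherit the marker direction.

## Stage 3: E_in vivo and E_predict

**E_in vivo = (S_c − S_t) × S_c** on scores linearly rescaled to 0–4 (the
common range of Metavir/Knodell/Ludwig-type scales). The multiplication by
S_c weights the score reduction by baseline severity — severe fibrosis is
harder to move, so the same absolute reduction counts for more. Negative
values (drug worsened fibrosis) are retained. When several studies cover a
(drug, model) pair the highest index is kept, within a model only: severity
induced by different hepatotoxins differs, so indices are never compared
across models. Display rounding is one decimal, half away from zero;
internal values are never rounded.

**Weight optimisation.** All `3^m` weight vectors over {0, 1, 2} are
enumerated (lexicographic order). For each vector the candidate predictor
`Σ w_m SAUC_m` is computed per training drug, negatives are clipped to 0
*before* the rank test (the predictor is defined with clipping; a flag
disables this), and the vector is kept if it achieves Spearman ρ = 1 with
the training E_in vivo, allowing one outlier. Each vector may discard a
different drug — the allowance is per evaluation, reflecting that with
training sets of five or six literature-derived values a single
incomparable study can mask an otherwise perfect ranking. The optimised
weight per marker is the **modal** weight among all ρ = 1 vectors, ties
broken toward the smaller weight (parsimony). If no vector achieves ρ = 1
the optimiser fails explicitly, reporting the best ρ attained, rather than
returning a silently sub-optimal vector.

*Numerics.* ρ = 1 with ≤1 removal is detected by a vectorised strict-
concordance check on the candidate matrix sorted by training rank (ties in
the candidate — e.g. several drugs clipped to 0 — correctly prevent ρ = 1
unless removing one drug resolves them). This is exactly equivalent to
per-vector Spearman evaluation, which the test suite verifies against a
naive brute-force reimplementation, but it keeps the full 59 049-vector
lattice below a second. The standard Spearman coefficient on [−1, 1] is
used throughout; since the only criterion is perfect concordance, any
monotone rescaling of ρ would select the same vectors.

**Non-specific collagen flag.** A drug whose collagen III total-intensity
KR exceeds +0.2 at the top two concentrations and is non-decreasing (within
a 0.05 tolerance) over the upper half of the series is increasing collagen
with dose — a cytotoxic/non-specific signature, not an anti-fibrotic one —
and its E_predict is set to 0. Both thresholds are arguments; the defaults
are placed so that a monotone concentration-dependent increase trips the
flag while null drugs (|KR| < 0.05) cannot.

## Stage 4: IVIVC and profiling

The regression of E_in vivo on E_predict is ordinary least squares with at
most one excluded drug. Exclusion accepts an explicit drug name (the
literature fixtures name their outliers) or `"auto"`: remove the point with
the largest absolute studentized residual if doing so improves R² by more
than 0.1, else keep all points. A non-finite studentized residual — the
remaining points fit perfectly without that one — is treated as maximally
outlying. Predicted treated scores invert the index definition:
`S_t = S_c − E/S_c`, clipped to [0, S_c]; this inverts `efficacy_index`
exactly on interior solutions.

Drug grouping: the **n** group is exactly the drugs with E_predict = 0, the
**vp** group the `vp_size` (default 7) largest positive values (boundary
ties broken alphabetically — documented, arbitrary), **p** the rest. PCA of
the SAUC matrix is column-centred and unscaled by default (SAUC columns
share units; a switch enables unit-variance scaling). Marker-saturation
curves report the mean best attainable ρ over random marker subsets of each
size; group intensity summaries use quartiles with 1.5 × IQR whiskers.

## The synthetic screen generator

The generator emulates the study design — drugs × (2-fold dilution series
+ control) × 10 markers × 16 features × ~1000–2000 cells per condition —
with known ground truth, so the pipeline's rank recovery can be measured.
Each drug has a `true_efficacy` in [0, 1], per-marker susceptibilities in
[0.5, 1] (drawn once per panel), and a Hill dose response
`h(c) = c^n/(c^n + EC50^n)` (default EC50 5 µM, Hill coefficient 1.5, so a
40 µM series spans h ≈ 0.1–0.96). Unimodal features are Gaussian
(mean 100, σ 20) whose mean shifts by
`1.5 σ × efficacy × susceptibility × direction × h(c)`; bimodal features
are two-Gaussian mixtures with modes 10 σ apart (50/100, σ 5 — well beyond
the ≥4 σ needed for unambiguous modality classification) whose responder
fraction shifts from 0.5 by 0.45 × the same factor. Shift directions follow
the marker-direction table, so anti-fibrotic drugs yield positive SAUC by
construction. Non-specific drugs instead *increase* collagen III intensity
by `1.2 σ × h(c)` regardless of efficacy, exercising the collagen flag.

Matched in vivo records draw S_c uniformly from a configurable range
(default 2.5–4) and set
`S_t = clip(S_c − g(efficacy)·S_c + ε, 0, S_c)` with
`ε ~ N(0, noise_sd)`; the link `g` is the identity by default — the
simplest monotone map consistent with a positive in vitro–in vivo
relationship.

*What it does not emulate:* image pixels and segmentation error,
plate/well-position artifacts, batch effects between staining sets,
feature–feature correlation structure within a cell, and heavy-tailed or
skewed feature distributions. Passing the recovery tests therefore shows
the statistics are implemented correctly and the design is identifiable
under clean conditions; it does not certify performance on real screens
with those artifacts.

All generation is seeded (`withr::with_seed`) and byte-reproducible: the
same design, panel and seed always give the identical table.

## Problem sizes and test design

The test suite exercises the full pipeline at deliberately modest sizes:
the end-to-end rank-recovery check uses 12 drugs × 10 markers × 8 features
× 11 concentrations × 300 cells per condition (≈ 400 000 rows), which
recovers the ground-truth ranking with Spearman ρ well above the 0.8
acceptance bar; null-drug bounds use a single drug at 5000 cells per
condition, where sampling noise keeps every |KR| below 0.05; oracle
equivalence checks (signed KS vs a brute-force ECDF scan, the optimiser vs
a naive reimplementation, the concordance mask vs per-column Spearman) run
exhaustively on small alphabets and panels. Literature-derived checks use
the packaged fixture tables: the 18-row histology table reproduces every
printed index at one decimal, the regressions reach R² ≥ 0.9 for both
treatment models (with their named outliers excluded) and 0.53 for the
preventive model, and the published predictor table yields the 16-drug n
group and the expected 7-drug vp group.

## Known limitations

* The exact published sign convention for the KS score and the bimodal
  ratio, the published non-specific-collagen rule, and the published
  optimised weight vector are not available in detail; the versions here
  are principled reconstructions, and published per-drug predictor values
  are therefore consumed as a fixture table rather than recomputed.
* Whether the published integration used a raw-µM or index concentration
  axis is unknown; absolute SAUC/E_predict magnitudes are consequently not
  comparable to published ones (the `scale` constant is cosmetic), while
  rankings are insensitive to the choice for complete 2-fold series.
* Modality classification below ~100 pooled control cells misclassifies a
  few percent of unimodal features as bimodal; pool controls across drugs
  where possible.
* The in vivo index inherits every limitation of literature curation:
  inter-observer variability of histological grading, dose/duration
  heterogeneity, and scale conversions are not modelled — the
  outlier-tolerant rank criterion is the only concession to them.
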