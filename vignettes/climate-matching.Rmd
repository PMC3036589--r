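---
title: "Climate matching for invasion risk: rule-based envelopes and an audited maximum-entropy model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate matching for invasion risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(climhull)
library(dplyr)
```

## The problem

Predicting where an introduced species could establish requires matching the
climate of candidate regions against the species' climatic tolerances. The
difficulty is that occurrence records only reveal the *realized* climate
space — the conditions a species happens to occupy in its native range,
after biotic interactions and dispersal barriers have cut down the larger
*fundamental* climate space it could tolerate. A model calibrated tightly to
the realized space will systematically underpredict invasion risk, and the
errors are asymmetric: for a risk screen, missing a suitable region is worse
than flagging an unsuitable one.

`climhull` implements two contrasting estimators of a species' climate
envelope plus the audit machinery needed to judge any such model:

1. a **rule-based envelope**: the minimum convex polygon of monthly
   (temperature, log10 precipitation) conditions at occupied localities,
   with months of hibernation and aestivation excluded from the suitability
   requirement; and
2. a **compact maximum-entropy model** (`maxent_fit()`): a Gibbs
   distribution over background cells with L1-penalized coefficients on
   linear, quadratic, product and hinge features of the 19 bioclim
   variables.

Everything runs on a seeded synthetic world, so the full pipeline is
testable without downloading climate rasters.

## The rule-based envelope

Each locality contributes up to twelve points in climate space, one per
month: $(T_m, \log_{10}\max(P_m, 0.1))$. The 0.1 mm/month floor keeps dry
months finite and matches the 0.1 log-unit resolution of the area grid. A
hibernation/aestivation hypothesis $(h, a)$ removes, per locality, the
circular block of $h$ consecutive months with the lowest mean temperature
and then, from the remaining arc, the $a$ consecutive hottest months — the
species is assumed to buffer itself against climate during dormancy, so only
the active season must be suitable. Ties between candidate blocks go to the
earliest starting month, and the two blocks may abut (merging into one long
inactive season); whether abutment should instead be forbidden is a
judgement call we make explicit rather than hide.

The envelope is the convex hull of the pooled active-season points
(`build_envelope()`). Two properties follow directly from the geometry and
are load-bearing for the method's robustness:

* **No central-tendency weighting.** Duplicated or redundant localities add
  interior points and cannot move the hull. Only *divergent* climates
  enlarge the envelope, so modest numbers of mislabeled records drawn from
  climates similar to the species' own leave the match unchanged — unlike
  density-weighted models, where a handful of such records can reshuffle
  fitted coefficients.
* **The interaction rule.** Containment is tested against the polygon, not
  the bounding box: a temperature occupied somewhere and a rainfall occupied
  somewhere do not make their *combination* suitable.

Envelope area is reported as the integer count of lattice cells (1 °C by
0.1 log-unit, anchored at integer coordinates) whose centres fall inside or
on the hull — deterministic, and directly comparable across samples.
Projection (`project_envelope()`) marks a map cell suitable when every one
of its active-season months falls inside the hull; suitability is therefore
monotone in both $h$ and $a$.

`capture_curve()` quantifies sample-size sensitivity: for each decile $d$ of
the sample size it draws subsets (round-half-up of $dN$, 10 draws by
default), rebuilds the envelope, and reports mean and standard error of the
area as a percentage of the full-sample area. The 100% decile is the full
sample itself — 100% by construction — and subsets whose points are
collinear are retained as zero-area draws rather than redrawn, keeping the
estimator unbiased and the curve exactly reproducible under a seed.

## The maximum-entropy model and its audit

`maxent_fit()` maximizes

$$\sum_{i \in \text{presences}} \lambda \cdot f(x_i) \;-\; n \log Z(\lambda)
\;-\; n \sum_j \beta_j |\lambda_j|, \qquad
Z(\lambda) = \sum_{x \in \text{background}} e^{\lambda \cdot f(x)},$$

with $\beta_j = \beta_{\text{mult}} \cdot s_j$ and $s_j$ the feature's
presence-sample standard deviation over $\sqrt{n}$ (floored at
$0.05/\sqrt{n}$). The penalty acts on the per-presence likelihood scale: a
given multiplier then applies comparable shrinkage at any sample size, a
very large multiplier drives every coefficient to exactly zero, and a small
one approaches the unpenalized fit. This is a deliberately simple, fully
specified dialect — not a clone of any particular MaxEnt release — built so
that every audit quantity (parameter count, likelihood, threshold) is
exactly computable.

The background characterizes availability and is assumed to include the
presence conditions (pass `bind_rows(presences, background_sample)`). If the
presences are separable from every background row the penalized likelihood
has no maximum; the optimizer then reports non-convergence rather than
returning an arbitrary iterate.

**Optimization.** Cyclic coordinate descent with an exact soft-threshold per
coordinate (so dropped features carry coefficients that are exactly zero),
followed after each sweep by an orthant-projected Newton step on the active
set with a halving line search. The second-order step exists because pure
cyclic descent zigzags badly between collinear bioclim features; the
objective is monotone throughout, and convergence is declared when a full
sweep gains less than `tol` (default 1e-7). Feature scaling comes from the
background only, hinge knots sit at background quantiles, and projection
clamps features to their training range.

The audit quantities are:

* `count_parameters()` — the number of exactly nonzero coefficients, $K$;
* `aicc()` — $2K - 2\ln L + 2K(K+1)/(n-K-1)$ with $\ln L$ taken over raw
  scores normalized on the fitting background (the model's landscape);
  models with $n - K - 1 \le 0$ are inadmissible;
* `beta_sweep()` — refits over a multiplier grid and selects the
  AICc-minimizing $\beta$, ties to the larger (more parsimonious) value;
* `min_training_presence()` — the lowest presence suitability, the
  zero-omission threshold;
* `auc()` / `cross_validate()` — rank-based AUC with ties at half credit,
  and replicated holdout refits (default 25 replicates withholding
  `ceiling(0.10 n)` presences each);
* `permutation_importance()` — drop in training AUC after permuting a
  variable across pooled presence + background rows, floored at zero and
  normalized to sum to 100.

**A finding worth stating plainly.** In this dialect, the default multiplier
$\beta = 1$ does *not* reproduce the dramatic parameter inflation reported
for default-settings runs of older maximum-entropy tools. On synthetic
worlds with 19 collinear variables and 90 biased localities, $K$ at
$\beta = 1$ sits near the AICc optimum (and AICc sometimes prefers *weaker*
regularization); even nearly unpenalized fits plateau around the data's
support ceiling rather than at several times the optimal count. The
historical inflation appears to be a property of sequential optimizers that
leave many near-zero coefficients technically nonzero — an exact
soft-threshold L1 fit is structurally parsimonious at matched penalties. The
audit machinery (AICc sweeps, parameter counting, the overfitting screen)
remains exactly as useful; it simply finds less to condemn in this
estimator. The corresponding acceptance experiment is implemented faithfully
and reports the measured rate.

## Bioclim, collinearity, MESS

`derive_bioclim()` computes BIO1–BIO19 from monthly means with circular
quarters (all twelve 3-month windows, Dec–Jan–Feb allowed, earliest-start
tie-break). Seasonality uses the WorldClim dialect — BIO4 = 100·SD of
monthly temperature, BIO15 = 100·SD(precipitation)/(1 + BIO12/12) — stated
explicitly because a CV-percent dialect also circulates. BIO3 is flagged
`NA` when the annual range is zero.

`collinearity_summary()` reports all 171 unordered Pearson correlations
among the 19 variables as a signed-r decile histogram with counts above 0.5
and 0.8. Because "in excess of 0.8" is ambiguous between $r$ and $|r|$, both
counts are always emitted and neither is preferred.

`mess_similarity()` scores a value against a reference sample on the
standard percentile scale (maximum 100 at the median, negative outside the
reference range), with ties counted strictly-below — the source formulation
is ambiguous on ties, so the choice is documented rather than implicit.
`mess_surface()` takes per-cell minima across variables; cells with negative
similarity are *novel*, and novelty is always reported separately from
unsuitability: extrapolation withholds judgement, it does not render a
verdict.

## The four screens

`screening_report()` operationalizes model screening as disqualification,
never ranking:

| screen | fails when | default threshold |
|---|---|---|
| native-range inclusion | coverage of the occupied range < `min_coverage` | 0.95 |
| minimum training presence | MTP < `mtp_cutoff` | 0.1 |
| overfitting | $K >$ `factor` × AICc-optimal $K$ (strict) | 2 |
| eco-plausibility | suitable overlap with an expert mask > `max_overlap` | 0 |

Commissions are never penalized by the native-range screen (the fundamental
space is *expected* to exceed the realized one). The 0.95 coverage default
operationalizes "a major portion of the native range" — the literature gives
no number, so ours is configurable and always reported. The eco-plausibility
mask is expert input, never inferred; an empty mask marks the screen "not
evaluated", and unevaluated screens cannot disqualify.

## The synthetic world

`generate_climate()` builds a seeded world: latitudinal temperature gradient
(28 °C at the warm edge falling 18 °C across the domain), seasonality
growing poleward to `seasonal_amplitude` (default 8 °C) with a July peak,
diurnal range growing inland from 8 to 16 °C, and an August-peaking monsoon
whose concentration is set by `monsoon_strength` (default 2) over an annual
total falling from 1800 to 600 mm/yr poleward. Each month of each variable
carries an independent spatially smooth anomaly field (separable
box-smoothing of white noise, default SD 0.5 °C for temperature and 4
mm/month for precipitation): monthly anomalies are what give the 19 derived
bioclim variables realistic, less-than-perfectly-collinear structure. Land
lies west of a seeded lobed coastline, so distance-to-coast (breadth-first
search in cell units) is defined everywhere.

A `virtual_species()` is specified directly in climate space — a convex
fundamental polygon, true tolerances $(h_{\text{true}}, a_{\text{true}})$,
an access seed cell and a biotic mask — so its realized range
(`realized_range()`) is *derived*: climatic suitability ∩ biotic mask ∩ the
4-connected component reachable from the seed. `default_species()` builds
the polygon from climate quantiles (25th–95th temperature, 15th–95th log
precipitation) and seeds dispersal from the largest contiguous suitable
region, since a species' occupied range is its main block of habitat, not a
peripheral outlier cell. By construction fundamental ⊇ realized, which the
tests assert as exact coverage.

`sample_localities()` emulates museum records: cells drawn with probability
$\propto e^{-d_{\text{coast}}/\text{scale}}$ (default scale 6 cells, the
coastal collection bias), jittered within the cell, with
$\lfloor \text{error\_rate} \cdot n \rfloor$ records drawn from an adjacent
sister-species ring (`contaminant_region()`, a 2-cell dilation of the
realized range) and mislabeled with the focal species' name. The default
contamination 4/90 mirrors a documented real-world mislabeling rate. Ground
truth survives only in the `source` column, which real data would not have.

What the generator does *not* emulate: topographic relief (so no
elevation-driven microclimate), temporally correlated interannual anomalies,
spatially varying collection effort beyond the coastal gradient, and
georeferencing error. Tests passing on this world show the algorithms are
correct and the qualitative contrasts hold; they do not certify performance
on real rasters.

## Numerical choices and degenerate inputs

* Hull containment is inclusive of the boundary, with a relative tolerance
  of 1e-9 on the cross-product test; areas are integer cell-centre counts.
* Degenerate (collinear) envelopes are errors at build time and zero-area,
  flagged draws inside the capture curve.
* Cells violating `tmin <= tavg <= tmax` are removed from the land mask at
  construction; unit violations (temperatures outside [-90, 60] °C,
  negative precipitation) are errors, never silent rescales.
* Coordinate transforms use half-open cell intervals, so every in-bounds
  point belongs to exactly one cell and centre-of-cell round-trips are
  exact. Cell indices are 1-based with row 1 the northernmost.
* Duplicate-locality collapse keeps the first-read record (stable order).
* Zero-variance bioclim columns are dropped from the correlation audit with
  both raw (171) and effective pair counts reported.
* A zero-span MESS reference is flagged with a warning; equality scores 100,
  anything else is negative infinity rather than a fabricated finite value.
* All stochastic stages take explicit seeds and restore the caller's RNG
  state.

## Problem sizes

The test suite and the acceptance script run on worlds of 32×32 to 64×64
cells, 40–151 localities, backgrounds of 300–1000 cells, 19 bioclim
variables with up to ~200 derived features, 6-point β sweeps and 25-replicate
cross-validation — sizes chosen so a complete run takes a few minutes on one
core while every qualitative contrast of interest (collinearity structure,
capture-curve shape, AICc selection, novelty masking, screening verdicts)
is already expressed.
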