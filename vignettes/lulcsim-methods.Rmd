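---
title: "Logistic-CA-Markov land-change simulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logistic-CA-Markov land-change simulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

`lulcsim` simulates the decadal evolution of a six-class land-use/land-cover
(LULC) mosaic — cultivated land, forest, grassland, water, built-up and
deserted land — and accounts for two downstream consequences of that
evolution: the region's **biocapacity** (its capacity to produce renewable
resources, in global hectares) and its **landscape pattern** (patch
structure, aggregation, diversity).

The simulation couples three classical components:

1. **Logistic suitability.** For each class $k$, a binary logistic
   regression of occurrence on a stack of standardized driver rasters,
   $\operatorname{logit} p_k = \beta_0 + \beta_1 X_1 + \cdots + \beta_n X_n$,
   yields a probability surface ("suitability atlas"). Discrimination is
   scored by the rank-based ROC area; 0.7 is the conventional adequacy
   floor, and the bundled synthetic scenario is constructed so every class
   scores above 0.9 region-wide.
2. **Markov quantities.** The class transition matrix $P$ is estimated by
   cell-by-cell cross-tabulation of two dated maps; row $i$ is the
   empirical distribution of the destinations of class $i$. Future class
   *quantities* follow $S_{t+1} = P^\top S_t$, which conserves total area
   exactly. One step is one observed inter-map interval (a decade in the
   default scenario).
3. **CA allocation.** The projected quantities are placed on the lattice by
   a cellular automaton: the transition potential of class $k$ at cell $x$
   is $p_k(x)\, W_k(x)$, the suitability times the fraction of class-$k$
   cells in the surrounding window (default $5 \times 5$, with a floor
   $\varepsilon = 0.01$ so isolated growth remains possible). Over a fixed
   number of cycles (default 10), interim quotas move linearly from the
   current composition to the Markov targets, and deficit classes claim the
   best-ranked cells of surplus classes. Because targets are
   largest-remainder roundings of the projection, the final composition
   matches them *exactly*: quantity is decided by the Markov model alone,
   spatial arrangement by suitability and neighbourhood alone.

Agreement between a simulated and a reference map is summarized by Cohen's
Kappa, $\kappa = (P_0 - P_c)/(1 - P_c)$, with the usual qualitative bands
(poor below 0.4, general below 0.75, very good at or above 0.75).

## The synthetic scenario and what it stands in for

Real applications of this pipeline calibrate on multi-date land-cover
products and a dozen driver rasters assembled from terrain, climate,
accessibility and county-level socio-economic statistics. Those inputs
cannot ship with a package, so `generate_scenario()` builds a fully
synthetic study region with the same *structure* and known ground truth:

* **Drivers** (11 layers in four categories): smoothed-noise elevation with
  finite-difference slope and aspect; precipitation and temperature as
  directional gradients plus smooth noise (temperature includes an
  elevation lapse); Euclidean distance transforms to seeded built-up points
  and road lines; and four piecewise-constant "county" layers. Counties are
  drawn as predominantly agricultural or predominantly pastoral, so the two
  sector-output layers are bimodal and anti-correlated — the defining
  feature of an agro-pastoral transition mosaic.
* **Initial map**: each cell's class is drawn from the softmax of per-class
  linear predictors under known coefficients, then 3×3 majority smoothing
  (2 passes) creates contiguous patches. Intercepts are calibrated so the
  composition hits the configured targets — cultivated ≈ 38%, grassland ≈
  46%, forest ≈ 11%, built-up ≈ 3%, deserted ≈ 2%, water ≈ 0.5% — the
  nested cultivated/grassland-dominated mix typical of such regions.
* **Forward transitions**: every cell draws its next class independently
  from its row of a known, strongly diagonal decadal matrix `true_P`
  (persistence 0.92–0.99), and the drawn destination multiset is re-matched
  within each origin class so that the most suitable cells are the ones
  that change. Aggregate transition frequencies therefore converge to
  `true_P` while change remains spatially coherent.

The ground-truth coefficients have magnitudes of roughly 0.5–9 on
standardized drivers, giving each class a clearly separable environmental
niche (water in the lowest basins, built-up adjacent to existing seeds,
deserted land at the dry extreme, and the cultivated/grassland split
carried largely by the bimodal county economy). This strength is a
*construction choice*: the scenario is meant to be one where the fitted
models demonstrably work (region-wide ROC above 0.9, validation Kappa in
the "very good" band), so that test failures indicate implementation
defects rather than an unlearnable world. Passing these tests shows the
machinery is correct; it does **not** show that real land-cover products
would be fitted equally well — real drivers are collinear, noisy, and
partially unobserved.

All stochastic steps draw from explicitly seeded generators (sub-seeds
derived arithmetically from the scenario seed), so a seed plus a
configuration reproduces every map bit-exactly.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| cell size | 500 m | working resolution; 25 ha per cell |
| grid size | 256 × 256 | desk-scale default, seconds per run |
| CA filter | 5 × 5 | contiguity window of the neighbourhood weight |
| CA cycles | 10 | quota interpolation steps per simulated interval |
| `neighbor_floor` | 0.01 | keeps isolated growth possible |
| `n_per_class` | 5000 | stratified sample size per class for fitting |
| connectivity | 8 | patch delineation; adjacency for AI is always 4 |

## Fitting and numerical choices

* Drivers are z-scored over valid cells before fitting, so coefficient
  magnitudes are comparable across drivers and an "important driver"
  threshold on $|\beta|$ is meaningful.
* Per-class fits balance presences against an equal-sized seeded subsample
  of absences, which stabilizes rare classes (water is ~0.5% of the
  default landscape).
* Fits use `stats::glm` (pivoted IWLS, 50-iteration cap). Exactly
  collinear drivers are aliased and reported with coefficient 0, leaving
  predictions unchanged; suspected separation produces a bounded-iteration
  estimate with a warning rather than a failure.
* The ROC reported for an atlas (`atlas_roc()`) is computed over **all**
  valid cells against observed occurrence. The per-model training ROC is
  also kept, but it depends on the stratified sampling mixture (rare, hard
  classes are over-weighted) and is only used for subset comparisons on a
  common sample.
* CA tie-breaking is deterministic (higher potential, then row-major cell
  index); a seeded random tie-break is available. Edge windows are
  truncated, not wrapped.
* Quota rounding uses largest remainders, so integer targets always sum to
  the valid-cell count and allocation is always feasible.
* Kappa banding applies a 1e-9 tolerance at the 0.4 and 0.75 boundaries so
  closed-form boundary cases land in their intended band.

## Landscape metrics conventions

Patches are connected components of like-coded cells (default 8-neighbour).
Class-scale indices: NP, MPS (ha), LPI (largest patch as % of *total*
landscape area), PSCV (population standard deviation of patch areas over
MPS, ×100), DIVISION ($1 - \sum_j (a_{ij}/A)^2$), and AI (4-neighbour
single-count like-adjacencies over the largest-square bound; a single-cell
class, whose bound is zero, reports 0). The landscape scale aggregates NP,
MPS, LPI and PSCV over all patches, takes AI as the class-area-weighted
mean, and adds SHDI $= -\sum_i P_i \ln P_i$. COHESION is deliberately
excluded. Every index is verified against an independent brute-force
oracle (flood-fill patch enumeration, explicit pairwise adjacency counts)
on hundreds of random grids.

## Biocapacity accounting

$BC = \sum_i A_i \cdot YF_i \cdot EQF_i$, with the bundled factor table
covering epochs 2000–2030 (the 2030 factors equal the 2020 ones by
assumption — a choice that likely understates late-horizon biocapacity and
can be overridden by passing a user factor file). Built-up and deserted
land carry $YF = 0$. BC is composition-only by design — rearranging the
same class areas leaves it unchanged — which is precisely why the landscape
metrics are reported alongside it.

## Problem sizes used in the checks

The bundled checks run the full pipeline on 256 × 256 scenarios (Markov
recovery, the ROC/Kappa benchmark over three seeds) and use 64 × 64
scenarios plus 15 × 15 random grids for unit-level properties; these sizes
make the whole suite run in about a minute on one core while leaving the
statistical bounds (binomial recovery error below 0.03, ROC above 0.9)
comfortably testable.

## Known limitations

* Synthetic forward change is drawn independently per cell before spatial
  re-matching, so simulated decades are speckled relative to real
  land-change processes; patch-count and MPS *trends* in the synthetic
  world are directionally meaningful but their magnitudes are not
  calibrated to any real region.
* Suitability is fitted to occurrence at one date, not to change events;
  with slowly changing landscapes the two differ mostly for rapidly
  expanding classes.
* The CA has no per-class persistence or protection constraints (e.g.
  immutable water), no multi-objective allocation, and a uniform
  contiguity kernel.
* Rasters are exchanged as Esri ASCII grids with a JSON sidecar; there is
  no reprojection, and coarser layers are aligned by nearest neighbour
  only.
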