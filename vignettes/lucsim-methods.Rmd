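---
title: "Forecasting categorical land-use change with lucsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting categorical land-use change with lucsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lucsim)
```

## The modelling problem

Land-use/land-cover (LULC) maps classify every cell of a regular grid into a
categorical class (Forest, Building, Glacier, ...).  Given a short series of
observed maps and a stack of environmental predictors, we want maps for future
time-steps that (i) place each class where the landscape is suitable for it,
(ii) honour an explicit *demand* — the number of cells each class should
occupy at each step — and (iii) only realise *allowed* class transitions.
lucsim implements this as four cooperating stages, mirroring the standard
architecture of pattern-based land-change models:

1. **Suitability.**  A multinomial classifier estimates, per cell, a
   probability simplex over the modelled classes for the next time-step.
2. **Demand.**  Per-class target cell counts per step, extrapolated linearly
   from the observed prevalences, with policy overrides.
3. **Transitions.**  A binary matrix per simulation period saying which
   current-to-future class conversions are legal.
4. **Allocation.**  The CLUE-S iteration merges the three into one
   categorical map per step.

A *static* subset of classes (lakes, rivers, transport infrastructure in the
shipped Swiss codebook) is excluded from modelling entirely: those cells never
change and are re-attached unchanged to every output map.

## Suitability model

### Features

For each dynamic cell the feature vector contains the cell's class at the
three most recent time-steps (categorical), the per-class neighbourhood
proportions and the dominant class in a centred square focal window at t0,
and the predictor-stack layers (continuous or categorical).  Two conventions
matter:

* **Window size.**  Focal windows must be odd so they can be centred; a
  5 km neighbourhood at 100 m cells is 50 cells and is therefore discretised
  to 51.  On the 100 x 100 toy landscape the default is `window_cells = 7`
  (700 m), keeping the neighbourhood local relative to the grid.
* **Encoding.**  Continuous features are ranked by the absolute
  point-biserial correlation with the changed-cell indicator, greedily
  filtered so no two retained columns correlate at `|r| >= 0.7`, and
  standardised (mean/sd stored at fit time).  Categorical features are
  one-hot encoded against level sets frozen at fit time; a level first seen
  at projection is an error rather than a silent schema change.  Indicator
  columns bypass both the correlation filter (it is defined for continuous
  variables) and the standardisation (scaling a 0/1 indicator adds nothing).
  The ranking statistic is a transparent stand-in for embedded
  selection procedures whose internals published workflows rarely restate.

### Sampling

Cells that change class are rare (about 5% per step under the default
generator, matching the sparsity of observed national series), so a model
fitted on all cells would learn to predict persistence only.  The training
sample therefore contains *every* changing cell plus an equal-size simple
random sample of non-changing cells.  Within the changing subset, minority
classes are oversampled with SMOTE-NC to the count of the most prevalent
changing class: synthetic rows interpolate continuous features uniformly
along the segment between a seed row and one of its `k = 5` nearest
same-class neighbours, and take the mode of the neighbours' values for
categorical features.  The mixed-type metric is Euclidean on the continuous
features with each categorical mismatch contributing `med^2`, where `med` is
the median of the continuous features' standard deviations.  `k = 5` is the
classical SMOTE setting; augmentation happens before one-hot encoding so
each original categorical variable acts as a single nominal attribute, which
is how the algorithm is defined.  Oversampling is applied only to the
changing subset — the non-changing subset is already balanced by
construction and even its rarest class outnumbers the most prevalent
changing class.

### Engines

Two interchangeable engines satisfy the same contract (features in,
probability simplex over modelled classes out):

* `engine = "mlp"`: a feedforward network with exactly five densely
  connected ReLU hidden layers separated by four dropout layers (rate 0.2)
  and a softmax output, trained with Adam (batch 256, learning rate 1e-3),
  a 0.2 validation split and early stopping on validation loss
  (patience 10, `max_epochs` 200).  Published applications of this
  architecture at national scale do not report hidden widths; the default
  256-128-64-32-16 taper suits a few hundred inputs and is configurable
  down for toys.  Weights use He initialisation; all stochastic elements
  (split, shuffling, dropout) derive from one seed.
* `engine = "multinom"`: multinomial logistic regression via `nnet::multinom`.
  It is fast, deterministic, and on the synthetic landscape it is also
  well-specified, because the generator's transition kernel *is* a
  multinomial logit.  The pipeline default uses this engine; the network is
  exercised by the test suite and available for richer feature sets.

Projection is autoregressive: to predict step t+1 the LULC-derived features
are recomputed from the history (t-2, t-1, t0) — which after the first
forecast step contains previously forecast maps — while time-varying
predictor layers (a climate scenario, say) can be swapped in per step and
all other features stay fixed.

## Demand

Observed per-class prevalences (cell counts over dynamic cells) are
extrapolated by continuing the straight line through the **last two
observed** steps.  Negative projections are clamped at zero and every step
is rescaled proportionally over the unconstrained classes so counts always
sum to the fixed dynamic total, then rounded to whole cells with a
largest-remainder scheme that preserves the total exactly.  Policy
overrides either *freeze* a class (it keeps the value of the last step
before the freeze) or make it *replacement-only* (it may never exceed that
value); the shipped Swiss scenario freezes the four urban classes and
Horticulture from the second forecast step on.  Overrides are idempotent,
and a configuration whose constraints leave no class free to absorb a
residual is rejected as infeasible rather than silently renormalised.

## Transitions

Transition rules are square 0/1 matrices (rows = current class, columns =
future class) with an all-ones diagonal — persistence is always legal.  Two
default matrices encode the baseline Swiss scenario (urban land is never
taken over; urbanisation only from Arable/Grassland and only in period 1;
one-way succession Alpine grassland to Brush/Trees to Forest; one-way
deglaciation Glacier to Bare land to Unproductive vegetation; and so on).
Every rule is asserted one-by-one in the test suite, so the matrices are
machine-checked against their written description.

## CLUE-S allocation

The allocator maintains one additive iteration parameter per class,
`lambda_c`, starting at zero.  Each pass assigns every competing cell to
the class maximising `suitability + lambda_c` *over its allowed
destinations* — a forbidden destination scores `-Inf`, never zero, so no
price can resurrect an illegal transition — then nudges
`lambda_c` by `step * (demanded - allocated) / n_dynamic`.  A class whose
deviation changes sign has its step damped by 0.9, so the prices settle.
This is the classic dual/auction view of the transportation problem: at a
price equilibrium that satisfies demand exactly, the assignment maximises
total suitability subject to the demand constraint.

Numerical choices, all configurable:

* tolerance `max(1, 0.05%)` of the dynamic area; initial step 0.5; damping
  0.9; `max_iter` 1000.  The reference description of the algorithm does
  not print its internal parameters; these defaults hold the demand audit
  comfortably under the 0.2% bound reported for the full-scale workflow.
* Ties are broken deterministically: lowest class id within a cell, fixed
  cell scan order across cells (column-major, the native array order here).
* Cells whose current class forbids every move are pre-assigned and removed
  from the competition; demand feasibility (enough convertible cells per
  class) is checked after this reduction and violations name the class.
* If the price iteration hits `max_iter` above tolerance, a deterministic
  greedy repair moves the cells with the smallest suitability loss from
  over- to under-allocated classes (legal moves only) until demand is met.
  This guarantees termination with exact demand on feasible instances at
  the cost of, in principle, a slightly sub-optimal total suitability; in
  the test suite the iteration converges without repair and matches an
  exhaustive-enumeration oracle on small instances.

After allocation, the post-processing stage can recode model-allocated
Glacier to Bare land and overlay externally supplied glacier/lake masks
(lake wins where they overlap, since new lakes form in deglaciated
terrain), then resolve static aggregate codes to fine-resolution classes.
Because the overlay overrides the allocator for Glacier and Bare land,
those classes are exempted from the demand audit when masks are used.

## The synthetic landscape

The generator is first-class, tested code — it defines the study conditions
for every quantitative claim the package makes about itself.  Defaults:
100 x 100 cells of 100 m, 6 classes with the last one static (laid out as
contiguous low-elevation blobs covering ~8% of the grid), 4 observed steps,
`change_rate = 0.05`.  Predictors are an elevation-like gradient, two
spatially autocorrelated Gaussian fields (box-blurred white noise), and one
categorical region layer (nearest of four random seed points).  Each step,
5% of dynamic cells are redrawn from a multinomial logit whose linear
predictor adds a class intercept (optionally drifting over time; the drift
coefficient is scaled by a gain of 25 so a configured trend of 0.01/step is
visible against redraw noise), per-class effects on the continuous
predictors, and a coefficient (default 3) on the same-class focal
proportion; redrawn cells always change class, so the realized changed
fraction is binomial around `change_rate`.  The generator reproduces the
statistical structure that matters downstream — rare changes, imbalanced
classes, spatial autocorrelation, a static mask, a recoverable suitability
signal — and deliberately not real geography, real predictor sets, or
climate fields; tests passing on it demonstrate algorithmic correctness,
not real-world forecast skill.

## Validation statistics

Map agreement is summarised by overall accuracy with a normal-approximation
confidence interval (Wilson by flag; the normal form matches the symmetric
intervals usually printed), the quantity/allocation decomposition of
disagreement (`Q + A = 1 - OA` exactly, a property the suite verifies on
random matrices), and one-vs-rest sensitivity, specificity and balanced
accuracy per class.  A class absent from the reference yields an undefined
(`NA`) sensitivity, excluded from averages with a warning — never a
silent zero.  Presentation rounding is half-away-from-zero and applied only
at print time.  The demand audit reports, per class and step, the obtained
minus the requested prevalence change relative to a baseline map, as a
fraction of the dynamic area.

## Worked example

```{r example, eval = FALSE}
land <- generate_landscape(landscape_config())
model <- train_suitability(land$maps, land$stack, land$codebook,
                           model_spec(engine = "multinom", seed = 1),
                           seed = 1)

obs <- t(sapply(land$maps, observed_prevalence))
sched <- extrapolate_demand(obs, n_future = 3)
ids <- modelled_ids(land$codebook)
rules <- transition_matrix(matrix(1L, length(ids), length(ids),
                                  dimnames = list(ids, ids)), "all")

fc <- run_forecast(model, land$maps[2:4], land$stack, sched, rules)
demand_audit(land$maps[[1]], sched, fc$maps)
```

## Problem sizes and design notes

* The suite and the examples run on the 100 x 100 default landscape (9200
  dynamic cells) with the `multinom` engine and a toy five-layer network;
  at these sizes generation takes well under a second, training seconds,
  and a full three-step forecast a few seconds on one CPU.  All sizes are
  configuration, not code.
* Rasters are read and written as ESRI ASCII grids (plain text,
  georeferenced header, `.prj` sidecar for the CRS id) plus the
  point-grid CSV dialect used by national statistics series; integer codes
  round-trip losslessly and grids are never resampled silently.
* The package keeps the classic modelling idiom where it fits — the
  suitability model is a fitting function returning a classed object with
  `predict`/`print`/`summary` methods — while the surrounding stages are
  plain functions, because a four-stage pipeline is not one estimator.
* Known limitations: demand extrapolation is linear by design; the
  allocator has no per-class elasticities or conversion costs (variants of
  CLUE-S have them, the baseline description does not); multiple
  simultaneous policy overrides are applied sequentially, so a later
  override can redistribute into classes constrained by an earlier one
  within the same step.
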