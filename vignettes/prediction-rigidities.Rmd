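---
title: "Prediction rigidities: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prediction rigidities: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the mathematical conventions, the rationale behind the
synthetic-system designs, and the deliberate engineering choices in `rigidr`.
It is a methods document: the code chunks illustrate usage but are not
evaluated at build time.

## 1. Model and loss convention

`rigidr` works with models whose prediction is linear in a readout weight
vector `w` of dimension `d`. A *structure* is a collection of *environments*;
the global prediction is the sum of per-environment readouts, so the gradient
of a global target with respect to `w` is the sum of the environment feature
rows. Force-style targets contribute one row per Cartesian coordinate,
`-sum_j d f_j / d x_alpha`. Targets of any provenance — including last-layer
gradients extracted from a deep network — enter uniformly as `target_row`
objects: a gradient vector `g`, a loss weight `lambda`, a kind tag, and an
optional observed value.

The loss convention is fixed throughout the package as

$$ L(w) \;=\; \sum_i \lambda_i\,(g_i\!\cdot\!w - y_i)^2 \;+\; \sigma^2 |w|^2 $$

with **no global factor of 1/2**. Two identities then hold *exactly*, and the
test suite enforces them at tolerances of 1e-9 or tighter:

1. the curvature of the loss is `H = sum_i lambda_i g_i g_i^T + sigma^2 I`,
   so the minimum loss subject to a prediction with gradient `g_star` being
   displaced by `delta` rises by `R * delta^2` with
   `R = 1 / (g_star^T H^{-1} g_star)`;
2. adding a training row equal to `g_star` itself with weight `lambda`
   raises `R(g_star)` by exactly `lambda` (a one-line consequence of the
   Sherman–Morrison formula).

Had the conventional `1/2` prefactor been used, both statements would carry
factor-of-two clutter; fixing the convention once keeps every identity clean
and exactly testable.

The rigidity family differs only in the query vector:

| Quantity | Query `g_star` | Question answered |
| --- | --- | --- |
| PR  | summed feature row of a structure | how firmly is this *global* prediction pinned down? |
| LPR | one environment's feature row | how firmly is this *local* contribution pinned down, given that only sums of local terms are ever observed? |
| CPR | global row masked to one column block | how firmly is the *partition* across additive components (body orders, range channels) pinned down? |

`1/R` is the predictive variance of the Gaussian posterior
`N(w_hat, sigma_n^2 H^{-1})` of a Bayesian ridge regression, which is why
rigidities act as an ensemble-free uncertainty measure; `variance_from_pr()`
applies the calibration constant.

## 2. Numerical core

`build_hessian()` assembles `H` and caches a solve handle: a Cholesky factor
when `H` is positive definite, otherwise an eigenvalue-clipped pseudo-solve.
The singular branch is deliberate, not defensive: component-wise diagnostics
*routinely* operate on rank-deficient curvature (that degeneracy is the
phenomenon being measured), and a query with a component outside the data
span has no finite answer at `ridge = 0` — the solver raises an error
advising a positive ridge rather than fabricating a number.

`rank_one_update()` refactors after each committed row, which is
definitionally identical to rebuilding from the concatenated row list (a
property test asserts this). Hypothetical what-if scores — `pr_gain()`,
`lpr_enhancement()`, and each candidate evaluation inside `greedy_augment()`
— never mutate the state: they use the Woodbury identity against the cached
factorization, so scoring a pool of `m` candidates costs `m` small solves,
not `m` refactorizations.

`greedy_augment()` breaks objective ties by the lexicographically lowest
candidate id, making selection traces fully deterministic.

## 3. Synthetic systems: what each one is for

All generators are seed-deterministic (identical bytes for identical seeds)
and emulate the *structure* of atomistic datasets — blocks, scales,
degeneracies — not their chemistry. Default sizes are desk-scale: tens to
hundreds of structures, feature dimensions of 10–32, so the full acceptance
suite runs in well under a minute per experiment.

### 3.1 Anisotropic linear system (`gen_linear_system`)

Column variances decay geometrically (`condition` ratio end to end) and each
environment carries a log-normal scale factor. This produces the realistic
situation of common, well-covered feature directions alongside rare ones,
giving LPR distributions with genuine spread — a flat isotropic Gaussian
would make every uncertainty diagnostic trivially uniform.
`committee_variances()` (10 disjoint folds by default, bootstrap optional)
anticorrelates strongly with LPR on this system; the acceptance suite
requires Spearman ≤ −0.8 and posterior-sampling calibration within 5%.

### 3.2 Two-domain augmentation task (`gen_two_domain`)

Emulates extending a model trained on one structural family (domain A) to
another (domain B). The design went through deliberate iterations, and the
final mechanism matters:

* In domain A the last feature channel is *exactly collinear* with the first
  (`f_d = alpha * f_1` per environment) — the way a density-like channel is
  slaved to coordination inside a single bulk phase. The fit therefore cannot
  split the two weights, and its estimate along the unidentified direction is
  fixed by regularization alone: a **deterministic O(1) bias** on domain-B
  predictions, independent of the noise realization.
* An earlier "weak coverage" variant (a tiny-but-nonzero feature scale) made
  the baseline error a noise draw instead: on a sizeable fraction of seeds
  the weak rows luckily estimated the deficit weight and greedy-vs-random
  comparisons degenerated to coin flips at the noise floor. Collinearity
  removes this failure mode structurally, rather than by tuning noise levels.
* The candidate pool mirrors a realistic augmentation round: a majority of
  bulk-like candidates (mixing parameter below 0.05, still collinear, useless
  for the targets) and a minority (`useful_frac`, default 15%) from the
  target-like regime. The deficit channel's true weight has magnitude drawn
  in `[1, 2]`, keeping the unresolved bias well above the noise floor.

On this task, greedy rigidity-guided selection finds the informative minority
immediately, and beats the mean of random selections at *every* budget.

### 3.3 Body-ordered blocks (`gen_body_ordered`)

Emulates body-ordered descriptors: four blocks, one per correlation order.
A sample of class `c` has a latent geometry `u`; in the orthogonalized
("purified") basis its block `nu` is a fixed class-level orthogonal map of
`u` for `nu <= c` and exactly zero above. Training on the highest class alone
leaves the energy partition across blocks degenerate — CPR of the first block
sits at the ridge floor — while adding pure pair samples resolves it.

With `overlap_kappa > 0` the features are expressed in a *self-interacting*
basis: block `nu` additionally receives `kappa * nu` times fixed orthogonal
mixes of all lower blocks. The multiplicity factor `nu` encodes that the
number of spurious terms re-counting an atom grows with the body order;
without it, the leakage was too weak to reproduce the qualitative phenomenon
(pairs still isolated block 1 reasonably well at `kappa = 0.5`). Energies are
always computed from the *purified* features — the physics does not depend on
the descriptor basis — so the two bases describe identical systems and differ
only in what a fit can disentangle.

### 3.4 Two length scales (`gen_two_scale`)

Emulates range-separated models: a short-range block encoding each unit's few
internal degrees of freedom and a long-range block carrying an interaction
decaying as `(r_min / r)^p`. With `separated = FALSE` the LR block
*double-counts* the SR content (a second fixed encoding of the internal
geometry), making the SR/LR energy partition degenerate. For held-out monomer
analogues the leaked encoding is evaluated under a perturbed map
(`eval_shift`), emulating the cell dependence of reciprocal-space evaluation:
whatever share of internal energy the fit assigned to the LR weights fails to
transfer, so the monomer error stalls no matter how many dimers are added.
`two_scale_learning_curve()` averages over four replicate systems because a
single seed's RMSE-vs-size curve is not strictly monotone at desk scale; the
replicate average reports the generator-class trend, which is the claim under
test.

### 3.5 Toy clusters and descriptor (`gen_toy_clusters`, `radial_descriptor`)

Small random clusters with a minimum-distance constraint and a smooth
Gaussian radial-basis descriptor with analytic Cartesian gradients. These
exercise the full force-row pipeline end to end; tests check the analytic
gradients against central finite differences and the descriptor's translation
invariance and smoothness at the cutoff.

## 4. Files, CLI and indexing

* **Feature containers** are plain-text directory bundles: `features.csv`,
  `envmap.csv`, `blocks.csv`, `gradients.csv` (long-format nonzeros),
  `targets.csv`, `meta.json`. Numerics are written with 17 significant
  digits, so write → read → write reproduces identical bytes; the format
  version is checked on read and missing datasets are named in errors. A
  plain-text bundle was chosen over a binary container so artifacts diff
  cleanly and round-trip exactness is testable at the byte level with no
  further dependencies.
* **Indexing** is 0-based *on disk* (single machine-checked convention,
  recorded in `meta.json`) and 1-based *in the R API* (anything else fights
  the language); conversion happens exactly once, in the reader/writer pair.
* **Configuration** files are flat `key = value` lines with `#` comments — a
  deliberately minimal subset of the common plain-text config dialects,
  parsed in a dozen lines. Explicit CLI flags always override the config.
* The **CLI** (`pr_cli()`, launcher in `inst/scripts/rigidr`) is the
  integration surface for models trained elsewhere: export last-layer
  features into a container, then `compute`, `rank`, `augment` or `monitor`
  without writing R. Every run logs its parameters, seed and format version
  to standard error, and errors exit nonzero with a single-line diagnostic.

## 5. Limitations

* Rigidities are curvature statements about a *linear readout*. For deep
  models they inherit the usual last-layer/Laplace approximation caveats:
  feature-space drift under retraining is not captured.
* `1/R` is a *relative* variance; absolute uncertainties require a
  calibration constant (`variance_from_pr(R, scale)`), typically fitted on a
  validation set.
* Dense linear algebra throughout: the implementation targets `d` up to a few
  thousand, not sparse million-parameter Hessians.
* The synthetic generators reproduce structural phenomena (degeneracy,
  leakage, domain shift), not chemistry; none of their energies mean anything
  physically.

## 6. Reproducibility contract

Every stochastic entry point takes an explicit `seed` and produces
bit-identical output for identical inputs; `scripts/acceptance.R` derives all
of its randomness from `--seed` and writes its measurements as JSON. The
acceptance tests in `tests/testthat/test-acceptance.R` state their tolerances
inline; each was fixed from the corresponding exact identity or from an a
priori operationalization of the qualitative claim, never fitted to observed
outcomes.
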