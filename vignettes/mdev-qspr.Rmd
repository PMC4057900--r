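---
title: "Distance-edge topology and the octanol/air partitioning of PBDEs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-edge topology and the octanol/air partitioning of PBDEs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdevqspr)
```

This vignette is the package's account of its science: what is modeled,
which conventions and parameters matter, where the design was genuinely
open and what was decided, and what the tests do and do not demonstrate.

## The molecular graph and its conventions

A PBDE congener is two phenyl rings joined by an ether bridge, with 1–10
bromines on ring positions 2–6 and 2′–6′ (position 1/1′ is the ipso
carbon carrying the bridge and is never substituted). `build_skeleton()`
represents the molecule as a purely topological graph: vertices are
heavy atoms, edges are bonds of unit length, and distances are
shortest-path bond counts from breadth-first search. Two conventions
deserve comment.

**Ether oxygen contraction.** The bridging oxygen is not a vertex; the
two ipso carbons are joined directly. This choice is forced by the
descriptor values the calibration dataset is built on: with the oxygen
contracted the Br(2)–Br(2′) distance in the 2,2′,4,4′ congener is 5
bonds and every tabulated descriptor value reproduces; with an explicit
oxygen vertex that distance would be 6 and none of the polybrominated
rows would match. The package validates this at load time —
`pbde_koa_dataset()` recomputes all 44 stored descriptor values from the
substitution patterns and refuses to return if any disagrees at 4
decimals.

**Canonical congener form.** The molecule is invariant under swapping
the rings and under each ring's mirror (2 ↔ 6, 3 ↔ 5). `congener_spec()`
therefore mirror-normalizes each ring to its lowest-locant tuple and
orders the rings lexicographically, so all eight symmetry images of a
substitution pattern collapse to one canonical object with one name.
The descriptor itself is symmetry-invariant (tested over random specs),
so canonicalization only matters for naming and deduplication.

## The MDEV descriptor

With bromine atoms as feature type 1 and benzene rings as type 2 (unit
relative electronegativity for both), the index element is the sum of
reciprocal squared distances over unordered pairs of distinct features:

$$M_{kl} = \sum_{(i,j)}\; \frac{1}{d_{ij}^2}$$

* `mu1` (M11): all $n(n-1)/2$ bromine pairs. Zero when fewer than two
  bromines — self-pairs are excluded (they would divide by zero, and the
  tabulated monobromo rows have μ1 = 0).
* `mu2` (M12): all $2n$ (bromine, ring) pairs, the distance being to the
  *nearest carbon* of the target ring: 1 for the bromine's own ring,
  2 + cycle-distance(position, ipso) for the far ring. This is the only
  reading that reproduces the tabulated values (e.g. μ2 = 1.0625 for the
  3-monobromo congener needs a far-ring distance of 4).
* `mu3` (M22): the single ring–ring term, identically 1 for every PBDE
  because the contracted ipso carbons are adjacent. It is computed for
  completeness but excluded from all modeling, since a constant carries
  no structural information.

One published worked expansion of μ2 for the 2,2′,4,4′ congener contains
two `1/4²` terms where the geometry (and the printed total, 4.3022)
requires `1/5²`; the implementation follows the value, and the oracle
tests (a naive double loop over a Floyd–Warshall distance matrix)
confirm the graph-derived sums.

## The calibration models

**MLR.** `fit_mlr()` solves ordinary least squares of experimental
lgK_OA on (μ1, μ2) with intercept, via QR decomposition. Diagnostics
follow the classical conventions: multiple correlation
$R = \sqrt{SS_{reg}/SS_{tot}}$, standard error of the estimate
$\sqrt{SS_{res}/(n-3)}$, and $F = (SS_{reg}/2)/(SS_{res}/(n-3))$ on
(2, n−3) degrees of freedom — the conventions under which the packaged
calibration reproduces its published diagnostic triple. Degenerate
inputs fail early with classed errors: fewer than 4 records
(`sample_size_error`) or a rank-deficient design
(`singular_design_error`).

The packaged dataset stores descriptors at the tabulated 4-decimal
precision, and the calibration is run on those values. This is
deliberate: the original calibration was evidently computed on the
rounded table (it reproduces the printed μ1 coefficient −0.7598 and
F = 202.46 exactly; full-precision descriptors shift the μ1 coefficient
to −0.7593). User data read through `read_qspr_dataset()` gets
full-precision descriptors computed on the fly — the differences are in
the third decimal of predictions.

**Sign convention.** The calibration equation is reported here as
`lgK_OA = −0.7598 μ1 + 0.9883 μ2 + 6.3470`; these are the signs the
least-squares refit produces, and the only signs under which the
external predictions (e.g. 12.22 for the hexabromo congener) are
reproducible.

**L-ANN.** `train_lann()` implements a linear network — two inputs, one
output neuron, identity activation, so the forward pass on z-scored
variables is the affine post-synaptic potential
$v = \sum_i x_i w_i + b$. Training is one-shot pseudo-inverse: the
calibration records are split (seeded) into training and verification
sets, the training design `[X, 1]` is factored by SVD, and candidate
weight vectors are formed at truncation ranks full, full−1, …, 1. The
verification set picks the candidate with the smallest RMSE, ties going
to the larger rank.

Two design questions were genuinely open here:

* *Early stopping.* A one-shot pseudo-inverse solve has no iterations to
  stop, yet the training protocol calls for a verification set that
  "identifies the best network". The package realizes that role as model
  selection over SVD truncation ranks — the natural one-parameter family
  of networks between the trivial and the full least-squares solution.
  On well-conditioned data the full-rank candidate wins and the network
  is exactly OLS (asserted to 1e−8 in the tests with the split
  disabled). On the study data, where μ1 and μ2 are strongly collinear
  and the verification set has only 3 points, truncated candidates win
  for some seeds; seed-to-seed LOO RMSRE then fluctuates a few tenths of
  a percent around the MLR value, which is why reported summary
  statistics for the network are anchored to the deterministic full-rank
  solution (`verification_fraction = 0`) or to the stored per-sample
  table rather than to any particular split.
* *Normalization.* Variables are z-scored per column. At the
  least-squares optimum the de-normalized predictor is invariant to any
  affine normalization, so the choice is cosmetic; z-scoring keeps the
  SVD well-scaled. A constant descriptor column cannot be z-scored and
  raises `singular_design_error`.

The architecture is linear throughout; no radial basis functions are
involved.

## Validation statistics

Errors are signed percents, `RE = 100 (pred − exp)/exp`, and
`RMSRE = sqrt(mean(RE²))` stays on the percent scale. `loo_cv()` refits
on n−1 records per fold — with the MLR modeler this is fully
deterministic and equals the closed-form leverage shortcut
$\hat y_{(i)} = (\hat y_i - h_i y_i)/(1 - h_i)$ (asserted to 1e−10);
with the lann modeler each fold draws a fresh seeded train/verification
split, the fold index offsetting the base seed so runs are reproducible.
The default `verification_fraction = 0.2` reproduces a 12/3 split of a
15-record fold. `external_validation()` fits once on a calibration set
and evaluates on a disjoint test set (overlap is a `protocol_error`).
`pred_vs_exp_line()` reports the least-squares line of predicted on
experimental plus the Pearson correlation; with fewer than 3 points or a
constant response the line is undefined and reports are filled with NA.

One internal inconsistency of the source tables is worth knowing: the
stored external MLR predictions for the test group differ slightly from
direct application of the calibration equation (largest gap ≈ 0.1 log
units for the 2,4,6 congener), so the RMSRE recomputed from the stored
relative-error column (2.95) differs from a fresh fit-and-predict
(2.68). Both computations are exposed — `rmsre(d$re_mlr_reported[...])`
for the former, `external_validation()` for the latter — and the
`reproduce` CLI subcommand prints both.

## The synthetic generator

`simulate_qspr_dataset()` emulates the statistical structure the
calibration assumes: congeners drawn uniformly-ish (each position
brominated independently with probability ½, empty draws rejected,
canonicalized), responses
`lgkoa = c1 μ1 + c2 μ2 + intercept + N(0, σ)`. Defaults are the study
conditions: n = 22 records, generating coefficients (−0.7598, 0.9883,
6.3470) and σ = 0.234 — the calibration's own coefficient vector and
residual scale.

What the generator does *not* emulate: correlated measurement error
across congeners, curvature or bromination-pattern effects beyond the
plane, the specific descriptor distribution of the 22 study congeners
(random draws lean toward heavier bromination than the study set), or
any temperature dependence of K_OA. Passing parameter-recovery tests
therefore shows that the estimation machinery is correct under the
model's own assumptions — not that the linear model is an adequate
description of real partitioning data.

Test problem sizes were chosen to keep the full suite in tens of
seconds while leaving Monte-Carlo margins comfortable: 200 random
congeners for the distance-oracle sweep, 200–500 replicates at n = 16–50
for coverage, bias and residual-scale checks, and n = 16, 50, 200 for
the consistency ladder.

## Known limitations

* Scope is exactly the PBDE skeleton (plus the unsubstituted diphenyl
  ether); there is no general molecule parser, no SMILES/InChI, no 3-D
  geometry, and the descriptor definition here is not a general MDEV
  implementation for arbitrary molecules.
* The calibration rests on 16 experimental values spanning mono- to
  hexabromination; predictions for hepta- through deca-congeners are
  extrapolations beyond the calibration domain, and no applicability
  domain analysis is provided.
* Experimental lgK_OA values are used at their printed 2–3 significant
  figures; no re-derivation from primary sources or temperature
  correction is attempted.
* μ1 and μ2 are strongly collinear on realistic congener sets, so
  individual coefficients are much less stable than predictions — a
  caveat for any mechanistic reading of the coefficient signs.
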