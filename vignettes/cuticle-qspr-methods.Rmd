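---
title: "QSPR modeling of plant cuticle-air partitioning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSPR modeling of plant cuticle-air partitioning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The plant cuticle is the waxy outer membrane through which airborne organic
pollutants enter vegetation, and the cuticle-air partition coefficient
$K_{ca}$ — the equilibrium concentration ratio of a compound between
isolated cuticle membrane and air — quantifies a plant's capacity to take
those pollutants up. Measured $\log K_{ca}$ values are scarce: compilations
hold a few hundred measurements spanning on the order of a hundred
compounds and a couple of dozen plant species, with each compound measured
in anywhere from one to five species/tissue combinations. This package
implements a quantitative structure-property relationship (QSPR) workflow
that regresses $\log K_{ca}$ on a small set of 2D molecular descriptors, so
that the coefficient can be estimated for compounds that have never been
measured, together with the validation battery, applicability-domain
delimitation and attribution analysis that make such a model defensible.

Where a compound's $K_{ca}$ has not been measured directly but its
cuticle-water and air-water coefficients have, the identity
$\log K_{ca} = \log K_{cw} - \log K_{aw}$ supplies it
(`derive_log_kca()`).

Two dataset layouts are supported, mirroring how measured compilations are
used in practice: a replicate-level table (one row per
compound-species-tissue measurement) and a compound-level table obtained by
averaging the replicates (`average_by_compound()`). The replicate-level
layout contains near-duplicate rows for the same compound, and a random or
rank-based split will place some of them on both sides of the
train/test divide; that leakage is a documented property of
replicate-level modeling, not a bug, and `y_ranking_split(group_by_compound
= TRUE)` is available when it must be prevented.

## The descriptors

Six descriptors are computed from the hydrogen-depleted heavy-atom graph of
a SMILES string (`parse_smiles()`, backed by OpenBabel for parsing and
aromaticity perception). All are 2D — no geometry optimization is needed.

* **`VE1_L`** — the sum of absolute coefficients of the eigenvector
  belonging to the largest eigenvalue of the graph Laplacian $L = D - A$.
  "Last eigenvector" descriptors of this family index eigenvalues in
  ascending order, so the last is the largest; the package follows that
  convention by default and offers the smallest-nonzero (Fiedler)
  alternative behind a flag, since both conventions circulate. When the
  selected eigenvalue is numerically degenerate the eigenvector is chosen
  deterministically (candidates sign-canonicalized, sorted
  lexicographically, last taken) — reproducibility is preferred over any
  claim that one eigenvector of a degenerate pair is canonical.
* **`SpPos_A`** — the sum of positive adjacency eigenvalues, a
  size-and-branching measure. For bipartite graphs it equals half the graph
  energy, which the test suite exploits as an independent identity.
* **`SpMax2_Bh(v)`** — the second-largest eigenvalue of the Burden matrix
  weighted by carbon-normalized van der Waals volume. The Burden
  construction uses the published convention: property weights on the
  diagonal, $0.1 \times$ bond order (aromatic $= 1.5$) on bonded
  off-diagonals, $+0.01$ when either endpoint is terminal, $0.001$
  elsewhere. The constants are exposed as arguments because descriptor
  vendors differ in the third decimal of these conventions.
* **`H_Dz(p)`** — a Harary-type index (half-sum of reciprocal distances)
  over the Barysz distance matrix weighted by carbon-normalized atomic
  polarizability: each bond $(i,j)$ with order $\pi$ has length
  $w_C^2 / (\pi\, w_i w_j)$, off-diagonal entries are weighted
  shortest-path lengths, and the diagonal is $1 - w_C / w_i$. On an
  all-carbon single-bond skeleton this collapses to the classical Harary
  index, another identity the tests pin.
* **`LLS_01` / `LLS_02`** — lead-likeness scores: the fraction of
  drug-discovery property rules a molecule satisfies, using a 6-rule
  rule-of-three style set and an 8-rule extended lead-like set
  respectively. The primary literature fixes the *number* of rules and the
  fraction arithmetic but not every numeric threshold at reproducible
  precision, so all bounds live in an overridable config
  (`lls_rulesets()`); the tests pin only the $m/k$ arithmetic and the
  monotone violations-lower-score behavior. The logP needed by two rules is
  OpenBabel's atom-contribution estimate, recorded in the property metadata
  because estimator choice moves compounds near thresholds.

The atomic property table (`atom_properties()`, polarizabilities and Bondi
van der Waals volumes from standard compilations, carbon-normalized) ships
with the package and is never fetched at runtime, so descriptor values are
bit-reproducible. Exact numerical parity with any specific commercial
descriptor engine is *not* claimed: conventions such as near-constant
thresholds and eigenvector ordering are under-documented there, and parity
is asserted only where closed forms exist.

## Dataset QC and splitting

`pauta_check()` applies the 3-sigma screen (sample SD, $n-1$ denominator)
used to quality-check measured compilations. `y_ranking_split()` implements
a response-ranked split: records are sorted by $\log K_{ca}$, the ranking
is cut into $n_{test}$ consecutive blocks of near-equal size, and one
record per block is drawn into the test set. A rank-based description in
terms of fixed-size blocks of five only works when $n_{test} = n/5$
exactly; the near-equal-block formulation generalizes it while reproducing
the canonical splits exactly (255 records split 204/51; 106 compounds split
84/22, since $n_{test} = n - \lfloor 0.8 n \rfloor$). The global minimum
and maximum records are excluded from test candidacy so the test set
interpolates the training response range — the standard rationale for
rank-based splitting. Ties are broken by compound identifier and the
within-block draws are seeded, so the split is byte-reproducible.

## Model building

`prefilter_descriptors()` performs the standard two-step pool reduction:
drop missing/constant/near-constant columns (modal share $> 0.95$), then
greedily remove one member of every pair with $|r| > 0.9$, keeping the
member more correlated with the response and scanning in decreasing
response-correlation order so the procedure is deterministic.

`stepwise_mlr()` is forward stepwise OLS with backward elimination, the
procedure behind classical QSPR equations: entry at $p < 0.05$, removal at
$p > 0.10$ (the common stepwise defaults, both exposed), a hard cap of four
descriptors, and a collinearity gate that rejects any step pushing a
variance inflation factor to 10 or beyond. `fit_mlr()` solves least squares
by QR; `vif()` reports $1/(1-R_j^2)$ with perfect collinearity reported as
`Inf` rather than an exception.

Two literature coefficient sets are available as presets
(`mlr_preset()`): a replicate-level equation over `VE1_L`, `LLS_02`,
`H_Dz(p)`, `SpMax2_Bh(v)` and a compound-averaged equation over `SpPos_A`,
`LLS_02`, `LLS_01`, `SpMax2_Bh(v)`. They serve as generating models for the
synthetic data and as regression targets in the tests: refitting OLS on
noiseless responses generated from either preset recovers its printed
coefficients to below $10^{-6}$ relative error.

`fit_learner()` adds three nonlinear learners behind one contract:
distance-weighted k-nearest-neighbor regression on standardized
descriptors, stagewise least-squares gradient boosting over depth-limited
`rpart` trees (fit tree to residuals, shrink by the learning rate — the
per-stage training MSE is therefore non-increasing, which the tests assert
stage by stage), and a single-hidden-layer `nnet` regressor on standardized
inputs and response. Hyperparameters are chosen by exhaustive grid search
under seeded 5-fold cross-validation. The CV score is the mean fold
$R^2$ by default with RMSE selectable — the choice is configurable
precisely because published workflows rarely state it. Standardization
parameters are learned on training folds only; trees are not standardized
(scale-equivariant). Published workflows likewise rarely print their full
hyperparameter grids, so the shipped default grids
(`default_grid()`) are modest, documented choices: KNN $k \in 1..15$, GBDT
trees $\in \{50,100,200,500\}$ × depth $2..5$ × learning rate
$\{0.05,0.1,0.2\}$, MLP width $\{4,8,16\}$ × decay
$\{10^{-4},10^{-3},10^{-2}\}$.

## Validation battery

`fit_metrics()` reports $R^2$ (squared Pearson correlation of observed and
fitted), $R^2_{adj}$, RMSE, MAE and the standard error of estimate $s$.
`q2_loo()` is the literal leave-one-out loop for any learner, with the
exact PRESS shortcut $e_i/(1-h_{ii})$ available for OLS — the two routes
agree to $10^{-10}$ and are kept as mutual oracles in the tests.
`q2_boot()` follows the 1/5-holdout bootstrap scheme: each iteration holds
out a random fifth of distinct points, refits on a bootstrap resample of
size $n$ drawn from the remainder, and predicts the holdout; predictive
residual and total sums of squares are pooled across iterations
(`1 - sum(PRESS)/sum(TSS)`), a choice documented here because the scheme's
name fixes only the resampling, not the aggregation. The reference
iteration count is 5000; tests and quick runs reduce it, which changes only
Monte-Carlo error.

`external_metrics()` computes $R^2_{ext}$, the external explained variance
$Q^2_{ext}$, and Lin's concordance correlation coefficient
$CCC = 2\,\mathrm{cov}(y,\hat y) / (\sigma_y^2 + \sigma_{\hat y}^2 +
(\bar y - \bar{\hat y})^2)$ with $n$-denominator moments. $Q^2_{ext}$
defaults to the classical F1 form (residuals scaled by deviations from the
*training* mean), with F2 and F3 selectable; which variant a given
published table used is often unrecoverable, so the choice is explicit
rather than silent. The admission thresholds
($R^2_{adj} > 0.7$, $Q^2_{LOO} > 0.6$, $Q^2_{BOOT} > 0.6$,
$R^2_{ext} > 0.7$, $Q^2_{ext} > 0.6$, $CCC > 0.85$) are encoded in
`validation_thresholds()` and applied by `check_thresholds()`, which
recomputes verdicts from the stored values every time rather than caching
them.

## Applicability domain

`applicability_domain()` builds the Williams table: leverage
$h = x'(X'X)^{-1}x$ on the intercept-augmented training descriptor matrix,
warning threshold $h^* = 3(p+1)/n$, standardized residual
$\delta = e / s$. The residual normalization divides by the training
standard error of estimate; a leverage-studentized option exists because
"normalized residual" is used both ways in the QSAR literature. Points
classify as in-domain, good-high-leverage ($h > h^*$, $|\delta| \le 3$ —
structurally unusual but well predicted), response outliers
($|\delta| > 3$), or structural outliers (both). For nonlinear learners
the leverage is still computed on the descriptor design matrix: it is a
property of where a query sits in descriptor space, not of the fitted
function, which mirrors standard QSAR practice. Training leverages sum to
$p + 1$ (hat-matrix trace), an identity the tests check.

## Shapley attribution

With only four descriptors per model, Shapley values need no approximation:
`exact_shap()` enumerates all $2^p$ coalitions with the interventional
(marginal) value function — coalition members fixed at the query's values,
the rest drawn from a background set, predictions averaged — which is also
what the widely used tree-model tooling computes by default. The background
defaults to the full training set, capped at 500 rows by seeded
subsampling. Efficiency ($\text{baseline} + \sum_j \phi_j =
\text{prediction}$), the dummy axiom and symmetry are all asserted in the
tests; for linear models the attributions equal the closed form
$\beta_j (x_j - \bar x_j^{bg})$ to $10^{-8}$. `shap_summary()` ranks
descriptors by mean $|\phi|$ (the summary-plot ordering) and labels the
sign of association by the Spearman correlation between descriptor value
and attribution, with $|\rho| \le 0.3$ reported as indeterminate rather
than forced into a sign.

## Synthetic data: what it emulates, and what it does not

`generate_kca_dataset()` reproduces the *statistical shape* of measured
$K_{ca}$ compilations: 106 compounds, replicate counts in 1..5 allocated
to hit 255 records, up to 25 exchangeable pseudo-species labels, three
tissue types. Responses come from a generating preset equation plus two
noise terms: compound-level lack-of-fit ($\sigma_{between} = 0.8$ log
units) and replicate scatter ($\sigma_{noise} = 0.3$ log units). The
descriptor marginals (parametric mode) and this noise budget were chosen
once so that the generated response distribution lands near the measured
scale (mean $\approx 6.3$, SD $\approx 3.1$ log units) and the generating
equation's fit quality lands in the $R^2_{adj} \approx 0.87$–$0.93$ band
reported for such models; the replicate SD is an assumption, since
compilations print only examples of cross-species spread, not a pooled
estimate. Fixture mode instead computes real descriptors for a shipped
library of 132 structures spanning the compound classes that dominate
measured $K_{ca}$ data (chlorobenzenes, PCB-like biphenyls, PAHs, alkanes,
alcohols, esters, phenols, halogenated aliphatics).

What passing tests on synthetic data show: the pipeline's arithmetic,
determinism, resampling statistics and recovery behavior are correct under
a known truth. What they do not show: that any particular fitted model
predicts *real* $K_{ca}$ well — the synthetic generator has linear truth
plus Gaussian noise, no measurement-method effects, no systematic
cross-species structure, and descriptor distributions only approximating
real chemical space. Claims about real-data performance require the real
measured table.

## Numerical choices and degenerate inputs

* Eigendecompositions use the dense symmetric solver; tests require
  agreement with an independently constructed dense oracle to $10^{-10}$.
* Single-atom graphs: `VE1_L` errors (no spanning structure), `SpPos_A`
  returns 0, `H_Dz(p)` returns 0 (empty off-diagonal sum).
* Multi-fragment SMILES are rejected outright — every descriptor here
  assumes a connected graph.
* Zero response variance errors in $R^2$-type metrics; zero-variance
  predictions score $R^2 = 0$ in CV rather than propagating `NA`.
* Perfect collinearity: `vif()` reports `Inf`; `fit_mlr()` errors naming a
  dependent column; the stepwise entry step treats a rank-deficient trial
  as inadmissible.
* All randomness (splits, CV folds, bootstrap, learner initialization,
  background subsampling) flows from explicit integer seeds; reruns are
  file-identical, which the pipeline tests check byte for byte.

## Problem sizes used in the shipped checks

The test suite and the reproduction script run at deliberately small
scale, chosen as the smallest sizes at which each property is
unambiguous: 100-row descriptor tables for coefficient recovery, 30-point
fixtures for LOO oracle equivalence, 200 points and 200 iterations for the
bootstrap's signal-share check, 50 seeded repetitions for stepwise
recovery, and a 60-compound synthetic study for the end-to-end pipeline.
The full-scale defaults (5000 bootstrap iterations, the complete grids)
remain available through the ordinary arguments.

## Known limitations

* OpenBabel's aromaticity perception and logP estimate define those inputs;
  other toolkits will differ slightly, and lead-like scores can move by one
  rule near thresholds.
* Formal-charge handling is minimal (read from bracket atoms); the target
  chemical space is neutral organic pollutants.
* No y-scrambling/randomization test is included, and KernelSHAP-style
  sampling for large descriptor sets is deliberately out of scope
  (enumeration is exact at $p \le 12$).
* The package does not attempt numerical parity with commercial descriptor
  software beyond the closed-form anchors described above.
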