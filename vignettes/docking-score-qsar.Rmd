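---
title: "Docking-score QSAR: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Docking-score QSAR: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsqsar)
```

## The model and its assumptions

A protein pocket can be abstracted as an arrangement of interaction features
(hydrogen-bond donors/acceptors, hydrophobic and charged sites — a
pharmacophore), and the binding free energy of a compound decomposes
approximately into a sum of feature–feature interaction terms.  If a panel of
unrelated protein pockets spans that feature space well, the panel acts as a
set of physical basis functions: the binding free energy of compound $i$ to a
target $a$ can be written as a linear combination of the compound's docking
scores $s_i^b$ against the $N_p$ probe proteins,

$$\Delta G_i^a \;\approx\; \sum_b R_b^a\, s_i^b + \beta^a .$$

This is the modelling assumption the whole package rests on.  It is a
single-site, linear approximation: it ignores intramolecular strain and
conformational entropy, and it cannot represent a target with several
distinct binding sites (orthosteric + allosteric), for which a single linear
map from scores to affinity does not exist.

Fitting $R_b^a$ directly is ill-posed ($N_p$ can exceed the number of
compounds, and columns are strongly correlated), so the regression runs in
principal-component space.  With column means $\bar s_b$ and loading vectors
$d_b^j$,

$$p_{ij} = \sum_b d_b^j\,(s_i^b - \bar s_b), \qquad
  \Delta G_i^a = \sum_{j \in \mathcal A} c_j^a\, p_{ij} + \beta^a ,$$

over a selected axis set $\mathcal A$.  Columns are centred but *not*
standardised: all scores live on the same kcal/mol-like scale, and rescaling
would distort the physical weights.

Coefficients minimise the restrained objective

$$\sum_i \left(\Delta G^{exp}_i - \textstyle\sum_j c_j p_{ij} - \beta\right)^2
  + \lambda \sum_j (c_j - c^{ideal}_j)^2,$$

with the offset $\beta$ unpenalised.  The restraint encodes a physical prior:
were the target itself in the panel, the ideal solution would be $c = $ "use
that column with weight 1"; with the target absent, $c^{ideal} = 0$ and the
restraint simply keeps the folded-back weights
$R_b = \sum_j c_j d_b^j$ at realistic magnitudes (binding free energies are
essentially always below 18 kcal/mol in magnitude, and the fit warns when a
coefficient reaches that size).

The robust variant replaces the quadratic data term with a Tukey-type
M-estimator: residuals are weighted by $w(d) = (1 - d^2/W^2)^2$ for
$|d| \le W$ and ignored beyond the cutoff, fitted by iteratively reweighted
least squares (IRLS) starting from unit weights.  Public bioactivity data
mix assay conditions, cell lines and even protein mutants under one target
id; the M-estimator keeps single grossly wrong records from steering the
fit.

## Tunable parameters

| parameter | meaning | unit | default | why |
|---|---|---|---|---|
| `lambda` | restraint strength | dimensionless | `1e-4` | centre of the flat region of the default grid; `0` disables the restraint and is rejected for collinear axes |
| `W` | robust error cutoff | kcal/mol | `20` | several times any plausible experimental error, so only gross outliers are discounted; `Inf` = plain restrained fit |
| `max_axes` | cap on selected PC axes | count | `15` | selection stops earlier when no axis improves the LOO correlation |
| `n_sigma` | replicate elimination multiplier | sd units | none | grid `0.2 … 3` available; see the caveat below |
| `temperature_K` | assay temperature for ΔG = RT ln K | K | `300` | RT ≈ 0.6 kcal/mol, room temperature |
| percent floor | ΔG of a non-informative percent record | kcal/mol | `-4` | weakest binder the conversion will claim |

Grid defaults (`dsq_lambda_grid()`, `dsq_w_grid()`, `dsq_n_grid()`) span 0 to
0.1, 5 to 100 kcal/mol (plus disabled), and 0.2 to 3 respectively; the best
grid cell maximises Q² with ties broken toward smaller RMSE, then smaller
λ, then smaller W.

## Activity conversion choices

* IC50 is treated as Ki (Cheng–Prusoff correction factor 1).  The correction
  requires per-assay substrate concentration and Km, which public exports do
  not reliably carry; assuming uniform conditions is the only consistent
  desk-scale option, and the replicate-elimination stage exists precisely to
  absorb the resulting heterogeneity.
* A percent-inhibition record at assay concentration $C$ implies
  $IC_{50} = C\,(100-p)/p$; complete inhibition is treated as 99% so the
  implied IC50 stays finite while ordering is preserved.
* 0% inhibition (equivalently 100% residual activity) carries no affinity
  information beyond "weak"; such records map to exactly −4 kcal/mol, and no
  percent-derived value is ever weaker than that floor.  Percent values
  slightly outside [0, 100] are clipped (assay noise).

## The Nσ elimination rule and its small-sample behaviour

A replicate is removed when $|E(k) - \overline{\Delta G}| > N\sigma$, with
mean and *sample* sd computed over the pair's full replicate set in a single
pass (statistics are not recomputed after removals; an iterative variant is
available behind a flag but makes no claim of protocol fidelity).  The final
pair value is the mean of the retained replicates — the consolidation
statistic is a package choice.

Two small-sample facts are worth knowing.  For duplicate pairs ($M = 2$) both
deviations equal $\sigma/\sqrt 2$, so *both* replicates are removed whenever
$N < 1/\sqrt 2$ — `consolidate()` treats an emptied group as an error rather
than silently dropping the pair.  For triplets, the largest squared deviation
always carries at least half of the total, so any $N < 1$ removes at least
one replicate from essentially every non-degenerate triplet.  Aggressive
small-N elimination therefore prunes a large share of perfectly ordinary
replicates — that is inherent to the rule, not a defect of the
implementation, and it is why the removal fractions at small N are large on
replicate-rich data.

## Axis selection

The selection criterion is the leave-one-out cross-validated Pearson
correlation of the restrained fit; the search is greedy forward selection
(ties to the lowest axis index), stopping when no axis improves the
criterion or `max_axes` is reached.  LOO predictions are exact, via the
penalised-least-squares smoother identity $e_i/(1-h_{ii})$; because
training-fold PC scores are orthogonal and centred, the greedy scan is
additive and costs $O(n\,m)$ per step, with a general fallback for arbitrary
projections.  An exhaustive subset mode (≤ 12 axes) exists to verify the
greedy search on small problems.  Axis selection uses the plain (non-robust)
restrained fit for tractability; the robust fit is applied to the selected
axes afterwards.

## Numerical choices

* PCA by SVD of the centred matrix; loading signs fixed by making the
  largest-magnitude entry of each column positive, so runs are reproducible
  across platforms.
* The restrained fit is solved in closed form through the penalised normal
  equations; singular systems at $\lambda = 0$ (collinear axes) are rejected
  with advice to use $\lambda > 0$.
* IRLS applies the Tukey weight to $|d|$ (residuals of both signs weight
  symmetrically), stops when the relative max change of $(c, \beta)$ drops
  below $10^{-8}$ (cap 100 iterations; in practice well under 20), and
  errors out if every observation lands beyond $W$.  The diagnostics record
  the Tukey robust loss $\sum_i \rho_W(d_i) + \lambda\|c - c^{ideal}\|^2$,
  scaled so $\rho_W(d) \to d^2$ as $W \to \infty$: each exact weighted fit
  is a quadratic majorisation step for that loss, so the recorded trace is
  provably non-increasing.  The weighted sum with weights re-evaluated at
  the current residuals is *not* monotone and is not used as a convergence
  measure.
* $W$ disabled is represented as `Inf`; the fit then bypasses IRLS and is
  bit-identical to the plain restrained solution.
* Cross-validation re-runs the entire pipeline (centring, PCA, axis
  selection, robust fit) inside every training fold; replicate consolidation
  is a per-pair operation and is applied identically to training and
  held-out pairs, so no held-out information can reach any training
  statistic.  k-fold partitions are seeded, balanced to within one, and
  stratified by target.  Folds with fewer than 3 compounds skip axis
  selection and use the leading-variance axis.
* Model JSON serialisation writes numbers through `%.17g`, so a round trip
  predicts bit-identically.

## What the synthetic generator does and does not emulate

`generate_synthetic()` draws a low-rank score matrix $F L^\top$ plus jitter —
the latent factors play the role of shared pharmacophore responses — and
builds true free energies as a sparse linear combination of the *noiseless*
scores, observed through replicates with Gaussian noise and an optional
planted fraction of shifted outliers.  Defaults: 500 × 60, rank 8, 10
informative probes with weights of at most a few tenths of a kcal/mol per
score unit (so that the effective weights stay near the magnitudes seen in
realistic fits), 0.7 kcal/mol replicate noise (the typical spread of repeated
public-database measurements of one pair), 3 replicates, scores centred
around a −9 kcal/mol free-energy level.  The 0.2 kcal/mol score jitter
represents scoring-function reproducibility; the systematic part of the
docking response lives in the low-rank structure by construction.

What it deliberately does not emulate: docking physics and pose generation,
metal–ligand quantum effects, target-dependent assay-condition shifts (batch
effects), mutant proteins sharing a target id, or non-Gaussian activity
distributions.  Because the generator satisfies the model's own linearity
assumption exactly, passing tests demonstrate that the estimator recovers
what it is designed to recover — near the replicate-noise floor on clean
data, robustly under gross contamination — not that real kinase or protease
data meet the assumption.

## Known limitations

* Single-site linear model: multi-pocket targets are out of reach by design.
* IC50 ≈ Ki ignores substrate-competition corrections where the substrate
  concentration is actually known.
* The Nσ rule with small replicate counts removes many ordinary replicates
  at small N (see above); choose N with the replicate structure of the data
  in mind.
* Axis selection inside every CV fold makes leave-one-out on large datasets
  CPU-bound in the number of pairs; the seeded 4-fold protocol is the
  practical alternative and is what the grid search uses by default.
* Naive per-target docking scores can be *evaluated* as a baseline by
  passing them as an external prediction column, but the package does not
  run a docking engine.
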