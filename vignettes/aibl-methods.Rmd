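---
title: "Bond-length models of pKa for tautomerizable cyclic 1,3-diketones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bond-length models of pKa for tautomerizable cyclic 1,3-diketones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiblpka)
```

## The problem and the model

Cyclic 1,3-diketones — the 1,3-cyclohexanedione and 1,3-cyclopentanedione
scaffolds found in triketone and oxime herbicides and in the tetracycline
antibiotics — tautomerize between a diketo form and two keto-enol forms.
Conventional empirical pKa predictors stumble on these compounds because the
dominant solution-phase tautomer is not the one their increment schemes
assume.  The AIBL ("ab initio bond lengths") approach sidesteps tautomer
enumeration entirely: it works from a quantum-chemically optimized geometry
of the keto-enol *anti* conformer and regresses the aqueous pKa directly on
a handful of equilibrium bond lengths.

The diagnostic distances are the five bonds of the keto-enol fragment,
labelled i–v in field convention:

| bond | atoms                | feature column  |
|------|----------------------|-----------------|
| i    | O–H (enol hydroxyl)  | `r_OH`          |
| ii   | C1–O (enol C–O)      | `r_CO`          |
| iii  | C1=C2 (enol C=C)     | `r_CC_double`   |
| iv   | C2–C3                | `r_CC_single`   |
| v    | C3=O (keto carbonyl) | `r_CO_double`   |

The physical rationale is resonance-transmitted electron withdrawal: across
a congeneric series, a more acidic compound has a longer O–H and C=C bond
and a shorter enol C–O bond, so each length is a linear proxy for the
free-energy change of deprotonation.  The core single-bond model is an
ordinary least-squares line in the enol C–O length,

$$\mathrm{p}K_\mathrm{a} = 93.381\,r(\mathrm{CO}) - 127.71,$$

with $r$ in Å (`published_co_model()`).  Multi-bond variants use PLS,
ε-insensitive SVR (linear and RBF kernels), random-forest regression and a
Gaussian process with the squared-exponential ARD kernel

$$k(x, x') = \exp\!\Big(-\tfrac12 \sum_{d} \frac{(x_d - x_d')^2}{\ell_d^2}\Big),$$

one length scale per bond.

## What the package computes

The package covers everything downstream of the quantum chemistry: the
upstream DFT geometry optimization (and any conformer/tautomer ranking) is
out of scope, and its output — an optimized 3D structure — is this
package's input.

1. **Geometry.** `read_xyz()` / `read_sdf()` parse structures;
   `perceive_bonds()` assigns connectivity by the covalent-radius criterion
   $d \le 1.2\,(r_i + r_j)$ with a bundled Cordero-type radius table (the
   factor is tunable in $[1.0, 1.5]$; 1.2 accommodates the elongated bonds
   of conjugated rings without fusing non-bonded contacts).
   `detect_keto_enol_fragment()` locates the
   C3(=O)–C2=C1(–O–H) path on a 5- or 6-ring, requiring an exocyclic keto
   oxygen and an enol oxygen with exactly one hydrogen, and classifies the
   conformer from the C2–C1–O–H torsion (syn for $|\tau| \le 90^\circ$,
   anti otherwise — the data only ever contain near-0° and near-180°
   forms, so the threshold's exact placement is immaterial).
2. **Models.** `fit_ols_single()` (raw Å, so the slope stays in pKa/Å),
   plus `fit_pls()`, `fit_svr()`, `fit_rfr()` and `fit_gpr()` on z-scored
   features.
3. **Selection.** `enumerate_subsets(5)` lists all 31 bond subsets in a
   canonical by-size-then-lexicographic order; `kfold_cv()` (default
   $k = 7$) scores each, with a per-subset grid search where the method has
   tunable hyperparameters; `flag_outliers()` applies the 4-of-5-bonds
   residual rule; `discover_subseries()` quantifies motif-sharing subsets.
4. **Validation.** `reproduce_validation()` recomputes the external-test
   statistics of all eight prediction methods from the bundled 22-compound
   table and compares them with the published values.

## Design choices in the genuinely open spots

**Feature standardization.** The multi-feature methods z-score each bond
length with training-set constants.  Raw bond lengths vary by only ~0.01 Å
within a series, which would make an RBF γ of 5 or an ARD length scale of
$e^{-8}$ meaningless; standardization puts the reported hyperparameter
magnitudes on a sensible scale.  Single-bond OLS stays in raw Å for
interpretability.  Reported ARD length scales such as $-8.21$ are read as
optimizer-space (log) values — a negative raw length is impossible.

**GPR noise handling.** No noise variance is learned; the model is
noiseless-plus-jitter.  The base jitter is $10^{-10}$, escalated tenfold on
Cholesky failure up to $10^{-4}$.  The optimizer (L-BFGS-B, best of
seeded random restarts; first restart always the all-zero point) works in
log space with box bounds $[-15, 3]$ on log length scales and $[-15, 8]$
on the log kernel variance: on z-scored features, length scales beyond
$e^{3} \approx 20$ are indistinguishable from a flat kernel and only
degrade the conditioning of the kernel matrix.  A short iterative
refinement of the weight vector after fitting keeps the posterior mean on
the training targets to well below $10^{-6}$ even when the optimum sits
near that flat regime.

**Cross-validation.** Records are ordered by compound id, shuffled with a
seeded Fisher–Yates permutation and chunked into contiguous folds whose
sizes differ by at most one, so fold membership is reproducible and
independent of input row order.  The headline cross-validated RMSE pools
the held-out residuals (invariant to fold-size imbalance); the
fold-averaged RMSE is reported alongside since the convention behind the
published cross-validation numbers is not recorded.  A cross-validated
$q^2$ is exposed as the squared Pearson correlation of observed versus
pooled held-out predictions — an interpretation, labelled as such.

**Tie-breaking.** Grid values are sorted ascending and subsets visited in
canonical order, with only strict improvements accepted: ties therefore
resolve toward fewer features, then the smaller canonical subset id, then
smaller hyperparameter magnitudes.

**Grids.** Defaults bracket the reported optima: $C \in \{1, 10, 100,
1000\}$, $\varepsilon \in \{0.01, 0.1, 1\}$, $\gamma \in \{0.5, 1, 5,
10\}$, $n_\mathrm{est} \in \{10, 25, 50, 100\}$, depth $\in \{2, 4, 6,
8\}$, and PLS latent variables from 1 to the subset size.

**The published split is irreproducible.** The original 49:22 train/test
membership is not printed (the full 71-compound feature table lives in
supplementary material only), so `split_dataset()` offers a seeded random
split — with an explicit `n_train` override, since `round(0.7 * 71)` is 50,
not 49 — and an explicit membership interface (`train_ids`) rather than any
pretence of recovering the original assignment.  The two training-set
outliers (dk29, tk3) ship as a declarative exclusion list with reasons
(`outlier_exclusions()`).

## The synthetic generator: what it emulates and what it does not

`generate_series()` emulates the statistical structure the analysis
assumes: a congeneric series whose pKa is linear in the enol C–O length
with Gaussian scatter, and whose five bond lengths co-vary.  Defaults are
the study conditions: $n = 49$ compounds, the published slope and intercept
(93.381, −127.71), C–O lengths uniform over 1.30–1.36 Å, and noise
s.d. 0.3 pKa units — the scale of the cross-validated single-bond errors.
The cross-correlation structure is a single-factor Gaussian copula with
loadings of magnitude 0.9 carrying the documented sign pattern (O–H and
C=C lengthen, C–O shortens with increasing acidity); the 0.9 magnitude is
a package choice, stated here, not an estimated quantity.  The other four
bond windows (O–H 0.96–1.02 Å, C=C 1.34–1.40 Å, C–C 1.42–1.48 Å, keto C=O
1.21–1.27 Å) are frozen chemically plausible defaults.
`generate_two_series()` adds a second series with a slope multiplied by a
chosen ratio (default 1.22, the steepness contrast between substituent
families), anchored at the window midpoint so both series share a pKa
range.

What the generator does **not** emulate: DFT-level geometric realism
(beyond bond lengths and ring planarity in the companion geometry builder
`generate_fragment_geometry()`), heterogeneity across ring sizes and
substitution patterns, multiprotic microstate effects, or non-Gaussian
measurement error.  Passing the property-based tests therefore
demonstrates that the estimators and the selection machinery behave
correctly under the model's own assumptions — not that real 1,3-diketone
data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Bond-length window (0.5, 3.0) Å: anything outside is rejected as a
  feature and merely warned about (extrapolation) at prediction time.
* A constant response gives a degenerate single-bond fit, flagged rather
  than silently returned; a constant bond length is an error.
* Heavy-atom-only structures fail fragment detection with a specific
  "no hydroxyl H" message — the O–H distance is the first feature, so
  guessing a protonation state would be worse than refusing.
* Multiple candidate enol sites (conceivable in triketones) resolve
  deterministically to the shortest O–H candidate, with a warning and all
  candidates recorded.
* SVR uses a frozen dual tolerance of $10^{-6}$; when an over-wide ε tube
  leaves no support vectors the predictor is the libsvm constant $-\rho$.
* The idealized ring builder closes the hexagon as a cyclic polygon
  (circumradius solved by `uniroot` to $10^{-14}$), so requested bond
  lengths are reproduced exactly; impossible side-length sets are rejected.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything they need:
the 22-compound bundled table for the validation surface; 100 replicates
of a 30-compound single-signal series for subset-selection recovery; 200
replicates of the 49-compound study-scale series for slope recovery; and
5- to 12-point problems for the Gaussian-process numerical checks, where
dense-matrix oracle evaluations are cheap and exact.  These sizes mirror
the study scale where the property is about the study (n = 49) and drop to
the smallest informative size where the property is purely numerical.

## Known limitations

* Recomputing correlation-based statistics from 2-dp-rounded predictions
  shifts them slightly: the C–O test $r^2$ recomputes as 0.90 against a
  printed 0.92, and the Marvin $r^2$ values move more; error metrics (MAE,
  RMSEP, s.d.) are stable.  `reproduce_validation()` therefore checks
  $r^2$ within ±0.02 and reports per-cell pass/fail honestly.
* The training-set rows of the published summary tables (7-fold CV values,
  training $r^2$) are not reproducible without the supplementary
  71-compound bond-length table and are deliberately not asserted;
  property-based parameter-recovery checks stand in for them.
* Bonds beyond the five-fragment set (exocyclic substituent bonds used
  during tautomer screening) are not extracted: their identity is not
  fully specified in the main text and the retained models do not use
  them.
* The Gaussian process reports point predictions only; posterior variance
  is computed nowhere because no published quantity calibrates it.
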