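---
title: "Methods: regularized CCA in a multiple-holdout framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularized CCA in a multiple-holdout framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

holdoutcca links a wide battery of epidemiological risk factors (body
composition, diet, physical activity, sleep, alcohol, smoking, air
pollution) to parcel-wise cortical structure (cortical thickness or gray
matter volume over 148 Destrieux-style parcels) in large population
cohorts. This vignette is the package's own account of the statistical
machinery: the model, its assumptions, the knobs that matter, the
synthetic cohorts used to validate it, and the numerical choices made
where the design was genuinely open.

## The model

Given standardized views $X \in \mathbb{R}^{n \times p}$ (brain
parcels) and $Y \in \mathbb{R}^{n \times q}$ (risk factors), canonical
correlation analysis seeks weight vectors $u, v$ maximizing
$\mathrm{cor}(Xu, Yv)$. Classical CCA overfits badly when $p, q$ are
large relative to $n$, so the within-view covariances are shrunk toward
the identity:

$$\tilde{C}_{xx} = (1 - c_x)\,C_{xx} + c_x I, \qquad
  \tilde{C}_{yy} = (1 - c_y)\,C_{yy} + c_y I,$$

with $c \in [0, 1]$. The solution comes from the singular value
decomposition of
$\tilde{C}_{xx}^{-1/2}\, C_{xy}\, \tilde{C}_{yy}^{-1/2}$:
left/right singular vectors $a_k, b_k$ give
$u_k = \tilde{C}_{xx}^{-1/2} a_k$ and
$v_k = \tilde{C}_{yy}^{-1/2} b_k$, normalized so
$u_k^\top \tilde{C}_{xx} u_k = 1$. At $c = 0$ this is classical CCA; at
$c = 1$ it degenerates to the partial-least-squares limit (singular
vectors of $C_{xy}$ alone). Both limits are verified in the test suite
against independent oracles (a generalized eigendecomposition and a
direct SVD, respectively).

*Scores* $Xu$, $Yv$ are subject-wise values; *loadings* — the Pearson
correlation of each original variable with its same-side score — are
the interpretation device. Weight signs are indeterminate; every
downstream aggregation aligns signs explicitly and is tested to be
invariant under joint flips of $(u_k, v_k)$.

The primal formulation is used throughout: with $p = 148$ and $q = 68$
the inverse square roots (symmetric eigendecomposition, eigenvalue
floor $10^{-12}$) are cheap, and no dual/kernel formulation is needed.
Covariances use the $n - 1$ denominator; since inputs are standardized
they are correlation matrices.

## The multiple-holdout framework

Two nested levels of random splits (independent repetitions, not
folds):

* **5 outer splits** divide all subjects into an optimization set (80%)
  and a holdout set (20%), used for statistical evaluation;
* **5 inner splits** divide each optimization set into training (80%)
  and test (20%) sets, used for model selection.

The 80/20 fractions are package defaults (configurable); the 5 × 5
scheme is the framework's standard configuration.

**Preprocessing without leakage.** Brain-size scaling (raw,
proportional, or corrected — regression of each parcel on the global
reference), confound regression (age, site, and sex in the mixed-sample
configuration; sex-stratified runs are the same pipeline minus the sex
confound), and column standardization are all *fitted on training rows
only* and applied to test/holdout rows with the training parameters.
Confounds are removed from both X and Y; a diagnostic check appends
confound columns to Y and asserts their loadings vanish. Composition
order is fixed: scaling, then confound removal, then standardization.
The test suite verifies bit-level invariance of every training-side
estimate under arbitrary mutation of holdout rows.

**Model selection.** For each candidate regularization level (default
grid $c \in \{0, 0.1, 0.3, 0.5, 0.7, 0.9, 0.99, 1 - 10^{-4}\}$, shared
between views), the model is fitted on each inner training set and two
criteria are recorded: the mean test canonical correlation, and the
*stability* of the weights — the mean pairwise absolute Pearson
correlation of the weight vectors across inner splits (absolute value
because of sign indeterminacy; u-side and v-side stabilities are
averaged). Candidates are ranked on both criteria and the minimal rank
sum wins; ties go to the more regularized candidate, favoring
stability. The rank-sum combiner and the tie-break are package design
choices — the two criteria ("highest test correlation and highest
stability") do not by themselves define a total order.

**Permutation evaluation and the omnibus rule.** Per outer split, the
model is refitted on the full optimization set with the selected
hyperparameters and the holdout is projected; the observed statistic is
the first holdout canonical correlation. Under the null, rows of Y are
shuffled independently within the optimization and holdout sets, the
model is refitted with the *same* hyperparameters, and the permuted
holdout is projected: 1,000 iterations give
$p = (1 + \#\{r_\text{null} \ge r_\text{obs}\}) / 1000$, then
Bonferroni over the five outer splits
($p_\text{corr} = \min(1, 5p)$). The dimension is significant under
the omnibus rule if at least one split's corrected p falls below
$\alpha = 0.05$. The smallest reportable corrected p is therefore
$5/1000 = 0.005$ exactly — the permutation floor. The statistic is the
signed correlation (one-sided): the first canonical correlation is
nonnegative by construction on the training side and the holdout
statistic inherits the planted orientation.

Because a row shuffle of Y leaves $C_{yy}$ (and $C_{xx}$) untouched,
the permutation refits precompute the whitening transforms and
recompute only $C_{xy}$ — algebraically identical to a full refit, an
order of magnitude faster. A refit failure inside an iteration counts
conservatively as a null value at least as large as the observed one.

**Deflation.** After a significant dimension, its variance is removed
by projection deflation: every column of X is residualized on the
x-score and every column of Y on the y-score. Holdout rows are deflated
with the optimization-estimated regression slopes, keeping the
operation well-defined out of sample. Projection deflation (rather than
weight-space deflation) is the package's reading of "removing the
dimension's variance from the data"; the exact formula is a recorded
assumption. Extraction stops at the first non-significant dimension or
at `max_dimensions`.

For dimensions after the first, the data already live in the
outer-preprocessed, deflated space, so inner-split preprocessing during
selection reduces to re-standardization on inner training rows; at
dimension 1, confound regression itself is fitted inside each inner
training split. Either way no holdout information reaches any fit.

**Loadings and stability.** Loadings are computed on each split's
optimization partition (the larger sample; recorded in the output
metadata — the alternative holdout-side loadings would be noisier).
Splits 2–5 are sign-aligned to split 1 by the sign of the correlation
of their risk-factor loading vectors (the same flip applies to the
brain side); a near-zero alignment correlation triggers a warning that
dimension matching is unreliable. The aggregated loading is the
per-variable mean across splits with a one-standard-deviation error
bar; a loading is *stable* iff $|\text{mean}| > \text{SD}$, i.e., the
error bar does not cross zero. Worked example: loadings
$\{0.5, 0.5, 0.5, 0.5, -0.1\}$ give mean $0.38$, SD $\approx 0.268$ —
stable.

## Spatial nulls for cortical maps

Parcel-wise loading maps are spatially autocorrelated, so their
comparison with annotation maps (receptor densities, metabolic maps,
functional gradients) uses a spin-permutation null: each permutation
draws a uniform random 3-D rotation (QR orthonormalization of a
Gaussian matrix, determinant forced to $+1$), applies it to the
left-hemisphere centroids and the x-mirrored rotation to the right, and
reassigns each parcel the value of the nearest original same-hemisphere
centroid. Duplicates are permitted (the standard parcel-level variant);
the identity permutation is stored as entry 0 and excluded from the
null count. The test is two-sided on the absolute correlation,
$p = (1 + \#\{|r_\text{null}| \ge |r_\text{obs}|\})/(n_\text{perm}+1)$,
with 10,000 permutations by default and Bonferroni over the battery
size. Spearman correlation is used against annotations; note that
duplicate reassignments break rank invariance, so each spun map is
re-ranked. Risk-factor loading profiles (no spatial structure) are
compared across models with a plain Pearson correlation instead.
Hemisphere-incomplete maps are rejected with an error rather than
special-cased.

## Subject scores and external markers

Subject-wise scores for a dimension are obtained by projecting all
subjects through each outer split's model (with that split's
training-estimated preprocessing and deflation chain), sign-aligning,
and averaging; a holdout-only variant restricts each split's
contribution to its held-out subjects for leakage-sensitive uses.
Association with an external inflammation marker (C-reactive protein in
the motivating application) uses Spearman correlation — invariant under
monotone transforms, appropriate for a right-skewed marker — with the
analytic large-sample p-value and Bonferroni correction over a
user-declared battery size (the family size is a reporting choice, so
it is a required input that is echoed in the output).

## The synthetic cohort generator

Restricted cohort data cannot ship with the package, so validation
rests on a generator whose defaults mirror the target study conditions:
7,370 subjects, 68 risk factors, 148 parcels split over two mirrored
hemispheres, age uniform on 46–81, balanced sex, four equal-probability
acquisition sites, and two planted latent dimensions with canonical
correlations 0.32 and 0.10 (the reported holdout ranges of the
cardiometabolic-health and physical-robustness dimensions), plus a
lognormal marker rank-linked to dimension 1 at Spearman $-0.39$.

Construction, per planted dimension $k$: a latent score pair
$(s^x_k, s^y_k)$ is bivariate normal with correlation $r_k$; $s^x_k$
enters X through a spatially smooth weight map over the parcel
centroids (Gaussian-process draw with kernel
$\exp(-d^2/2\sigma^2)$ on chord distance — the simplest stationary
autocorrelation on the sphere) and $s^y_k$ enters Y through
block-patterned weights. Weight vectors are orthonormalized across
dimensions and the additive noise is projected orthogonal to them, so
the population canonical correlation equals $r_k$ *exactly* and the
recorded truth scores carry it too — this is what makes the
calibration invariants sharp (empirical correlation within
$3/\sqrt{n}$ of target). Risk-factor blocks (body composition: 10
variables at within-correlation 0.7; air pollution: 6 at 0.7) are
induced by shared block factors. The marker is
$\exp(a\, s^y + \varepsilon)$ with $a$ solved from the target Spearman
correlation through the bivariate-normal identity
$\rho_S = (6/\pi)\arcsin(\rho_P/2)$ — exponentiation induces the
CRP-like right skew without touching ranks. The noise scale
(`noise_sd = 0.3`) is calibrated so planted loadings span the
magnitudes typical of population cortical-structure studies
(risk-factor loadings to ~0.8 within the driving block, brain loadings
to ~0.5).

What the generator does **not** emulate: the marginal distributions of
real risk-factor fields (only block topology and scale), site- or
scanner-specific artifacts, missingness (the pipeline rejects
incomplete records by design), non-linear confound effects, and
non-stationary cortical autocorrelation. Passing recovery tests
therefore demonstrates correctness of the machinery under a faithful
covariance structure, not robustness to every feature of real data.
Parcel centroids are a Fibonacci-style lattice on each half-sphere with
the right hemisphere mirrored through the $x = 0$ plane — the mirror
symmetry the spin null assumes — and real centroid tables can be
substituted in the same format.

## Numerical choices and degenerate inputs

* Eigenvalue floor $10^{-12}$ in matrix inverse square roots; the
  $c \to 0$ limit is still validated against the classical oracle at
  $10^{-6}$.
* Standardization before RCCA is adopted (covariance-based solvers
  assume column scaling); whether the motivating analysis standardized
  is unknown, and the choice is irrelevant to all rank-based downstream
  statistics.
* Dummy coding of categorical confounds drops the first level; the
  intercept is always included; rank-deficient confound designs error
  with the collinear column names; unseen categorical levels at
  application time error rather than extrapolate.
* Zero-variance columns: an error in standardization and stability
  computations (where they poison everything), a flagged `NA` in
  loadings (where they are local).
* "Uncorrelated after residualization" means $|r| \le 10^{-10}$ on
  training rows — exact arithmetic up to floating point.
* p-value conventions: permutation $p = (1 + k)/n_\text{perm}$
  (framework) and $(1 + k)/(n_\text{perm} + 1)$ (spin), both bounded
  away from zero; corrected values are clipped at 1.
* Selection ties break toward larger regularization; the degenerate
  one-candidate grid short-circuits to that candidate.

## Validation scale

The automated suite exercises the full machinery at desk scale, chosen
as the smallest sizes at which the statistical claims are sharp: oracle
equivalence on 50 × 4 / 50 × 3 instances; the permutation floor on a
strongly planted cohort (n = 500, p = 40, q = 20, r = 0.6, 1,000
permutations); two-dimension recovery at the full study shape
(n = 4,000, p = 148, q = 68, r = 0.5/0.3, 200 permutations);
family-wise error control over 200 null cohorts (n = 400, 200
permutations); spin-test calibration over 200 independent smooth map
pairs on the 148-parcel geometry (500 rotations). The
`scripts/acceptance.R` entry point re-derives the permutation-floor
value (corrected p = 0.005) from scratch.

## Known limitations

* Dimension identity across outer splits is by extraction order;
  when two dimensions have similar strength their order can swap
  between splits, which the alignment warning surfaces but does not
  repair. Cross-run matching goes through loading-profile correlation.
* The permutation scheme shuffles whole Y rows, so it tests the
  hypothesis of no X–Y association conditional on the confound removal
  being adequate; exchangeability violations from residual confounding
  are not detected.
* Selection shares one regularization level between views by default;
  a two-dimensional grid is supported but quadratically more expensive.
* The spin null is parcel-level (nearest-centroid with duplicates);
  vertex-level and variogram-based nulls are out of scope.
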