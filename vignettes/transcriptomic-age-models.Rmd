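---
title: "Building transcriptomic age models with txclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building transcriptomic age models with txclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txclock)
```

## The problem

A transcriptomic clock is a regression that maps a tissue's gene expression
profile to the donor's chronological age. Deviations between predicted
("biological") and chronological age are of direct interest in aging
research, and the predictive quality of different tissues — and of tissue
combinations — is informative about whether aging is organ-local or
systemic. `txclock` implements the complete model-building protocol for
single tissues and for pairs of tissues sharing donors, together with a
simulator that generates cohorts with known ground truth so that every claim
the package makes about its own behaviour is testable without
access-controlled human data.

## Model and estimation

For one tissue, the clock solves

$$\hat\omega = \arg\min_\omega \sum_{i=1}^{M}\Big(Age_i - \omega_0 -
\sum_{j=1}^{N} x_{ij}\omega_j\Big)^2 + \lambda\Big(\alpha\sum_j|\omega_j| +
\frac{1-\alpha}{2}\sum_j \omega_j^2\Big),$$

with $x_{ij}$ the log2 expression of preselected gene $j$, $\alpha\in[0,1]$
mixing lasso and ridge penalties and $\lambda>0$ the overall penalty
strength. Two conventions matter and are easy to mix up:

* **No $1/(2M)$ factor on the residual.** $\lambda$ is defined against the
  raw residual sum of squares. The reference grid $\lambda = 2^{-10}\ldots
  2^{10}$ only makes sense on this scale; solvers that normalize by sample
  size (such as glmnet) need their penalty rescaled by $2M$ — and, less
  obviously, glmnet's internal response standardization additionally
  rescales the ridge term by the standard deviation of the response. The
  test suite pins both conversions against glmnet as an independent solver.
* **The penalty applies to raw-scale coefficients.** `fit_elastic_net()`
  rescales features internally purely as a numerical preconditioner: the
  per-coordinate penalty weights are rescaled in step, so the optimized
  objective is identical with and without standardization (a tested
  invariant), coefficients are returned on the log2-expression scale, and
  the $\alpha=0$ solution coincides with the closed-form ridge estimate on
  centered, unscaled data. The alternative — penalizing standardized
  coefficients — would change the estimator itself and break that
  closed-form correspondence, so it was deliberately not adopted.

The solver is cyclic coordinate descent (compiled via Rcpp), stopping when
the relative objective change over a full sweep falls below `tol` (default
`1e-7`, maximum $10^5$ sweeps, warning on non-convergence). Constant
features receive a zero coefficient. Inside cross-validation two exact
shortcuts keep the grid search tractable without changing results beyond
solver tolerance: $\alpha = 0$ cells are solved exactly for the whole
$\lambda$ grid at once through the thin SVD of the centered design, and
$\alpha > 0$ cells are solved along a descending $\lambda$ path with warm
starts. Fold fits use a looser `1e-5` tolerance; averaged validation metrics
are insensitive at that level (the final refit uses the reference
tolerance). Both shortcuts are tested against cold reference solves.

## Preprocessing

Quantile normalization forces every sample to the common reference
distribution (row means of the column-sorted matrix). Tied values within a
sample receive the mean of the reference values at their tied ranks — the
standard convention; note that under ties the output multisets are no longer
exactly identical across columns, which is visible already in a 3×2 worked
example in the tests. Normalization is computed on the full per-tissue
matrix *before* any cross-validation split. This mirrors the usual protocol
in which normalization precedes modelling; it does leak marginal
distributional information across folds, which we note rather than "fix",
since the leakage-sensitive step — gene selection — is strictly
fold-internal. Whether normalization should instead be computed globally
across all tissues is not settled; the package normalizes per modelled
tissue, which keeps tissues exchangeable and pairs well with the shared-donor
design.

The log2 transform uses a pseudocount (default 1) because expression-level
values contain zeros. The pseudocount compresses the signal of genes whose
baseline expression is near or below it; for simulated cohorts, whose raw
values are strictly positive by construction, a pseudocount of 0 recovers
the generative log2 values exactly and is used where tests need that
exactness.

## Gene preselection

Genes are ranked by the Pearson correlation between log2 expression and
donor age, computed once per training set. The ordering key is $|r|$:
published clock models contain coefficients of both signs, so restricting to
positively correlated genes would discard half the signal (`signed = TRUE`
restores a signed ranking). Zero-variance genes have no defined correlation
and are excluded (counted, not silently dropped); ties break
lexicographically by gene identifier so rankings are reproducible across
platforms. The preselection size $N$ is a tuning parameter with reference
grid $\{50, 100, 200, 400, 600, 800, 1600, 3200, 6400\}$.

**Fold-internal reranking.** Inside cross-validation the ranking is
recomputed from the training folds only. This is the step that separates an
honest validation estimate from an optimistically biased one: with ~2000
candidate genes and ~150 samples, ranking on all samples before splitting
lets validation RMSE on pure noise fall far below the standard deviation of
age. The test suite checks the no-leakage direction explicitly: with
permuted ages, no grid cell's mean validation RMSE may fall below
$0.7\,\mathrm{sd}(age)$.

## Cross-validation and model selection

"Repeated" cross-validation re-randomizes a 10-fold split `repeats` times
(reference: 100) and averages validation RMSE and PCC over all repeats ×
folds; repeat $r$ derives its fold seed as `base_seed + r`, so a run is
bit-reproducible from one master seed and a two-repeat run is exactly the
pooled pair of one-repeat runs (a tested contract). An alternative reading
of "bootstrapped" — resampling training sets with replacement and validating
out-of-bag — is available as `cv_scheme = "bootstrap"` but is not the
reference behaviour, because averaging over re-randomized splits is what
reduces split-randomness bias. Samples are put into a canonical internal
order before splitting, so results do not depend on input row order.

`grid_search()` evaluates the full joint lattice it is given and selects the
cell with the lowest mean validation RMSE; ties break toward the smallest
$N$, then the largest $\lambda$, then the largest $\alpha$ — the sparsest,
most regularized candidate. The full reference lattice
($9 \times 101 \times 21$ cells, each costing `repeats` × k fits) is
expensive; `refine_alpha = TRUE` provides a two-stage alternative (coarse
$\alpha$ grid first, then $\alpha$ at step 0.01 in a ±0.25 window around the
winner, with the chosen $N$ and $\lambda$ held fixed). The joint lattice is
the reference behaviour; results at the reported granularity should not
depend on the search order. The final model refits the winning cell on all
samples with a fold-free ranking.

## Two-tissue models

`fit_tissue_pair()` restricts both tissues to donors present in each (pairs
below 70 shared donors are refused by default), builds a donor-by-feature
matrix in which each tissue contributes all of its genes as tissue-tagged
candidate features, and cross-validates over donors — the donor is the unit
of splitting, so no individual can appear in training via one tissue and
validation via the other. Budgets $(N_A, N_B)$ are free grid parameters; the
reference configuration combines a 600-gene budget for the primary tissue
with 50–400 from the second. Rankings for each tissue are computed on the
shared donors only (fold-internally during CV): ranking on each tissue's
full cohort would let non-shared samples influence feature selection
(`rank_on = "full"` restores that behaviour for comparison). A gene measured
in both tissues enters twice under distinct tags and is never merged.
Combinations of three or more tissues are not implemented — shared-donor
counts shrink quickly with each added tissue — but the paired-dataset design
generalizes.

## The cohort simulator

`simulate_cohort()` draws, per gene $g$, donor $s$, tissue $t$:

$$\log_2 x_{g,s,t} = \mu_g + \delta_{g,t} + \beta_{g,t}\,
\frac{age_s + \eta_{s,t} - \mathrm{mid}}{\mathrm{halfrange}} +
\varepsilon_{g,s,t},$$

with raw expression $2^{\log_2 x}$. Defaults (chosen once, as study
conditions, and used by the recovery tests): 300 donors with integer ages
uniform on 20–70; two tissues each including a donor with probability 0.8
(every donor is guaranteed at least one tissue); 2000 genes of which 50
carry a shared age slope; slopes $\beta \sim N(0, 2^2)$ in log2 units per
standardized age, with magnitudes below `effect_floor` (default 0.1) times
the slope sd redrawn so a configured causal gene is never effectively null;
per-gene baselines $\mu_g \sim N(5, 2^2)$ and tissue shifts
$\delta_{g,t} \sim N(0, 0.5^2)$; residual noise
$\varepsilon \sim N(0, 0.5^2)$ log2 units.

The term $\eta_{s,t} \sim N(0, 3^2)$ years is the simulator's model of
tissue-level biological-age deviation: all genes of one tissue of one donor
read out the same, noisy, version of that donor's age. It is the component
that caps single-tissue accuracy near 3 years RMSE regardless of how many
genes are used — per-gene noise averages away with the feature count, a
shared deviation does not — and, because it is drawn independently per
tissue, it is exactly the component that combining two tissues can average
down (to $3/\sqrt 2 \approx 2.1$ years at equal weights). That gives the
two-tissue machinery a testable direction: paired models should beat the
better single tissue when both carry signal, and lose to it when the second
tissue is pure noise, since its "top" genes are then the most spuriously
age-correlated of thousands of nulls. Both directions are asserted over ten
seeded replicates in the test suite.

Sex is generated (expected male:female ratio 1.5) but unused by the models;
it exists so cohort-summary ratios are exercised. What the simulator does
*not* model: read-count sampling, batch and library-size effects, nonlinear
age trajectories, correlated co-expression modules. Passing recovery tests
on simulated cohorts therefore demonstrates correctness of the pipeline's
statistics, not clock accuracy on real tissue.

## Problem sizes used by the shipped checks

The slow checks run at fixed seeded sizes: leakage (150 samples × 2000
genes, permuted ages, 20 repeats, reduced grid), recovery (the 300-donor
default cohort, grid $N\in\{50,100,200\}$, $\alpha\in\{0,0.5,1\}$,
$\lambda\in 2^{\{-2,0,2,4\}}$, 5 repeats), and the two-tissue directions
(ten replicates of the default cohort at budget 50+50, 2 repeats each).
Reduced lattices are used because the properties under test are insensitive
to grid density; the full reference lattice remains available through
`param_grid()`'s defaults.

## Degenerate inputs and edge cases

Single-sample matrices cannot be quantile-normalized (error); zero values
with a zero pseudocount name the offending gene and sample; constant genes
are excluded from rankings; constant features receive zero coefficients;
prediction refuses profiles missing any model gene (listing them) rather
than imputing zeros — the only zero-imputation path is the explicit
`all_zero` diagnostic mode, which evaluates the prediction equation at an
all-zero profile and so returns the intercept. Validation folds with fewer
than three training samples, empty tissue cohorts and empty donor overlaps
are errors, not empty results.

## Known limitations

* The optional minimum-expression filter is not an attempt to reproduce any
  particular published gene count; quality-control pipelines vary.
* The two-stage $\alpha$ search refines around a coarse optimum and can in
  principle miss a distant one; use the joint lattice when that matters.
* Repeated-CV validation RMSE is an internal selection criterion; the
  package intentionally provides no outer test-set machinery beyond holding
  out data yourself before calling the fitting functions.
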