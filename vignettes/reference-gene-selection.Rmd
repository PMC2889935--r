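---
title: "Selecting reference-gene subsets from the full covariance of a qRT-PCR panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting reference-gene subsets from the full covariance of a qRT-PCR panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refgenopt)
```

## The model

For a homogeneous set of N samples and J candidate reference genes, the
log-transformed expression levels (or raw threshold cycles, which are
log2-scale up to sign and offset) are modeled per sample as a J-variate
normal vector

$$\mathbf{Y}_i \sim \mathrm{MVN}_J(\mathbf{g}, \mathbf{V}), \qquad
\mathbf{V} = \sigma^2 \mathbf{1}_{J\times J} + \mathbf{R},$$

where $\sigma^2$ is the variance of a per-sample experimental effect shared
by all genes measured in that sample (loading, RNA quantity, RT
efficiency), and $\mathbf{R}$ is the covariance of the genes' innate
(biological, between-individual) variation — *not* constrained to be
diagonal. Technical replicates are averaged beforehand, so replicate-level
error is folded into $\mathbf{R}$.

The log normalizing factor of a subset with indicator $C$ and size
$L=\sum C$ is $F_i = C^\top \mathbf{Y}_i / L$ (the arithmetic mean of log
values, i.e. the log of the geometric mean of linear expressions), with

$$\operatorname{Var}(F) = C^\top \mathbf{V} C / L^2
 = \sigma^2 + C^\top \mathbf{R} C / L^2 .$$

Two consequences drive the whole design. First, $\sigma^2$ enters every
subset identically, so subsets can be compared on the total variance
without ever separating the components — convenient, because $\sigma^2$,
$\mathbf{R}$ and a replicate-error matrix are not separately identifiable
without structural constraints. Only the total $\mathbf{V}$ is ever
estimated here. Second, off-diagonal entries of $\mathbf{R}$ move
$\operatorname{Var}(F)$ directly: a negatively correlated pair can have a
far more stable geometric mean than any individual gene, which no
independence-assuming per-gene ranking can detect.

## Estimating V

`estimate_covariance()` fits each gene column by OLS on a shared design
matrix (intercept-only by default; covariates such as tissue enter through
`design_spec()`), then takes $\hat{\mathbf V} = E^\top E/(N-p)$ from the
residual matrix $E$. Because the mean model is identical across genes and
$\mathbf{V}$ is unstructured, this closed form *is* the multivariate
normal REML solution — iterative mixed-model machinery would return the
same matrix, so none is used. Intercept-only reduces to the textbook
unbiased sample covariance (divisor $N-1$), which the test suite exploits
as an exact oracle: the quadratic form on $\hat{\mathbf V}$ must equal the
empirical variance of the computed per-sample log geometric mean to
1e-10, for every subset.

An unstructured $\mathbf{V}$ has $J(J+1)/2$ parameters, so the fit is
weakly identified unless $N > (J+3)/2$; the function warns (rather than
fails) below that line. No shrinkage is applied — the bootstrap is the
intended remedy for estimation noise.

## The bootstrap and the three criteria

`bootstrap_selection()` resamples **whole samples** (rows) with
replacement — resampling cells or genes would destroy the cross-gene
correlation that is the entire point. Per replicate it re-estimates
$\mathbf{V}$, computes all $2^J-1$ subset variances, and ranks them
(average ranks on ties; exact ties are measure-zero for continuous data
but do occur between overlapping subsets in degenerate replicates). The
summary per subset is

* `ucl95_variance`: the 95th percentile of its variance across replicates
  (empirical quantile with linear interpolation, R type 7; the choice is
  immaterial at the default B = 1000);
* `ucl95_sd`: its square root — the UCL is computed on the variance scale
  and transformed, which is the same thing by monotonicity;
* `mean_rank`: the average rank across replicates.

A row resample is equivalent to a multinomial count vector over the rows,
and both the covariance entries and the quadratic forms are linear in
those counts and in the cross-products, so for the intercept-only design
the whole B-replicate computation collapses into three matrix products.
This is bit-for-bit identical to an explicit resampling loop fed the same
counts (a test asserts this) and makes B = 1000 over 31 subsets take tens
of milliseconds. General designs fall back to the explicit loop, redrawing
(counted, warned) any replicate whose resampled design matrix loses rank.

Selection criteria: **A** minimizes `ucl95_variance`; **B** takes the
smallest subset with `ucl95_sd` at or below a user threshold (log units —
on the natural-log scale an SD of 0.5 means roughly ±65% multiplicative
spread of the NF; no subset qualifying is a status, not an error);
**C** minimizes `mean_rank`. Ties in A and C prefer the smaller subset,
then the fixed enumeration order (size-major, lexicographic), so results
are reproducible. When A and C disagree, `ucl_vs_rank_plotdata()` scales
both metrics to [0, 1] by min–max and reports each subset's Euclidean
distance to the ideal lower-left corner; min–max scaling was chosen over
standardization because both axes are bounded, heavily skewed, and the
corner — not the bulk — is what matters.

Everything is seeded explicitly (the seed is a required argument and is
embedded in every report), and identical inputs + seed reproduce the
summary bit-identically.

## Ct handling

`ct_to_relative_expression()` maps threshold cycles to
$Q_{ij} = 2^{\min_i Ct_{ij} - Ct_{ij}} \in (0,1]$, anchored at each gene's
*minimum* Ct so that 1 marks the sample with the most template — the
convention of the established spreadsheet tools. The anchor is exposed
(`anchor = "max"` gives $2^{\max Ct - Ct}$) because the two differ only by
a per-gene constant on the log scale, which cancels in every variance;
descriptions of this transform in the literature are self-contradictory
about the direction, and the option makes the choice explicit rather than
silent. Raw Ct matrices may also be analyzed directly (CLI
`--no-transform`): if downstream quantification uses Ct numbers, selection
should too, and the analysis is invariant to the affine relation between
the two scales anyway (a test pins the covariance ratio at $\ln(2)^2$).

Missing values default to a hard error naming the cell; the only
alternative offered is complete-case dropping of samples, because the
model is a joint J-variate distribution per sample and imputation is out
of scope.

## Baselines

**geNorm.** Implemented as the published backward elimination: a gene's
stability M is its mean pairwise variation (SD of the log expression
ratio) with the other genes still in play; the worst gene is removed and M
recomputed until a pair remains. The common forward description — "seed
with the most agreeing pair, then grow" — identifies the same surviving
pair, which is reported as `seed_pair` and tied-best in the ranking. A
brute-force recomputation oracle checks every round. M rescales by a
constant under a change of log base, so rankings are base-invariant.

**Independence-assuming comparator.** Under a diagonal covariance the best
size-L subset is simply the L smallest per-gene variances, scored
$\sum_j v_j / L^2$, with the overall pick the argmin across sizes. What
"per-gene variance" means is a genuine fork, so all three options are
implemented and tagged in the result:

* `total` — plain sample variances (diagonal of $\hat{\mathbf V}$,
  $\sigma^2$ included). This is the mode that matches the *analytic*
  comparator column of the simulation design table for the scenarios with
  a consistently printed column, and it is what the analytic
  `cmd_simulate` minima report uses.
* `innate` — column variances of residuals after an *unweighted* two-way
  additive fit. Simple, but the unweighted sample-effect estimate mixes
  every gene's noise into every residual, badly compressing the spread of
  the estimates when variances differ by an order of magnitude.
* `innate_weighted` (default inside the sensitivity experiment) — the
  heteroscedastic fixed-sample-effect model fitted properly: sample
  effects as precision-weighted means, per-gene variances updated with a
  REML-style df correction $N - 1 - N w_j/\sum w$, iterated to a fixed
  point. The df correction is what prevents the collapse ($\tau_j^2 \to 0$
  for the most precise gene) that plain ML suffers with N incidental
  sample-effect parameters. This is the estimator that mixed-model
  software actually produces for the comparator model, and the only one of
  the three whose simulated sensitivities reproduce the published behavior
  of the independence-assuming method across all five scenarios; `total`
  misses badly in the uncorrelated scenario (60% vs 86% at N = 80, a
  12-SE gap). The experiment therefore defaults to it, while the other
  modes remain available.

## The synthetic-data generator

`scenario_spec()` / `simulate_dataset()` draw i.i.d. samples from
$\mathrm{MVN}(\mathbf 0, \sigma^2\mathbf{11}^\top + D\,\mathrm{corr}\,D)$
via pivoted Cholesky (tolerating PSD-singular inputs such as
$\sigma^2=0$ with a degenerate correlation). The mean is zero without loss
of generality — no method here depends on it. The five library scenarios
(`scenario_library()`) span: no innate correlation; uniform weak (+0.2)
and strong (+0.4) positive correlation; and mixed-sign patterns at ±0.2
and ±0.4; innate SDs 0.3–1.2 and sample-effect variances 0.02–0.16 on the
natural-log scale, magnitudes typical of validation panels of 5 candidate
genes. Defaults for the sensitivity experiment are N = 80 (options 25/40
mirror realistic study sizes), 400 simulated datasets (binomial 95% CI
half-width under 5 points), and B = 1000 bootstrap replicates inside each
dataset; `fast = TRUE` scales down to 100 datasets and B = 200 and flags
the result `scaled_down`. Per-dataset seeds are drawn up front from the
master seed, so the experiment is reproducible and trivially
parallelizable.

What the generator does *not* emulate: non-Gaussian expression (outlier
samples, mixture populations), replicate-level technical error as a
separate stratum, gene-specific amplification-efficiency error, missing
values, or tissue fixed effects (the data container and design machinery
support covariates, but the experiment deliberately uses a homogeneous
population). A green sensitivity test therefore establishes correct
behavior of the estimators and selection rules under the stated
multivariate-normal world — not robustness to assay pathology.

## Numerical choices

* Reported per-size minima are rounded **half away from zero**
  (`round_half_up()`), the convention of the statistical software that
  standard report tables come from; base R's round-half-even differs on
  exact halves such as 0.1985, which genuinely occur in the analytic
  tables. A nudge of 1e-7 of the last kept digit absorbs binary
  representation error; test comparisons use ±0.0005 instead of equality.
* Symmetry of a covariance input is enforced to 1e-8 relative; estimated
  matrices are symmetrized by averaging with their transpose before use.
* Correlation matrices must be PSD to eigenvalue ≥ −1e-8.
* Degenerate inputs are defined, not errors: a bootstrap replicate with
  one distinct sample yields zero variances (legal); identical samples
  give every subset mean rank $2^{J-1}$ by tie-averaging; a zero-variance
  residual column makes its correlations NA with a warning, never a
  silent 0.
* Subset enumeration is capped at J = 20 (about 10^6 subsets) with an
  explicit override, since the exhaustive design is O(2^J).
* Pearson p-values for residual correlations use the plain N − 2 df
  t-test; this slightly understates the df spent estimating the sample
  effects, a known approximation accepted for a screening diagnostic.

## Limitations

Exhaustive enumeration is exponential in J (fine for the intended
J ≤ ~10–15, impossible beyond ~25). The bootstrap UCL is a plain
percentile, not bias-corrected. Efficiency-adjusted quantification,
amplification-curve processing, and decomposition of $\mathbf{V}$ into
variance components are out of scope. Selection assumes one homogeneous
population; if variances or correlations differ across tissues, a single
reference set may not be appropriate for all of them.
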