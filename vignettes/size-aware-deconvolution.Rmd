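---
title: "Size-aware deconvolution of bulk RNA-seq: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-aware deconvolution of bulk RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deconsize)
```

## The model

Reference-based deconvolution treats a bulk expression profile as a linear
mixture of cell-type-specific profiles:

$$Y_{G\times J} = Z_{G\times K}\,P_{K\times J},$$

where $Y$ holds $G$ marker genes by $J$ bulk samples, $Z$ is the signature
matrix of per-type mean expression, and $P$ the cell-type proportions to be
estimated, each column on the probability simplex ($p_{kj}\ge 0$,
$\sum_k p_{kj}=1$).

This model silently assumes every cell contributes the same amount of RNA.
When cell types differ in size — cortical neurons carry roughly three times
the mRNA of glia; plasmablasts dwarf other blood cells — a bulk sample's
reads are apportioned by *RNA mass*, not by *cell count*. Solving the
unadjusted model then recovers the RNA fraction

$$\hat p \;=\; \frac{s \circ p}{\sum_k s_k p_k},$$

where $s$ is the vector of relative per-cell RNA contents: the larger type
is systematically overestimated. The correction is a single diagonal
rescaling. Writing $S = \mathrm{diag}(s)$,

$$Y = Z\,S\,P, \qquad Z' = Z\,S,$$

and solving $Y = Z'P$ with the same solver yields cell fractions.
`rescale_reference()` implements $Z' = ZS$; `run_deconvolution()` applies
it exactly once per run (the `scaled` flag on a reference blocks silent
double scaling; `force = TRUE` overrides deliberately).

Two consequences of this algebra drive the package's property tests:

* **Exact recovery.** For noiseless pseudobulk $Y = Z S P$ with a
  full-column-rank reference, deconvolution against $Z' = Z S$ recovers
  $P$ to machine precision (observed pooled RMSE around $10^{-16}$, the
  same magnitude the scaled experiment arms reach in practice).
* **Mismatch law.** If the sizes used to build the pseudobulk ($s_{pb}$)
  and the sizes used to deconvolve ($s_{dec}$) differ, the estimate is
  $\hat p \propto (s_{pb}/s_{dec}) \circ p$. In particular scale factors
  are identifiable only up to a constant: $s_{dec} = c\,s_{pb}$ still
  recovers $P$ exactly. `run_shuffle_experiment()` exercises exactly this
  five-term identity, labelling which terms were matched.

## The solver

The default algorithm is non-negative least squares. The constraint set
stated for the model is $p \ge 0$ with unit sum, but the solver named for
it is plain NNLS, which does not constrain the sum; we therefore solve
$\min\lVert Zp - y\rVert_2,\ p\ge 0$ per sample and divide by the
coefficient sum afterwards. This matches standard usage, satisfies both
constraints a posteriori, and makes the estimate invariant to the overall
scale of a bulk column (sequencing depth). The residual norm recorded per
sample comes from the unnormalized fit. An all-zero NNLS solution is an
error (degenerate reference), never silently uniform.

No NNLS solver ships with our dependency set, and the solver sits at the
core of the method, so Lawson–Hanson active-set NNLS is implemented
directly in R; $K$ is small (2–30 cell types) so the passive-set
subproblems are tiny QR solves.

One numerical subtlety worth recording: "NNLS then normalize" is *not*
the same estimator as least squares constrained to the simplex. Because
the reported quantity is scale-invariant, the correct independent check
enumerates simplex *directions* $(p, 1-p)$ and profiles out the optimal
nonnegative scale $c$ per direction in closed form
($c = \max(0, \langle Zd, y\rangle / \lVert Zd\rVert^2)$). The test suite's
$K=2$ grid oracle does exactly that at step $10^{-4}$; a literal grid over
simplex points disagrees with the solver whenever the best-fitting
coefficient vector does not happen to sum to one.

`deconvolute_weighted_nnls()` solves the per-gene-weighted problem
$\min\lVert W^{1/2}(Zp-y)\rVert_2$, $p \ge 0$. With uniform weights it
equals the unweighted solver exactly (this equivalence is tested at
$10^{-12}$). Weights may be supplied directly or derived from per-gene
variance across samples as $w_g = 1/(\sigma^2_g + \nu)$, with the ridge
constant $\nu$ defaulting to the mean per-gene variance times $10^{-3}$ —
the package's own choice, made to keep weights finite at zero-variance
genes and documented here because no canonical formula exists. Weighting
is an extensibility exercise for the registry, not a reimplementation of
any published multi-sample estimator; wrappers for external algorithms
plug in via `register_algorithm()`.

## Marker selection

`mean_ratio_scores()` scores gene $g$ for target type $k$ as the target's
mean expression divided by the *highest* mean among the other types (not
the mean of all non-targets — the stricter denominator is what "mean
ratio" names in the companion marker-selection literature, and we record
that reading as an assumption). Genes expressed in no other type have an
undefined ratio; they are maximally specific, so they receive an infinite
sentinel that ranks above every finite score, ordered among themselves by
target mean descending. `select_markers()` first lets each gene be claimed
by the type where it scores highest (marker lists are therefore disjoint),
then keeps the top `n_per_type` genes with score above `min_ratio`
(default 1). A shortfall is a recorded warning, not an error. The default
panel size is 40 per type, with 80 equally supported — the two sizes in
common use for the brain panels this design follows; neither is
hard-coded. Whether means are computed on linear counts or log-scale
expression is the caller's choice: the scorer accepts any genes-by-types
mean matrix, including batch-adjusted input. Batch correction itself
(e.g. ComBat) is deliberately out of scope — it is an upstream,
external step.

Two count-level preprocessing utilities accompany selection.
`sample_qc_filter()` retains bulk samples with at least `min_counts`
summed marker counts (default 38,750) and at most `max_zero_markers`
silent markers (default 30). `downsample_counts()` equalizes library
sizes within each cell type by *exact* without-replacement subsampling
(multivariate hypergeometric, drawn gene-by-gene with conditional
`rhyper()` calls) to the minimum per-cell library observed in the group —
the common tooling uses binomial thinning, which only hits the target in
expectation; the exact scheme makes output totals deterministic, which
the tests rely on.

## Cell-size scale factors

Three estimation routes, all returning the same table shape:

* `estimate_scale_factors_from_library_sizes()` — per-cell total counts
  over a gene set, summarized per type by the **median** (robust to the
  long right tail of library sizes; the mean is available since the
  upstream description does not fix the summary). Optional
  `normalize_min_to_one` divides by the minimum, preserving all pairwise
  ratios; both raw and normalized forms are exposed because scaling is
  identifiable only up to a constant anyway.
* `estimate_scale_factors_from_measurements()` — imaging-derived per-cell
  rows; cells with nucleus area above 78 (in the micron-based units of
  the input — the threshold is a pass-through, units are the caller's)
  are discarded as out of focus, then the per-type median of either
  nucleus area or marker puncta copies is taken. A dataset-specific
  nuclei-count quantile filter is not hard-coded; apply quantile filters
  upstream if needed.
* `manual_scale_factors()` — user-chosen constants, e.g. 10 for neurons
  and 3 for glia (ratio ≈ 3.33), a round-number choice sitting between
  expression-derived ratios and previously published values for cortex.

## The synthetic world

`generate_synthetic_sc()` is first-class, tested code, and the stated
world of the acceptance checks. Each of $K$ types owns $M$ planted marker
genes whose negative-binomial mean is `fold_change` times the base mean;
every cell's expected counts are multiplied by its type's size
multiplier; counts are NB with variance $\mu + \mu^2/\theta$ (the
mean/dispersion convention, stated to avoid drift). Defaults: $f = 8$,
$\mu = 2$, $\theta = 10$, 40 markers per type — marker enrichment and
overdispersion in the range a well-separated snRNA-seq type structure
shows, strong enough that planted-marker recovery is expected but not
trivial. The size-world default in the acceptance checks is the 10:3
neuron/glia factor pair, and proportion sweeps span a neuron fraction of
0.25–0.80 over 17 points, the range the motivating brain experiments
cover. What the generator does **not** emulate: ambient RNA, doublets,
batch effects across samples, gene–gene correlation, or the zero
structure of droplet data. A green recovery test therefore establishes
the algebra and the solver, not robustness to real-data artifacts.

`generate_pseudobulk()` mixes at the *reference* level ($Y = ZSP$
exactly), matching the generative model; it does not sample individual
cells. Noise (Poisson or NB around the noiseless mean) is opt-in and off
by default, because the exact matrix product is what makes machine-
precision recovery a meaningful check. All randomness flows through one
seed per call, restored afterwards, so runs are reproducible and never
perturb the caller's RNG state.

## Metrics

Error is the entrywise absolute difference between known and predicted
proportions. RMSE follows the per-sample form
$\sqrt{\sum_k (P_{known}-P_{pred})^2 / K}$; because published summaries
rarely state how per-sample values are pooled, `evaluate_predictions()`
reports both the mean of per-sample RMSEs and the pooled form (square
root of the grand mean of squared errors), explicitly labelled. For
$K=3$ summaries a derived "neuron" entry as the sum of excitatory and
inhibitory predictions is supported via `rmse(..., combine = )`.
Correlation is Pearson, per cell type across samples, reported when at
least 3 samples exist and returned as NA when a margin is constant.

## Degenerate inputs and tolerances

Simplex membership is checked at $10^{-9}$; renormalization is always
explicit. Label alignment is by identifier, never by position, and
mismatches are errors naming the offending labels. All-zero bulk columns,
all-zero reference columns, empty gene intersections, zero-cell samples,
and zero minimum library sizes are labelled errors. Exact-recovery
assertions use $10^{-8}$, comfortably above accumulated floating-point
error at these problem sizes and far below any scientifically meaningful
proportion difference.

## Known limitations

* Per-type scalar sizes only; within-type size variation is not modelled.
* The NNLS registry ships two built-ins; published multi-sample or
  assay-bias-correcting algorithms are intended to be registered as
  external wrappers, not reimplemented here. Note that an algorithm which
  internally renormalizes its reference per column can absorb — and thus
  nullify — the diagonal rescaling; whether that happens is a property of
  the wrapped algorithm.
* Reference construction supports raw-count means (default) or any
  pre-normalized matrix the caller supplies; it does not itself normalize.
* Gene-identifier translation between annotation systems is out of scope.
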