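---
title: "Methods: the linearly decoded VAE in ldvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the linearly decoded VAE in ldvae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, the choices made
where the design was genuinely open, and what the synthetic benchmarks do
and do not establish. It states no empirical result that the test suite
does not itself compute.

## The generative model

Counts `y_ng` for cell *n*, gene *g* arise from

\[
z_n \sim \mathrm{N}(0, I_D), \qquad
s_n \sim \mathrm{logNormal}(s_\mu, s_\sigma^2), \qquad
\mu_n = \mathrm{softmax}(z_n W^\top),
\]
\[
v_{ng} \sim \mathrm{Gamma}(\text{shape} = \theta_g,\ \text{mean} = \mu_{ng}),
\qquad
y_{ng} \sim \mathrm{Poisson}(v_{ng}\, s_n).
\]

* `W` (genes × factors) is the loading matrix: the only map from the latent
  space to genes, hence the object that makes the model interpretable.
* `s_n` is the cell's exposure (count depth). Factoring depth out of
  `mu` is what lets `mu` be a proportion on the gene simplex.
* `theta_g` is a per-gene inverse dispersion (Gamma shape): the larger it
  is, the closer gene *g* is to Poisson. It is stored on the log scale as a
  free parameter, learned jointly and shared across cells, so positivity
  needs no constraint.
* The Gamma–Poisson emission is never sampled during inference: it is
  marginalized analytically to a negative binomial with mean
  `s_n * mu_ng` and inverse dispersion `theta_g` (`nb_log_pmf()`), which is
  exact and numerically stable. Sampling `v` happens only in
  `sample_generative()`.

**Softmax after the linear map.** The decoder is defined as
`softmax(z W^T)` rather than the bare linear map: the Gamma mean must be a
proportion for the exposure/depth factorization to make sense, so the
linear decoder replaces only the neural network inside the softmax. `W`
(the pre-softmax weights) is what `get_loadings()` reports. A consequence
worth knowing: adding a constant per factor to every gene's loading does
not change `mu` (softmax gauge), so loadings are identified only up to
column shifts — all subspace comparisons in the package center columns
first.

**Batch norm.** Optionally the logits `z W^T` are batch-normalized before
the softmax (the only placement that preserves the simplex output), with
learnable affine scale/shift, running statistics in evaluation mode, and
variance epsilon `1e-5`. `get_loadings()` folds the evaluation-mode scale
`gamma_g / sqrt(rvar_g + eps)` into the returned matrix, so the reported
loadings are exactly the slope of the evaluation-mode logit map — a
property the acceptance suite verifies on basis vectors.

**Logistic-normal latent.** The `"ln"` family pushes a *D*-dimensional
standard normal through a row-wise softmax, embedding cells in a simplex
(archetype-style, similar to semi-NMF). Because rows sum to one, the
centered covariance of the coordinates is singular: one factor is always a
linear combination of the others. `simplex_rank_check()` reports this
(relative eigenvalue tolerance `1e-8`, the float64 eigensolver noise
floor).

## Inference

The posterior is amortized: a multilayer perceptron (default one hidden
layer of 128 ReLU units on `log1p` counts — deliberately shared across all
decoder variants so that accuracy comparisons isolate the decoder) outputs
per-cell Gaussian parameters for `z` and `log s`. For the `"ln"` family
the Gaussian lives on the pre-softmax space and the KL term is computed
there; the softmax is applied to the sampled draw.

The objective is the standard single-sample ELBO: NB log-likelihood of the
batch under one reparameterized draw of `(z, s)` per cell, minus
`KL(q(z) || N(0, I))` and `KL(q(log s) || N(s_mu, s_sigma^2))`, both in
closed form (`kl_normal()`). The exposure prior `(s_mu, s_sigma)` is set
empirically per dataset to the mean and standard deviation of per-cell log
total counts — the established convention for this model family; the
spec-level alternative of fixing `s` to observed depth is not used, `s` is
inferred variationally. Optional KL warm-up (linear annealing over
`kl_warmup_epochs`) exists but is off by default, keeping the plain
objective.

All gradients are hand-derived reverse-mode expressions (`R/engine.R`);
`test-engine.R` checks every parameter block of all six model variants
against central finite differences.

## Training

`fit_ldvae()` runs seeded shuffled mini-batch Adam (defaults: learning
rate 1e-3, batch size 128 — unstated in the source material, standard for
this model family), records per-epoch train and held-out objectives, and
is bitwise reproducible for a fixed seed and configuration. The holdout is
a uniform random 10% of cells by default, drawn with a dedicated split
seed. `n_epochs = "auto"` applies the rule of thumb `max(1,
ceiling(1e6 / n_cells))`, using the full dataset size. Early stopping
(`patience`) is available but off by default: the reference protocol
trains a fixed number of epochs.

**Reconstruction error** (`heldout_reconstruction_error()`) is defined as
the mean per-cell negative NB log-likelihood at the variational mean
embedding — posterior locations for `z` and `log s`, no sampling noise —
so repeated evaluation is deterministic. The metric is a package
convention (the source material does not define one); all comparisons in
the tests use it consistently.

**PCA warm start.** The negative-ELBO landscape of the linear decoder is
multi-modal: with random `W` initialization most seeds settled into a mode
that represents one planted factor redundantly and drops another, visibly
worse in train ELBO, and neither KL warm-up, larger learning rates nor
doubled epochs escaped it. `fit_ldvae()` therefore initializes `W` at the
leading principal components of `log1p` depth-normalized counts (columns
scaled by the component standard deviation so unit-variance latents
reproduce the observed logit spread; computed on a seeded subsample of at
most 5000 cells). This is an initialization only — every parameter
remains free — and after it all tested seeds reach the same, better ELBO
mode. Users can reproduce cold starts via `init_ldvae()`.

## Interpretation conventions

* `center_scale()` centers columns and scales by the **sample** (N−1)
  standard deviation; zero-spread columns are centered, zeroed and
  flagged.
* `factor_covariance()` divides `Ẑ^T Ẑ` by N−1, making it a correlation
  matrix for non-degenerate columns. The normalization is a convention —
  ordering and rank statements are invariant to it.
* `order_factors()` sorts eigenvalues, reports eigenvalue/trace as
  variance explained, and attributes eigenvalue ranks to original factors
  greedily by dominant eigenvector component (ties and mixing make any
  attribution rule a convention; this one is documented and deterministic).
* `top_genes()` ranks by absolute (or signed) weight with lexicographic
  gene-identifier tie-breaks, so outputs are stable across runs.

## The synthetic world

`sim_scenario()` fixes a stated world: disjoint "program" gene blocks with
strong loadings of ±2 over a weak N(0, 0.1) background, per-gene
dispersions log-uniform in 1–20, and lognormal depths (median 1000
molecules, log-sd 0.4). The block design is the testbed for the
qualitative claim that factors align with co-expressed gene sets; the
weight magnitudes are fixture conventions. Sparsity is dialed through
exposure depth only (`calibrate_sparsity()`, bisection to ±0.02 of the
target on a seeded 1000-cell pilot) — *not* through zero-inflation, which
the model deliberately omits — and the targets used in tests (11% and 2%
non-zero) mirror deeply and shallowly sequenced atlas regimes.

`simulate_nonlinear_truth()` replaces the linear decoder with a random
one-hidden-layer tanh network. Its defaults (8 hidden units, input-weight
scale 5) were chosen by an independent criterion: the best affine fit of
the gene-centered true logits in `z` must leave a sizable share (~25%) of
their variance unexplained, otherwise the "nonlinear" truth would be
linearly approximable and comparisons against the linear decoder would be
vacuous. A test asserts this property of the generator itself.

What a green test does **not** establish: the generator draws i.i.d.
cells from the model's own family (plus the tanh variant), with no batch
effects, doublets, ambient RNA, cell-cycle structure or discrete cell-type
mixtures; real-data performance claims are out of scope here.

## Numerical choices

* Posterior log-scales are clamped to [−8, 5] (gradients masked when
  clamped); NB means are floored at 1e-10 so the objective stays finite
  when softmax underflows; softmax subtracts row maxima.
* NB–Poisson limit: the exact gap between the NB log-pmf at `theta = 1e6`
  and the Poisson log-pmf reaches 1.5e-4 at `y = 20`, `mean = 2`; tests
  assert the 1e-4 agreement one decade further out (`theta = 1e7`).
* Moment checks (variance = mean + mean²/θ and variance/mean → 1) are
  conditional statements; the tests realize them with near-degenerate
  latents and depth, where they hold marginally.
* Batch-norm training mode needs ≥2 cells; trailing 1-cell mini-batches
  are skipped for batch-norm models only. Running variance uses the
  unbiased correction, momentum 0.1.
* Genes with zero total count are kept: their `theta_g` and loading rows
  are trained like any other (no silent filtering), and the NB support
  keeps held-out likelihoods finite for genes unseen in training.

## Known limitations

* Single batch only; no covariate conditioning, no zero-inflation, no
  protein/CITE modalities, no importance-weighted bounds.
* One Monte Carlo sample per cell per step: gradient variance is handled
  by mini-batching, not by multi-sample estimators.
* Pure-R training is practical to roughly 10^5 cells × 10^2–10^3 genes at
  fixture scale; it is linear in cells but not competitive with
  GPU-backed implementations, and makes no wall-clock claims.
* The epoch rule of thumb is exposed as a heuristic
  (`recommended_epochs()`), not a convergence guarantee.
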