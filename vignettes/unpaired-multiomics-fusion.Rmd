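---
title: "Integrating unpaired transcriptome and methylation cohorts with omixfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating unpaired transcriptome and methylation cohorts with omixfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omixfuse)
```

## The problem

Bulk gene expression and DNA methylation are rarely measured on the same
individuals. Two case/control cohorts — one transcriptomic, one
epigenomic — therefore cannot be joined row-by-row, yet the disease
signal they carry is partly shared: a transcriptional program and the
promoter methylation that regulates it reflect the same underlying
biology. omixfuse implements a dual-channel autoencoder–Transformer
classifier that learns from such *unpaired* cohorts by pairing samples
combinatorially within diagnostic labels, and that explains its
predictions by counterfactual integrated-gradients attribution.

## Model

Each modality's gene-level vector $x$ is compressed by a two-layer
autoencoder encoder,

$$H_1 = \mathrm{ReLU}(W_1 x + b_1), \qquad
  Z = \mathrm{ReLU}(W_2 H_1 + b_2),$$

and decoded back through a ReLU hidden layer and a sigmoid output layer,
so reconstructions live in $(0,1)$ and inputs are min–max scaled to the
unit interval (beta values already are). The latent vector $Z$ of length
`n_tokens * d_model` is reshaped into a token sequence, given sinusoidal
positional encoding

$$PE_{(pos,2i)} = \sin\!\big(pos/10000^{2i/d_{model}}\big), \qquad
  PE_{(pos,2i+1)} = \cos\!\big(pos/10000^{2i/d_{model}}\big),$$

and refined by a stack of Transformer encoder layers: multi-head
self-attention $\mathrm{softmax}(QK^\top/\sqrt{d_k})V$, a
position-wise feed-forward network
$\max(0, xW_1 + b_1)W_2 + b_2$, residual connections and layer
normalization in post-norm order (sublayer, add, normalize). The two
encoder outputs are concatenated through a linear fusion layer; the
fused vector feeds

* an MLP classifier with a sigmoid head (case probability), and
* two modality-specific Transformer decoders — self-attention,
  cross-attention over fusion-derived memory tokens, feed-forward —
  whose outputs pass through the corresponding autoencoder decoder to
  reconstruct each modality *from the fused representation*.

Training minimizes a five-term loss: binary cross-entropy on the class
probability, one mean-squared reconstruction error per modality through
each modality's own autoencoder path, and one *cycle-consistency*
mean-squared error per modality through the fused decoder path. The
cycle terms couple the channels: the gradient of the expression cycle
loss is nonzero with respect to the methylation encoder (this is
asserted by a finite-difference test), which is what lets signal
transfer across modalities. A denoising input mask (each feature zeroed
independently with rate `mask_rate`, default 0.1, training only)
regularizes the autoencoders; the mechanism is a design reconstruction —
only its presence, not its form, is externally specified.

### Pairing and splits

Cohorts are first split by label into case/control subsets per modality;
training pairs are the Cartesian product of same-label subsets
(`enumerate_pairs()`), and mini-batches sub-sample this corpus: each
batch draws `rna_per_batch` expression samples without replacement and
pairs each with `meth_per_rna` same-label methylation samples. All
splitting — the 80/20 train/test split and the stratified
cross-validation folds — happens at the *sample* level per modality
before any pairing, so no sample ever contributes pairs to both sides of
a split; the test suite asserts this leakage-freedom on every fold.

### Two metric surfaces

Held-out evaluation is per-pair by default. Because a fused pair score
depends on *both* members, it carries partner noise that a
single-modality score structurally lacks; for comparisons across
modality conditions the package therefore also reports the
sample-level view, scoring each anchor sample by its mean predicted
probability over its test pairs (`metrics_sample`). The sample-level
view is the one comparable across conditions and corresponds to
reporting per-subject confusion matrices.

## Attribution

Integrated gradients assign feature $i$ the score

$$\mathrm{IG}_i(x) = (x_i - x'_i)\int_0^1
  \frac{\partial F\big((1-k)x' + kx\big)}{\partial x_i}\,dk,$$

with the counterfactual baseline $x'$ an all-zeros vector by default
("feature absent" after unit scaling; all-ones and custom baselines are
exposed). The integral is approximated on a straight-line path. Two
quadrature rules are available: the plain right-endpoint Riemann sum
over $j/n$, $j = 1..n$ (the form in which the discrete approximation is
usually written), and the default trapezoidal rule over $j/n$,
$j = 0..n$. The default is trapezoid because its $O(1/n^2)$ smooth-error
term keeps the completeness identity
$\sum_i \mathrm{IG}_i = F(x) - F(x')$ much tighter at moderate $n$;
both rules agree exactly on linear models (an exact-oracle test) and
converge to the same integral.

A numerical limitation is worth stating plainly: the completeness gap
equals the one-dimensional quadrature error of the directional
derivative along the path, and that derivative jumps wherever a ReLU
unit's pre-activation crosses zero. These jumps put an irregular error
floor of roughly $10^{-3}$ (absolute, probability scale) on any fixed
256-point rule — adaptive node placement does not help because the
jumps are dense and quasi-uniform along the path. For samples whose
output is far from the baseline output this is negligible; for samples
whose output happens to sit near $F(x')$ the *relative* gap is
ill-conditioned and can exceed a few percent. The gap shrinks with
`n_steps` (the suite checks convergence), so the axiom itself is
satisfied in the limit.

Per-sample scores are aggregated over samples by the unweighted mean of
absolute values (default) or the signed mean — the weighting of the
cross-sample average is not externally specified, so the simplest rule
is used and exposed.

One behavior matters for interpretation: correlated informative
features are interchangeable to a single trained model, which will rely
on an arbitrary subset of them and attribute only that subset. Stable
rankings therefore come from *averaging attributions across models* —
either across cross-validation fold models (`attribute_cv()`) or across
models trained under different conditions (the reference study
ensembles two fused fits with the two single-modality fits,
mean-normalizing each model's score vector before averaging). Rankings
are validated three ways: a sparse
L2-logistic classifier on the top-$k$ features against random,
variance, univariate-F and PCA selections; stepwise feature ablation
with retraining and size-matched random control bands; and a Pearson
co-expression network ($|r| > 0.75$) among top features.

## The synthetic cohort generator

`generate_unpaired_cohort()` draws two structurally unpaired cohorts
(independent sample sets, disjoint IDs — never a shuffled paired draw)
sharing a generative factor model. Factor 1 is the disease factor:
cases receive a `+effect_size` shift on it, and each modality's
informative features load on it exclusively with unit weight, so the
class-conditional mean difference of an informative feature equals
`effect_size` in expectation (on the logit scale for methylation, which
is generated as a logistic squash of the linear predictor plus a
per-feature baseline offset, keeping every value in $[0,1]$). The
remaining factors are standard-normal background shared by
non-informative features with weak random loadings, giving realistic
correlation structure without class signal.

Two dispersion choices are deliberate and fixed:

* the disease factor's within-class standard deviation is **0.4**, not
  1. It models shared biological heterogeneity, but kept small so that
  the *feature-level* effect size — the quantity the configuration
  actually promises — is the binding determinant of separability. With
  a unit-variance shared disease factor, the Bayes-optimal AUC under
  the default conditions would be capped near 0.85 regardless of the
  classifier, because all informative features would share one
  dominating noise source; the analysis
  $\mathrm{AUC}_{Bayes} \approx \Phi\!\big(\mathrm{eff}/\sqrt{2(\sigma_f^2 + 1/k)}\big)$
  makes the dependence explicit.
* per-feature noise is unit Gaussian; with the default effect size of
  1.5 this corresponds to strong, well-replicated cortical biomarkers.

What the generator does *not* emulate: probe-level microarray
artifacts, batch effects (beyond the optional per-batch mean-centering
hook), realistic genomic coordinates, or nonlinear feature-feature
interactions. Passing tests on this generator therefore demonstrate
that the pipeline recovers linear-factor class structure from unpaired
cohorts — not that it handles platform-specific technical variation.

## Reference desk-scale configuration

The documentation, tests and `scripts/acceptance.R` all use one
reference study so results are comparable:

* cohort: the `synth_config()` defaults — 200 expression / 120
  methylation samples, 400 genes, 20 informative features per modality,
  effect size 1.5, 5% missingness;
* architecture: autoencoder hidden width 64, latent 32 reshaped as 4
  tokens x 8 channels, 4 heads, 3 encoder layers, 1 decoder layer,
  feed-forward width 32, classifier hidden width 32, mask rate 0.1,
  all five loss weights 1;
* training: Adam at learning rate 0.001 with weight decay $10^{-4}$,
  plateau scheduler (factor 0.5, patience 5, floor $10^{-6}$) on the
  validation loss, 40 epochs with early stopping (patience 12), and
  best-epoch checkpoint selection by validation AUC with validation
  cross-entropy as tie-break. An inner validation set (25% of training
  samples, stratified) drives scheduling and selection.

These sizes were chosen so a single training run takes seconds to tens
of seconds on one CPU and the full cross-validation a couple of
minutes; the decoder depth of 1 (rather than mirroring the 3-layer
encoder) is part of the same desk-scale choice and is config-exposed
(`n_decoder_layers`).

```{r demo, eval = FALSE}
ref <- reference_cohort(seed = 1)
cv <- cross_validate(ref$rna, ref$meth,
                     cfg = reference_train_config(seed = 5))
cv$summary
```

## Numerical and design notes

* **Degenerate inputs.** Zero-variance features scale by 1 (z-score) or
  map to 0 (unit rescale); constant features are excluded from
  correlation networks with a warning; zero-denominator classification
  metrics report 0 with an explicit flag instead of `NaN`; predictions
  are clipped to $[10^{-7}, 1-10^{-7}]$ inside the cross-entropy.
* **Ties.** Equal scores share one ROC threshold step, which makes the
  trapezoidal AUC equal the Mann–Whitney concordance with ties counted
  one half (verified against a brute-force oracle and pROC).
* **Determinism.** Every stochastic stage derives its seed from the
  global seed and the stage name; two runs of the pipeline with the
  same configuration produce byte-identical metrics files. Training is
  single-threaded R, so no nondeterministic reductions exist.
* **Gradients.** The network is trained by a small reverse-mode
  autodifferentiation tape over dense matrices written for this
  package; every operator's backward pass, and the full composite
  graph, are tested against central finite differences.
* **TSS window convention.** CpG probes map to a gene when their signed
  TSS offset lies in $[-1500, 0]$ base pairs, negative meaning
  upstream; probes annotated to multiple genes are dropped as
  ambiguous.
* **Single-modality conditions** feed the withheld channel an all-zero
  placeholder and drop its reconstruction losses, leaving parameter
  counts comparable across ablation conditions.
* **Fine-tuning** freezes both autoencoders and the methylation
  channel, updating the expression Transformer encoder, the classifier
  head and (by default, flag-exposed) the fusion layer.

## Known limitations

* Pure-R training is practical at desk scale (hundreds of samples,
  hundreds of features) but not at full-cohort scale (tens of
  thousands of genes).
* The intra-label Cartesian pairing assumes the label is the only
  systematic link between cohorts; confounders shared across modalities
  (age, batch) are not modeled.
* Attribution completeness at fixed step counts is limited by ReLU
  kink noise as described above.
* The probe-collapse and TSS-window operations assume annotation tables
  are already on the correct genome build; no liftover is attempted.
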