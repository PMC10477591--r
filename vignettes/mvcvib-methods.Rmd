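---
title: "MV-CVIB: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MV-CVIB: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvcvib)
```

## The problem

Microbiome case/control cohorts are small (tens to a few hundred samples)
and wide (hundreds to thousands of taxa), and the data are compositional:
each sample is a vector of relative abundances summing to one, typically
with many structural zeros. Discriminative networks overfit such data
badly. The variational information bottleneck (VIB) counters this by
learning a *stochastic* code `U` that is predictive of the label while
being compressed toward an uninformative prior, with a Lagrange multiplier
`beta` trading the two pressures.

## Views

`mvcvib` feeds the classifier two representations of each sample:

1. **Abundance view** — the relative-abundance vector itself.
2. **Distance view** — the vector of Euclidean distances from the sample to
   every *training* sample. Neighbourhood structure is often more stable
   than individual taxon abundances in sparse compositional data, and the
   view costs nothing: it is derived from view 1.

Two design points deserve emphasis:

* **Full distance vector, not k-nearest-neighbours.** The second view is
  the complete row of the sample-by-training-sample distance matrix; no
  truncation parameter exists, so there is nothing to tune and the encoder
  input dimension is fixed at the training-set size.
* **Leakage control.** Distances are always computed against the training
  samples of the *current* fit — inside cross-validation, against the 4/5
  training portion of that fold. A held-out sample's view never includes
  distances to other held-out samples, and the input dimension is
  independent of the split. During training, each training sample's own
  zero self-distance is part of its row.
* **Square root.** `pairwise_euclidean()` returns true Euclidean distances.
  A `squared_distance` flag provides the plain sum of squared differences
  for users who prefer the squared form; the two are monotonically related,
  but the encoder sees different scales.

## Encoders, PoE fusion, decoder

Each view has a dedicated stochastic encoder producing a diagonal Gaussian
`N(mu_i, diag(sigma_i^2))` over the K-dimensional latent code:

* The abundance view is zero-padded to the smallest square `s^2`
  (`s = ceiling(sqrt(d))`), reshaped row-major to an `s x s` one-channel
  grid, convolved (8 filters of 3x3 by default, stride 1, zero padding that
  preserves size), passed through SiLU and a non-overlapping 2x2 max-pool,
  flattened, and then through three fully connected SiLU layers (512, 256,
  256 by default) with inverted dropout (p = 0.2) during training.
* The distance view skips the convolutional front end — its dimension is
  the number of training samples and carries no spatial arrangement — and
  uses the same three-layer fully connected head.
* The last layer emits `2K` numbers read as `(mu, logvar)` with
  `sigma = exp(logvar / 2)`. The log-variance link keeps the output
  unconstrained and makes the zero-weight encoder emit exactly the prior
  (`mu = 0`, `sigma = 1`).

The per-view posteriors are fused with the standard-normal prior by a
product of experts. For diagonal Gaussians the product is Gaussian with
summed precisions,

```
T = 1 + sum_i sigma_i^-2,  mu = (sum_i mu_i sigma_i^-2) / T,  var = 1 / T
```

so the joint is always at least as concentrated as every expert and the
prior — `poe_combine()` is checked against a grid-normalized density
product in the tests. An absent view simply drops out of the product, which
is how single-view mode works without any special casing.

One latent draw `u = mu + sigma * eps`, `eps ~ N(0, I)`, is taken per
sample per training step (the single-sample estimator of the expected
cross-entropy); at evaluation time `eps = 0`, i.e. the posterior mean is
decoded, making prediction deterministic. The decoder is logistic
regression `q(y = 1 | u) = sigmoid(w'u + b)`.

The objective is the mean binary cross-entropy plus `beta` times the mean
KL divergence of the *joint* (PoE) posterior from `N(0, I)` — the joint,
not a sum of per-view KLs, so the compression pressure acts on the code
actually decoded. The closed form
`0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)` is verified against a
Monte-Carlo estimator in the tests.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `latent_dim` (K) | 256 | dimension of the code U |
| `beta` | 1e-5 | compression weight; 0 recovers a plain stochastic classifier |
| `dropout_p` | 0.2 | inverted dropout after each hidden dense layer, training only |
| `hidden_sizes` | 512, 256, 256 | widths of the three dense layers, tapering toward 2K |
| `conv_channels`, `conv_kernel`, `pool_size` | 8, 3, 2 | convolutional front end of the abundance view |
| `learning_rate` | 1e-3 | Adam step size, full-batch updates |
| `max_epochs`, `patience` | 200, 20 | epoch budget and early-stopping patience per fold |
| `seed` | 42 | controls initialization, dropout masks, noise draws and splits |

The widths, optimizer and batch regime are package choices: cohorts at the
intended scale are tiny, so full-batch Adam is both simplest and fastest,
and the hidden widths taper from the input toward the `2K` output. The
convolution settings are deliberately minimal — one layer, small kernel —
since the grid is an artificial reshape of a 1-D profile; the front end
buys smoothing and weight sharing, not spatial semantics.

## Evaluation protocol

`train_mvcvib()` runs the protocol end to end:

1. **Stratified 8:2 split.** Per class, `round(n * 0.2)` samples (half-up,
   at least one when the class allows) go to the test set by a seeded
   within-class shuffle.
2. **Stratified 5-fold CV on the training set.** Within-class shuffle, then
   round-robin fold assignment with the counter running on across classes,
   so fold sizes differ by at most one and each fold's class mix is within
   one sample of the global proportions.
3. **Epoch selection.** Each fold trains with a fresh initialization; its
   validation AUC (deterministic pass) is recorded every epoch and the fold
   stops early after `patience` epochs without improvement, after which its
   last AUC carries forward (the fold's model is frozen, so later epochs
   remain comparable). The selected epoch maximizes the mean validation AUC
   across folds; ties go to the earliest epoch.
4. **Refit and test.** A fresh model trains on the full training set for
   the selected number of epochs and is scored once on the held-out test
   set with the rank-formula AUC.

AUC uses ascending midranks, making it exactly the normalized Mann-Whitney
statistic; ties contribute one half, which the tests pin against a
pairwise-concordance oracle.

Determinism is a contract: all randomness (splits, folds, initialization,
dropout, noise) derives from `config$seed`, and two runs with the same
configuration produce bit-identical evaluation records.

## The synthetic cohort generator

`generate_cohort()` emulates the output of an amplicon pipeline: per class
a base composition is drawn from a symmetric Dirichlet
(`concentration = 0.5`, giving the skewed profiles typical of 16S data);
class 1's informative taxa are enriched by a multiplicative `effect_size`
and renormalized; each sample is drawn from a Dirichlet centred on its
class composition with precision `concentration * n_taxa` (keeping
per-taxon spread comparable to the base draw); a `sparsity` fraction of
taxa is zeroed per sample and the row renormalized. The `separable_cohort`
preset (40/class, 100 taxa, 10 informative, effect 8, sparsity 0.3) is
strong enough that a leave-one-out centroid classifier already exceeds 0.8
AUC — establishing separability before the network is asked to find it —
while `effect_size = 1` gives an exchangeable null cohort.

What the generator does *not* emulate: phylogenetic correlation between
taxa, sequencing-depth variation, batch effects, or compositional bias from
extraction and PCR. Passing tests on these cohorts therefore demonstrate
that the implementation learns learnable signal and stays at chance on
null data — not that the model ranks well on any particular real cohort.

## Numerical choices and degenerate inputs

* Decoded probabilities are clamped to `[1e-12, 1 - 1e-12]` inside the log
  loss only; reported scores are the raw sigmoid outputs.
* Squared distances are clamped at zero before the square root to absorb
  negative round-off from the inner-product expansion.
* Zero-sum abundance rows are rejected by name at normalization; an
  all-zero simulated sample is redrawn (bounded retries).
* A non-finite loss aborts training with a diagnostic rather than
  continuing silently.
* Early stopping compares against the best AUC so far with a `1e-12`
  margin, so plateaus count as non-improvement.
* The problem sizes exercised in the tests and the acceptance script — the
  80-sample presets, five seeds per arm, a toy batch for the gradient
  check — were chosen as the smallest cohorts at which the protocol's
  behaviour (discrimination, null calibration, ablation direction) is
  stable and quick to verify.

## Known limitations

* Binary labels only; no multi-class decoder.
* Views are derived from one abundance table; additional modalities
  (markers, metabolomics) would each need an encoder, though the PoE
  fusion already supports any number of experts.
* Full-batch training assumes cohorts of at most a few hundred samples.
* The hand-written backpropagation covers exactly the published
  architecture; arbitrary layer graphs are out of scope.
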