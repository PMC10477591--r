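# mvcvib

Binary disease-state classification from gut-microbiome relative-abundance
profiles with a **multi-view convolutional variational information
bottleneck (MV-CVIB)**. The package is aimed at microbiome studies with few
samples and many taxa — e.g. distinguishing metastatic from non-metastatic
colorectal cancer from 16S rRNA feature tables — where a stochastic,
compressed latent representation regularizes far better than a plain
discriminative network.

## The model

Each sample is observed through `V` views `x¹, …, x^V`. View 1 is the
relative-abundance vector itself; view 2 is the vector of Euclidean
distances `d(a, b) = √Σᵢ(aᵢ − bᵢ)²` from the sample to every *training*
sample — a nearest-neighbour representation computed from the abundance
data, so no extra assay is needed and test samples never leak into the
reference set.

Each view has a dedicated stochastic encoder emitting a diagonal Gaussian
posterior `q̃(u | xⁱ) = N(μᵢ, diag σᵢ²)` over a K-dimensional latent code.
The abundance view is zero-padded to the smallest square, reshaped to an
`s × s` grid, and passed through a 2-D convolution + max-pool before three
SiLU fully connected layers; the distance view uses the fully connected
stack alone. The per-view posteriors are fused with the standard-normal
prior by a **product of experts** — for diagonal Gaussians, precisions add:

```
T = I + Σᵢ σᵢ⁻²,   μ = (Σᵢ μᵢ σᵢ⁻²) / T,   σ² = 1 / T
```

A latent sample `u = μ + σ ⊙ ε`, `ε ~ N(0, I)` (the reparameterization
trick) is decoded by logistic regression `q(y = 1 | u) = σ(wᵀu + b)`, and
training minimizes the information-bottleneck objective

```
J = (1/N) Σₙ E_ε[ −log q(yₙ | uₙ) ]  +  β · KL[ q(U | xₙ¹, …, xₙ^V) ‖ N(0, I) ]
```

with `K = 256` and `β = 10⁻⁵` by default. Evaluation follows a stratified
8:2 train/test split with stratified 5-fold cross-validation on the
training set: the epoch with the best mean validation AUC (rank-formula /
Mann–Whitney AUC, midranks for ties) is selected, the model is refit on the
full training set for that many epochs, and the held-out test AUC is
reported. The whole network — encoders, convolution, PoE fusion, and exact
backpropagated gradients with Adam — is implemented in base R matrix code
and verified against finite differences and independent oracles in the test
suite.

## Worked example

```r
library(mvcvib)

# A synthetic cohort: 40 samples per class, 100 taxa, 10 informative taxa
# enriched 8-fold in class 1, 30% structural zeros.
cohort <- separable_cohort(seed = 1)
fit <- train_mvcvib(cohort$table, cohort$labels, mvcvib_config(seed = 1))
fit
#> <mvcvib_fit>
#>   views:      abundance + distance
#>   train/test: 64 / 16 samples
#>   best epoch: 23 (mean validation AUC 0.970)
#>   test AUC:   1.000
```

The printout reports the class-stratified split (8 test samples per class),
the epoch chosen by cross-validation, and the AUC on the 16 held-out
samples. Ablations are one flag away: `mvcvib_config(multi_view = FALSE)`
drops the distance view, `use_conv = FALSE` drops the convolutional front
end.

Real data enter through files:

```r
tab  <- normalize_relative_abundance(read_abundance_table("abundance.tsv"))
meta <- read_metadata("metadata.tsv", c("mCRC" = 1, "non-mCRC" = 0))
al   <- align_samples(tab, meta)
fit  <- train_mvcvib(al$table, al$labels)
```

A command-line front end wraps the same functions
(`system.file("cli", "mvcvib.R", package = "mvcvib")`):

```sh
Rscript mvcvib.R simulate --preset separable --seed 1 --out cohort/
Rscript mvcvib.R train --abundance cohort/abundance.tsv \
    --metadata cohort/metadata.tsv --out run/ --seed 1
Rscript mvcvib.R evaluate --checkpoint run/checkpoint.rds \
    --abundance cohort/abundance.tsv --metadata cohort/metadata.tsv --out eval/
```

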