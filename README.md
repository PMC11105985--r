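# subgenrecon

Reconstruction of high-dimensional MR images — accelerated multi-echo T2
mapping and SNR-limited spectroscopic imaging (MRSI) — that combines three
complementary constraints: an explicit low-rank **subspace model**, a
subject-adapted **generative image prior**, and **joint-sparsity**
regularization. The package is a complete desk-scale laboratory for the
method: it simulates multi-contrast phantom acquisitions, pretrains and
adapts a miniature style-based generator, and reconstructs by alternating
minimization with intermediate-layer network inversion.

## The model

A multi-echo or spectroscopic image series is written as a Casorati matrix
`ρ ∈ C^{N×T}` and factored as `ρ ≈ U V̂`, where `V̂` (R orthonormal rows,
R ≪ T) is a temporal basis predetermined from navigator k-space lines and
`U` are the unknown spatial coefficients. With multi-coil Cartesian
measurements `y_c = Ω F S_c ρ + n`, the reconstruction solves

```
min_{U, w_t}  Σ_c ‖y_c − Ω F S_c U V̂‖²
            + Σ_t λ₁,t ‖(U V̂)_t − Φ_t ⊙ G_θ̂(w_t)‖²_F
            + λ₂ ‖D U V̂‖₂,₁
```

alternating between (I) inversion of the generator `G_θ̂` against the
current frames — staged intermediate-layer optimization with l1-ball latent
chaining across adjacent echoes — and (II) a convex coefficient update
solved by conjugate gradients (IRLS for the `ℓ2,1` term). The generator is
pretrained adversarially on a phantom image corpus and adapted once per
subject to a reference image (the sum-of-squares of an initial subspace
reconstruction); afterwards only its latents move, so the prior tracks
contrast changes without overfitting the data. The spectroscopic variant
anchors the coefficient maps `U_r` with magnitude-times-phase network
products and uses an edge-weighted quadratic penalty, with the
field-inhomogeneity phase `B` inside the encoding operator.

## Worked example

```r
library(subgenrecon)

# 1. population prior: pretrain on 300 synthetic contrast images (~4 min CPU)
corpus <- phantom_corpus(300, 64, seed = 42)
prior  <- pretrain_generator(generator_spec(resolution = 64, output = "magnitude"),
                             corpus, steps = 300, batch = 8, seed = 42)

# 2. one accelerated T2-mapping experiment: 48x48, 16 echoes, AF 4, 1% noise
d <- t2_benchmark_data(seed = 1, AF = 4)

# 3. reconstruct with the four standard pipelines
suite <- t2_method_suite(prior)
for (m in names(suite)) {
  out <- suite[[m]](d$kspace, d$basis, d$truth)
  series <- if (inherits(out, "recon_state")) out$series else out
  cat(sprintf("%-18s %.3f%%\n", m, relative_l2(series, d$truth)))
}
```

Output from this exact run (relative l2 error of the reconstructed series
against the noiseless truth; smaller is better):

```
subspace           3.073%
subspace+sparsity  2.970%
subspace+gan       1.954%
proposed           1.835%
```

The plain subspace solve is limited by undersampling noise amplification;
the tiny joint-sparsity weight trims it slightly; the adapted generative
anchor roughly halves the error; and the full method (anchor plus sparsity)
is best. Fitting `PD·exp(-TE/T2)` voxelwise to the reconstructed series
(`fit_t2()`) quantifies the same ordering in T2-map error.

The command-line pipeline (`inst/cli/subgenrecon`) chains the same steps:
`simulate`, `pretrain`, `adapt`, `recon`, `evaluate`.

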