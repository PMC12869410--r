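# ptgmm

Structural heterogeneity analysis for cryogenic electron microscopy
(CryoEM) particle images, built on a Gaussian-mixture-model (GMM)
representation of protein density and a **point-transformer decoder**.

## The problem and who this is for

A CryoEM data set contains many two-dimensional projections of a
molecule frozen in different states: whole segments may be present or
absent (compositional heterogeneity, e.g. assembly intermediates), and
domains may move continuously (conformational heterogeneity). `ptgmm`
is for methods developers and structural biologists who want a
self-contained, fully seeded R implementation of GMM-based
heterogeneity analysis: simulators with complete ground truth, the
training and inference machinery, accuracy metrics, and an
interpretability workflow that segments the structure into regions with
correlated dynamics.

## The model

Density is a mixture of `N` isotropic 3-D Gaussians with centres `c_i`
(box units), amplitudes `a_i` and widths `sigma_i`. An
encoder-decoder pair is trained without labels: the encoder maps each
particle's low-frequency, phase-flipped Fourier coefficients to a
latent conformation code `z`; the decoder maps `z` to per-Gaussian
changes `(dc_i, da_i, dlog sigma_i)` applied to a fixed neutral model,

    c_i + dc_i,   a_i * clamp(1 + da_i, 0, 2),   sigma_i * exp(dlog sigma_i),

and the forward model projects the deformed mixture analytically in
Fourier space (each Gaussian contributes
`a 2 pi sigma^2 exp(-2 pi^2 sigma^2 |k|^2) exp(-2 pi i k.(c_xy + s))`,
`k` in cycles/box), multiplies by the CTF, and scores the particle with
a negative Fourier-ring-correlation loss

    L = -mean_r  Re<P_r, O_r> / (||P_r|| ||O_r|| + eps).

The decoder is the core contribution: vector self-attention over a
precomputed k-means point hierarchy (64/256/N points by default), with
learned relative-position encodings, inverse-distance transition-up
between levels, residual branches from the intermediate levels straight
to the full GMM, and a pointwise 5-channel head. A plain MLP decoder
with identical output activations is included as the baseline. All
gradients are implemented in the package and checked against finite
differences; hot kernels are compiled (RcppArmadillo) with pure-R
reference implementations kept for cross-checks.

The decoder output doubles as an interpretability substrate: embedding
each Gaussian's across-particle amplitude profile to 2-D and
density-clustering it groups Gaussians that change together — the parts
of the molecule that assemble or move as one unit. Focusing a second
embedding of the *particles* on one region isolates that region's
states.

## Worked example

Simulate a 9-segment toy complex in which 8 peripheral segments each
vanish independently in half the particles, train the point-transformer
model, measure ground-truth accuracy, and segment the GMM into regions:

```r
library(ptgmm)

res <- run_compositional_benchmark(seed = 1, n_particles = 2048, D = 48,
                                   n_gaussians = 256, snr = 2,
                                   epochs = 24, verbose = TRUE)

res$sim
#> <comp_simulation> 2048 particles, 9 segments, 256 distinct states
res$accuracy
#> <amplitude_accuracy> 95.2% at threshold 0.50 over 8 segments
res$match$n_matched
#> [1] 8
table(res$regions$region)
#>  1  2  3  4  5  6  7  8  9
#> 30 30 20 65 32 19 19 20 21
```

Read: the simulator realised all 256 compositional states; after 24
epochs of unsupervised training the decoded amplitude gate classifies
segment presence per particle with 95.2% accuracy at the 0.5 cutoff;
and DBSCAN on the 2-D embedding of per-Gaussian amplitude profiles
recovers 9 clean regions — the core (region 4, 65 Gaussians) plus all
8 toggleable segments — without manual intervention.
`autoplot(res$regions)` draws the embedding, and
`focus_embed_particles(res$outputs, res$regions, region = 1, k = 2)`
classifies particles by the presence of one region;
`class_difference_volume()` renders the difference map between two
classes.

The same surface drives continuous motion:
`run_motion_benchmark(seed = 3)` simulates rigid swinging of a domain
with uniformly distributed angles and reports per-particle motion RMSD
against the rigid no-motion baseline (`motion_rmsd()`).

A thin command-line interface wraps the same functions
(`simulate-comp`, `simulate-motion`, `train`, `infer`, `evaluate`,
`segment-gmm`, `focus`, `diffmap`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ptgmm.R", package = "ptgmm"))')" \
    simulate-comp --out /tmp/toy --n 2048 --size 48 --snr 2 --seed 1
```

Every command writes a provenance JSON and reproduces its outputs
bit-identically under one seed.

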