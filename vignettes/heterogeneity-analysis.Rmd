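---
title: "Point-transformer decoding of GMM-based CryoEM heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-transformer decoding of GMM-based CryoEM heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ptgmm)
```

## The model

A protein density map is represented as a Gaussian mixture model (GMM):
$N$ isotropic 3-D Gaussians with centres $c_i$ (box-normalized
coordinates in $[-0.5, 0.5]$), non-negative amplitudes $a_i$ and widths
$\sigma_i$. A *neutral* GMM — the consensus, average-state model — is
seeded once from a segmented structure by k-means
(`seed_gmm_from_structure()`). Per-particle structural states are
expressed relative to it: a decoder network maps a low-dimensional
latent code $z$ to per-Gaussian changes
$(\Delta c_i, \Delta a_i, \Delta\log\sigma_i)$, and
`apply_deltas()` produces that particle's GMM with

* centres $c_i + \Delta c_i$,
* amplitudes $a_i \cdot \mathrm{clamp}(1 + \Delta a_i,\, 0,\, 2)$,
* widths $\sigma_i \exp(\Delta\log\sigma_i)$.

The amplitude gate is linear around its neutral value 1 and reaches
exactly 0 at its floor, so a fully absent segment is representable; a
sigmoid gate cannot reach 0, which matters when scoring presence/absence
against ground truth. All three channels come out of bounded (scaled
tanh) activations so early training cannot throw centres out of the box.

Training is unsupervised. For particle image $x$ with known orientation
$R$ and CTF, the forward model projects the decoded GMM analytically in
Fourier space — a Gaussian at $c$ contributes
$a\, 2\pi\sigma^2 e^{-2\pi^2\sigma^2 |k|^2} e^{-2\pi i k\cdot(c_{xy} + s)}$
per frequency $k$ (cycles/box) — multiplies by the CTF, and compares
with the observed particle through a Fourier ring correlation (FRC)
loss:
$$\mathcal{L} = -\frac1R \sum_{r=1}^{R}
  \frac{\mathrm{Re}\langle P_r, O_r\rangle}{\|P_r\|\,\|O_r\| + \epsilon}.$$
The loss is invariant to per-ring positive rescaling, so neither the CTF
envelope nor an overall intensity scale has to be estimated. Ring
weights are uniform up to a configured cutoff (`max_ring`); the DC ring
carries no correlation information and is excluded. Per-ring SNR
weighting is a plausible refinement that we deliberately did not adopt
to keep the loss assumption-free; the cutoff plays the role of a crude
band-pass.

Both encoder and the forward model are differentiable end to end; the
package implements reverse-mode gradients for every stage (validated
against finite differences in the test suite) and trains with Adam under
a cosine learning-rate decay. All randomness — weight initialisation,
shuffling, simulation noise — derives from explicit integer seeds, and
retraining with one seed is bit-reproducible on a fixed BLAS.

## The point-transformer decoder

The decoder is the interesting part. Instead of an MLP that treats the
$N \times 5$ output as a flat vector, the point-transformer (PT) decoder
treats the Gaussians as a point cloud and uses vector self-attention
over local neighbourhoods:

1. **Point hierarchy.** Because the decoder only outputs *changes*
   relative to the neutral GMM, the point geometry is shared by all
   particles. `build_hierarchy()` precomputes k-means point sets of
   increasing size (defaults 64/256/$N$; the toy benchmarks use
   32/96/256), per-level k-nearest-neighbour tables (`k_attn = 16`) and
   inverse-distance interpolation tables (3 nearest coarse points per
   fine point, weights summing to 1).
2. **Latent seed.** A two-layer MLP maps $z$ to a `(B, 64, C)` tensor
   assigned to the coarsest level's points.
3. **Attention blocks.** At each level,
   $y_i = \sum_{j \in N(i)} \mathrm{softmax}_j\!\big(\gamma(\varphi(x_i)
   - \psi(x_j) + \delta_{ij})\big) \odot (\alpha(x_j) + \delta_{ij})$
   with position encoding $\delta_{ij} = \theta(p_i - p_j)$ (two-layer
   MLP) and a residual connection. The softmax is channel-wise (vector
   attention), $\gamma$ is a one-hidden-layer MLP.
4. **Transition up.** Features move to the next finer level by
   inverse-distance interpolation of linearly projected features.
5. **Residual branches.** The outputs of the first two levels are also
   upsampled *directly* to the full GMM (32 channels each by default),
   concatenated with the final level's features, and passed through a
   pointwise dense head with 5 output channels per Gaussian.

Channel widths (256/128/64 by default, descending with level size),
the residual width, and $\gamma$'s hidden width are engineering choices;
the hierarchy sizes and the `(B, 64, 256)` seed tensor follow the
published architecture. The pointwise head is shared across Gaussians,
consistent with point-cloud practice. An MLP decoder
(`init_mlp_decoder()`, three hidden layers) with identical output
activations is kept as the baseline; both decoders are plug-compatible
with the trainer, evaluator and interpretability stages, so comparisons
isolate the architecture.

The attention block and the projection kernels have compiled
(RcppArmadillo) implementations used by default; the plain-R reference
implementations remain in the package and the tests assert exact
agreement between the two.

## The simulators and what they do (and do not) emulate

`make_toy_structure()` builds a download-free segmented pseudo-molecule:
a large core blob and `n_segments - 1` compact blobs on a spherical
shell, sizes varied ±20%, non-overlap enforced (centroid separation at
least three blob radii, otherwise rejected).

*Compositional heterogeneity* (`simulate_compositional()`): every
non-core segment is independently absent with probability 0.5 per
particle. With 8 toggleable segments this yields 256 equally likely
states; 12,800 particles cover all of them with overwhelming
probability.

*Conformational heterogeneity* (`simulate_motion()`): chosen regions
rotate rigidly about fixed axes by independent per-particle angles,
uniform on $[-a/2, a/2]$. The default toy axes are anchored between core
and blob, perpendicular to the blob direction, so blobs swing rather
than spin. The range $a$ is calibrated with
`calibrate_angle_range()` so the expected mean per-particle atomic RMSD
hits a target (closed form for one region,
$E[\mathrm{RMSD}] = 2\sqrt{\sum r_a^2 / M}\cdot 4(1 - \cos(a/4))/a$;
low-discrepancy quadrature for several). The toy benchmark targets
2.5 Å: large enough that the no-motion baseline is a meaningful
contrast, small enough that the required per-Gaussian displacements stay
well inside the decoder's bounded output and the FRC loss basin — the
toy's short lever arms need very large rotation angles per Ångström of
RMSD, and beyond roughly ±40° the motion leaves the convergence basin
of a correlation loss. The published-scale recipe records the
transporter value of 2.23 Å, which that molecule's much longer lever
arms reach with small rotations.

`render_particles()` draws orientations from a deterministic
low-discrepancy sequence on the rotation group (Halton triples through
the uniform-quaternion map) — "evenly distributed" rather than i.i.d. —
splats atoms as small Gaussians through the same analytic Fourier model
used in training, applies a CTF with defocus uniform over a range, and
adds white Gaussian noise scaled to a target SNR (signal variance /
noise variance). What this does **not** emulate: structural noise,
colored/ice background, beam-induced motion, detector MTF, orientation
errors, or CTF estimation errors — so passing benchmarks here shows the
method recovers heterogeneity under an idealised image model with known
poses, not that it is robust to the full pathology of real micrographs.

Simulated SNR, box and pixel size are not prescribed by the study
design; the toy benchmarks use SNR 2-4 ("high SNR"), 32-48 px boxes and
3-4 Å pixels, recorded in `run_compositional_benchmark()` /
`run_motion_benchmark()`.

## Evaluation

`amplitude_accuracy()` maps each Gaussian to its nearest atom
(`map_gaussians_to_atoms()`, ties to the lowest atom index), predicts
"present" when the decoded gate is at least 0.5, and pools accuracy over
Gaussians of toggleable segments (core Gaussians have constant truth and
are excluded by default; `include_core` restores them). It also returns
the two histograms of gate values split by true presence. Under a
random-gate null with absence probability 0.5 the expected accuracy is
exactly 0.5 regardless of the gate distribution, a property the tests
exploit.

`motion_rmsd()` transfers each atom's predicted displacement from its
nearest Gaussian's $\Delta c$ (a kNN-weighted variant was considered and
left out for transparency — with one Gaussian per atom the transfer is
exact, which the tests use), and reports per-particle RMSD over all
atoms plus the no-motion baseline, which equals the ground-truth
movement magnitude.

## Region segmentation and the divide-and-conquer workflow

The decoder output is itself a data set: one amplitude (or motion
magnitude) per Gaussian per particle. `build_feature_matrix()` collects
per-Gaussian profiles across a seeded subsample of at most 2,000
particles and z-scores each row, so clustering responds to the *pattern*
of co-variation, not its depth. Gaussians whose amplitudes rise and fall
together across particles — parts assembled or moving as one unit — form
clusters.

`segment_gmm()` embeds the profiles in 2-D and density-clusters the
embedding. The embedding is a UMAP-style fuzzy kNN graph layout
implemented in the package (no R implementation of UMAP is available):
smooth-kNN bandwidths calibrated to $\log_2 k$ effective neighbours,
fuzzy-union symmetrization, attraction along graph edges under the
standard $1/(1 + a d^{2b})$ curve. Two deliberate departures from the
reference algorithm, made so that seeded runs are *exactly*
reproducible and row-permutation-equivariant: repulsion is evaluated
deterministically over all pairs (scaled to the equivalent
negative-sampling budget) instead of by random negative sampling, and
exact duplicate rows are collapsed into one layout entity and
re-expanded afterwards (identical profiles otherwise acquire arbitrary,
index-dependent neighbourhoods). Initialisation is the first two
principal components with a fixed sign convention.

DBSCAN (also implemented here) picks `eps` from the sorted 4-NN distance
curve: the largest relative jump in the top quarter of the curve
separates isolated points from the within-cluster scale; absent such a
jump every point is treated as core. The naive endpoint-chord knee was
tried first and collapses when many embedded points nearly coincide —
exactly what near-perfect decoder outputs produce. Degenerate
all-noise clusterings fall back to a single region with a warning.

`focus_embed_particles()` then embeds *particles* using only the chosen
region's outputs and classifies them by k-means; for a continuously
moving region the embedding forms a one-dimensional curve tracking the
rotation angle. `class_difference_volume()` renders the per-class mean
GMMs (`render_volume()`) and subtracts them; rendered GMM volumes stand
in for particle-based reconstructions by design — they are exact and
fast at these scales — with naive direct-Fourier backprojection of raw
particles deliberately out of the acceptance path.

## Numerical choices and degenerate inputs

* Fourier images are `(D/2+1) x D` half-planes in cycles/box with the
  centring phase absorbed, so analytic values match DFTs of centred
  images; conversions are exact round trips (`fourier_from_image()` /
  `image_from_fourier()`).
* The CTF uses the common underfocus-positive, leading-minus convention;
  one function serves simulator and trainer so the convention cannot
  drift.
* FRC rings with an all-zero argument contribute 0 (an
  $\epsilon$-guarded denominator).
* k-means steps (GMM seeding, hierarchy, classification) use 10 restarts
  under a fixed seed; inverse-distance interpolation snaps to a
  coincident coarse point.
* The encoder consumes phase-flipped Fourier coefficients up to a cutoff
  (default $D/4$ cycles/box; the prior-work prescription is kept as a
  config value), scaled by one global factor recorded in the model.
* Training aborts with a diagnostic on a non-finite loss; `infer()`
  rejects stacks whose image size disagrees with the checkpoint.

## Problem sizes used by the shipped benchmarks

The package's own desk-scale study conditions (also used by the
acceptance script): compositional — 9 segments, 2,048 particles, 48 px
box at 3.33 Å/px, SNR 2, defocus 1–2 µm, 256 Gaussians, PT levels
32/96/256 with channels 32/24/16, latent dimension 8, FRC rings ≤ 16,
24 epochs of Adam (lr 2e-3, cosine decay, batch 32); motion — one
swinging region, 768 particles, SNR 10, 192 Gaussians, latent 2,
mean-RMSD target 2.5 Å, amplitude/width activation scales 0.3/0.1, FRC
rings ≤ 12, 30 epochs. The motion loss stops at ring 12 because a
192-Gaussian mixture cannot represent the atom-splat images beyond
roughly that band; with higher rings included, the per-particle pose
couples the unfittable residual into the gradients and the decoder
acquires a position wobble on static parts that dominates the motion
error.
On these conditions the pipeline reaches ~0.95 amplitude accuracy and
recovers all 8 toggleable regions without manual intervention; the
published-scale recipes (12,800 particles, 1,024 Gaussians, levels
64/256/1024) are recorded as configuration objects
(`fullscale_compositional_recipe()`, `fullscale_motion_recipe()`) and
need the corresponding segmented atomic models plus far longer training.

## Known limitations

* The image model is idealised (white noise, perfect poses and CTF);
  conclusions transfer to real data only qualitatively.
* Isotropic single-width Gaussians; no anisotropy, no map-based seeding
  from experimental density.
* The embedding is a compact reimplementation tuned for reproducibility,
  not a drop-in UMAP; its layouts are similar in character but not
  numerically comparable.
* Training on CPU limits practical sizes to a few thousand particles and
  a few hundred Gaussians; the architecture itself scales, the R/BLAS
  backend is the constraint.
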