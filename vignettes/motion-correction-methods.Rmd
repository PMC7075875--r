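---
title: "Multishot motion simulation, CG-SENSE and adversarial correction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multishot motion simulation, CG-SENSE and adversarial correction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multishot MRI covers k-space in $S$ separate excitations ("shots").
Between shots the subject can move; each shot then samples the Fourier
transform of a *differently positioned* object, and the assembled k-space
is internally inconsistent.  The result is ghosting and blurring in the
reconstructed image.  `mrimoco` implements a retrospective pipeline for
in-plane rigid motion: simulate the corruption, reconstruct the corrupted
data with CG-SENSE, and remove the residual artifacts in the image domain
with a conditional adversarial network.  Everything runs on synthetic
phantoms, so the whole pipeline is testable without any external data.

## Forward corruption model

For shot $s$ with rigid parameters $(\theta_s, t_s)$, sampling mask $u_s$
and coil sensitivities $\{S_c\}$, the acquired multi-coil k-space is

$$ y \;=\; \sum_{s=1}^{S} \; u_s \odot F\!\left( S_c \cdot M_s x \right), $$

where $M_s$ rotates the object by $\theta_s$ about the image center and
translates it by $t_s$, and $F$ is the centered orthonormal 2D DFT.  The
per-shot masks partition the grid, so with zero motion the sum collapses
to the clean encoding exactly — a property the tests check with exact
equality, not a tolerance.

Choices that the model family leaves open, fixed here:

* **Motion is applied in image space** before Fourier encoding (not as
  k-space phase ramps), with bilinear interpolation and zero fill outside
  the frame.  Rotation is about the image center with the half-pixel
  convention for even grids.  The identity transform short-circuits to
  the input, so zero-motion paths are bitwise exact.
* **Shot 1 always carries zero motion**: "relative rotation between
  shots" needs a reference frame, and the first excitation defines it.
* **Motion schedules.** `constant_increment` ramps linearly from 0 to
  $\Delta\theta$ across shots, so consecutive shots differ by a constant
  rotation; `random_uniform` draws each shot's parameters independently
  from $U(-\Delta\theta, \Delta\theta)$ (shot 1 forced to zero).  Both
  are first-class because the experimental literature is ambiguous about
  which pattern is meant by "varying degrees of rotational motion";
  `constant_increment` is the default.
* **FFT convention.** Centered, orthonormal ($1/\sqrt{N^2}$ each way).
  Orthonormality makes the encoding operator's adjoint equal its inverse
  on fully sampled single-coil data, keeps CG well scaled, and lets the
  adjoint tests demand $10^{-10}$ relative accuracy.
* **Coils.** Sensitivities are simulated: Gaussian magnitude profiles
  centered on a circle around the field of view with a gentle linear
  phase per coil, normalized so $\sum_c |S_c|^2 = 1$ exactly at every
  pixel.  Real reference-scan estimation is out of scope; the default
  count of 8 matches a common head-coil configuration and is
  configurable.

## Encoding trajectories

Four per-shot sampling schemes are provided, all exact partitions of the
$N \times N$ grid: contiguous row blocks (`cartesian_sequential`), row
interleaving (`cartesian_parallel_1d`), a 2D lattice decimation
(`cartesian_parallel_2d`), and a balanced random assignment of individual
points (`random`).  Two conventions had to be fixed: rows are the
phase-encode direction; and the 2D lattice generalizes to arbitrary $S$
by factoring $S = a \times b$ with $a \le b$ and $a$ the largest divisor
not exceeding $\sqrt S$ (a square lattice whenever $S$ is a perfect
square).  When $S$ does not divide $N$, remainder rows go to the earliest
shots.  The random scheme deals a seeded permutation of grid points into
near-equal chunks, which mirrors the practice of giving every excitation
the same readout budget.

## CG-SENSE reconstruction

Reconstruction solves the SENSE normal equations
$(E^H E)\,x = E^H y$ by conjugate gradient, applying $E$ and $E^H$
implicitly through FFTs — the pseudo-inverse
$(E^H E)^{-1} E^H$ is never formed.  Numerical policy:

* initialization at the adjoint image $x^0 = E^H y$;
* optional Jacobi-style preconditioning by the inverse coil-intensity
  profile $1/\sum_c |S_c|^2$ — an exact no-op for the package's
  normalized simulated coils, kept as a hook for unnormalized maps;
* stopping at relative residual $10^{-6}$ or 50 iterations by default
  (no iteration budget is canonical for this method; these defaults are
  fixed for reproducibility and are configurable);
* the returned image is the magnitude of the complex solution rescaled
  to $[0, 1]$, which is what the corrector consumes.

Because the trajectories partition k-space, the simulated systems are
fully sampled and $E^H E$ is the identity up to coil normalization: CG
converges immediately, and the motion artifacts — not undersampling —
are what remains in $x_m$.  The solver is nevertheless a general CG and
is verified, on undersampled single-shot masks where $E^H E$ is a
nontrivial positive-definite operator, against a dense direct solve at
$N = 16$ to $10^{-6}$ relative error.

## The adversarial corrector

The corrector is a conditional GAN.  The generator $G$ is a residual
U-Net: encoder blocks of five convolutions with feature counts
$(n, n, n/2, n, n)$, stride 2 on the first layer of each block, a
residual connection from the first to the last layer of the block, and
leaky-rectifier activations (slope 0.2); decoder blocks mirror this with
four stride-1 convolutions and a stride-2 transposed convolution as the
last layer; symmetric skip connections concatenate each encoder block's
output onto the matching decoder block's input; a final 1-channel
convolution with a sigmoid keeps outputs in $[0, 1]$.  The discriminator
$D$ is exactly the generator's encoder stack plus a global-average-pool,
one affine unit and a sigmoid.

Within that stated design a few details are necessarily this package's
own: kernels are $3 \times 3$; no normalization layers are used inside
blocks (the residual and skip connections are the stated convergence
mechanism); the decoder's in-block residual spans the four stride-1
layers, because the fifth layer changes resolution and cannot be the
residual's endpoint; and the discriminator head is the simplest scalar
head consistent with "same as the encoder".

**Losses.**  With $x_m$ the artifact image and $x_c$ the clean target,

$$ \mathcal{L}_G \;=\; \big\| x_c - G(x_m) \big\|_2
   \;+\; \lambda \, \log\!\big(1 - D(G(x_m))\big), $$

batch-averaged, with the data term the *unsquared* per-image L2 norm,
and the standard cross-entropy objective for $D$.  Two deliberate
choices: $\lambda = 0.6$ by default, the midpoint of the
adversarial-weight region ($> 0.5$) that wins on validation in this
model family; and the generator's adversarial *gradient* uses the
non-saturating form (ascend $\log D(G(x_m))$) while the *reported* loss
keeps the definition above — the saturating form provides almost no
gradient early in training.  Probabilities are clamped to
$[10^{-7}, 1 - 10^{-7}]$ before any logarithm.

**Training schedule.**  RMSProp for both networks at learning rate
$10^{-4}$, batch size 16, two discriminator updates per generator
update, and Adam pretraining of the generator on the data term alone —
these full-scale defaults are kept in `train_config()`.  Training is
deterministic per seed on CPU; checkpoints are single RDS files that
reload to bit-identical forward outputs.

The engine behind this is a compact CNN stack written for this package:
im2col/col2im data movement in C++ with BLAS matrix products, and
hand-derived backpropagation verified against central finite differences
to $10^{-4}$ relative error in the test suite.

## Quality metrics

Against a reference $r$: PSNR $= 20\log_{10}(\max(r)/\sqrt{\text{MSE}})$
(identical images return `Inf` rather than an error, since the
zero-motion pipeline produces exact recoveries); SSIM with an
$11 \times 11$ Gaussian window ($\sigma = 1.5$), $k_1 = 0.01$,
$k_2 = 0.03$ and unit data range — the constants of the reference SSIM
formulation; a uniform window is available behind a flag since the
windowing scheme is not canonical.  Artifact power is
$\sum(|r| - |x|)^2 / \sum |r|^2$, which depends on magnitudes only.
PSNR uses $\max(r)$ over the actual reference rather than a fixed
data-range constant.  All three are pinned to independent brute-force
implementations in the tests.

## The phantom generator

Phantoms are randomized soft-edged ellipse composites inside a bright
elliptical "skull" ring, normalized to $[0, 1]$: piecewise-smooth,
anatomy-like structure with sharp-but-smooth boundaries, deterministic
per seed, and — because the ring is elliptical and the interior is
random — never invariant under rotation, so every simulated motion
changes the image.  They emulate what matters to this pipeline:
magnitude brain-like slices whose Fourier data respond realistically to
rigid motion.  They do **not** emulate tissue-specific contrast,
pathology, noise texture, partial-volume effects, or 3D continuity
across slices; a corrector trained on them demonstrates that the method
works, not that its weights transfer to clinical data.  An optional
NIfTI path (`load_volume()`, `preprocess_slice()`) applies the standard
preparation — center crop to the smaller square, bilinear resize,
per-slice max normalization, and discarding of blank (all-zero) slices —
to real volumes.  A slice counts as blank exactly when its maximum
intensity is zero; no threshold is involved.

## Desk-scale study conditions

The heavy tests and the acceptance script run one fixed desk-scale task:
128 training and 32 held-out pairs of $32 \times 32$ phantoms with
$\Delta\theta = 5°$, $S = 4$, random trajectory and 8 coils; a 2-block
U-Net with 16 base features; Adam pretraining for 600 steps at
$2\times10^{-3}$; then 500 adversarial steps with RMSProp at $10^{-4}$,
$\lambda = 0.6$, batch 4.  These problem sizes are the package's chosen
trade-off between statistical stability of the checks (seed-majority
over three seeds) and a test suite that runs in minutes on one CPU; the
artifact-power ordering check uses 32 phantoms at $64 \times 64$ with
$S = 16$.  The transfer check warm-starts this task from a model trained
at $S = 16$ and uses the validation-loss early-stopping hook in
`train()` to measure steps-to-target.

## Known limitations

* In-plane rigid motion only: no through-plane or non-rigid motion, and
  no noise model beyond the motion itself.
* Cartesian grids only; no spiral/radial trajectories or
  variable-density sampling, and no ordering effects within a shot.
* No regularized SENSE, field-inhomogeneity correction, or gridding.
* The corrector operates on magnitude images (one channel); complex or
  k-space-domain networks are out of scope.
* Full-scale (e.g. $128 \times 128$, 64 base features) configurations
  are provided but training them to convergence is a compute commitment
  the test suite deliberately does not make.
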