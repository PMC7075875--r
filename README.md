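# mrimoco

Retrospective rigid-motion correction for multishot MRI, end to end and
self-contained: simulate per-shot motion-corrupted multi-coil k-space,
reconstruct it with CG-SENSE, correct the residual artifacts with a
conditional adversarial network, and quantify the result — all on
synthetic brain-like phantoms, with no external data required.

**Who it is for.** Researchers and students working on MRI motion
artifacts who want a reproducible test bed: a controllable forward model,
a verified SENSE solver, a trainable image-domain corrector, and the
standard quality metrics, each usable on its own.

## The model

In a multishot acquisition with $S$ shots, inter-shot rigid motion
$M_s$ (rotation $\theta_s$ about the image center plus in-plane
translation) corrupts the assembled k-space

$$ y \;=\; \sum_{s=1}^{S} u_s \odot F\big(S_c \cdot M_s x\big), $$

where $u_s$ are disjoint per-shot sampling masks that together cover the
grid (four trajectories: Cartesian sequential, 1D/2D interleaved,
random), $S_c$ are sum-of-squares-normalized coil sensitivities and $F$
the centered orthonormal 2D DFT.  The artifact image $x_m$ is obtained
by solving the SENSE normal equations $(E^H E)x = E^H y$ with conjugate
gradient, and a conditional GAN — a residual U-Net generator $G$ against
an encoder-shaped discriminator $D$ — is trained to map $x_m$ back to
the clean image by minimizing

$$ \|x_c - G(x_m)\|_2 \;+\; \lambda \log\big(1 - D(G(x_m))\big), $$

with $\lambda = 0.6$, RMSProp, two $D$ updates per $G$ update, and Adam
pretraining of $G$ on the data term.  Quality is reported as PSNR,
SSIM and artifact power $\mathrm{AP} = \sum(|r|-|x|)^2 / \sum|r|^2$.
The network engine (convolutions, transposed convolutions, backprop,
Adam/RMSProp) is built into the package on BLAS matrix products with
C++ data-movement kernels; see the methods vignette
(`vignettes/motion-correction-methods.Rmd`) for every design decision.

## Worked example

```r
library(mrimoco)

phantom <- generate_phantom(64, seed = 7)
coils   <- simulate_coil_maps(8, 64)
scheme  <- make_scheme("random", n_shots = 16, grid_size = 64, seed = 1)
motion  <- make_motion("constant_increment", n_shots = 16, max_rotation = 5)

kspace  <- forward_corrupt(phantom, motion, scheme, coils)
recon   <- cg_sense_reconstruct(kspace, coils)
recon
#> <cg_result> 64 x 64 image, 0 CG iterations, final rel. residual 4.14e-16

cat(sprintf("PSNR %.2f dB  SSIM %.3f  AP %.5f\n",
            psnr(phantom, recon$image),
            ssim(phantom, recon$image),
            artifact_power(phantom, recon$image)))
#> PSNR 30.72 dB  SSIM 0.911  AP 0.00757
```

Five degrees of inter-shot rotation at 16 shots leaves visible ghosting:
the reconstruction sits at 30.7 dB with an artifact power of 7.6e-3
relative to the motion-free phantom (with zero motion the same pipeline
recovers the phantom to machine precision — "0 CG iterations" because
the partitioned trajectories make the system fully sampled, so the
adjoint start is already the solution).  Training the corrector on such
pairs is one call:

```r
ds    <- make_paired_dataset(128, 32, delta_theta = 5, n_shots = 4,
                             scheme_name = "random", seed = 101)
model <- train(ds,
               train_config(learning_rate = 1e-4, batch_size = 4,
                            pretrain_steps = 600,
                            pretrain_learning_rate = 2e-3, seed = 11),
               unet_config(n_blocks = 2, base_features = 16,
                           input_size = 32))
fixed <- correct(model, ds$corrupted)
```

A YAML-driven command-line wrapper for the full experiment grid
(simulate / reconstruct / train / correct / evaluate / report) is
installed at `inst/cli/mrimoco.R`.

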