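# sphfod

Voxel-wise estimation of white-matter **fiber orientation distributions
(FODs)** from **reduced multi-shell diffusion MRI**, using a rotationally
equivariant spherical convolutional network (sCNN) operating in the
spherical-harmonic (SH) domain — together with the full scaffolding needed
to exercise it end to end without any external data: a multi-shell dMRI
simulator, a spatial-domain training loss, an MLP baseline, angular
evaluation metrics, NIfTI/bval/bvec IO, and a command-line interface.

## Who this is for

Researchers in diffusion MRI methods who want a compact, fully inspectable
reference implementation of SH-domain equivariant convolution for FOD
estimation — e.g. to study how much the SO(3)-equivariant inductive bias
buys over an unstructured regressor when the acquisition is shortened to
~30% of its directions (19/26/38 directions at b = 400/1000/2600 s/mm²,
emulating a reduced neonatal protocol).

## The model

Every spherical function is a length-45 vector of real, symmetric,
even-degree SH coefficients (lmax = 8, MRtrix3-compatible ordering). The
network maps the three per-shell SH fits of a voxel's signal to its FOD:

- **Equivariant spherical convolution**: one learnable scalar per
  (out-channel, in-channel, even degree l), shared across all orders m —
  `y[c_out, (l,m)] = Σ_c_in W[c_out, c_in, l] · x[c_in, (l,m)]` — which
  commutes exactly with SH rotation operators (block-diagonal Wigner-style
  matrices, verified to 1e-10 in the tests). Bias on l = 0 only.
- **Shell attention**: global average pooling over the SH dimension →
  48-vector → 24-unit Leaky ReLU layer → 3 softmax weights that rescale the
  shells before fusion.
- **Encoder–decoder** of such convolutions (16 → 32 → 64 → 32 → 16
  channels) with the spatial-domain nonlinearity ISFT → LeakyReLU → SFT
  between layers, then a small fully connected head (batch norm + ReLU)
  emitting the 45 FOD coefficients.
- **Loss**: mean squared amplitude difference after projecting both SH
  vectors onto an N-point sphere sampling (equals SH-distance/4π on tight
  samplings). AdamW, lr 1e-3 halved every 17 epochs, gradient clipping at
  global norm 10, decoupled weight decay 1e-4.

The simulator plants 1–3 fiber populations per voxel (crossing angles
≥ 40°), builds ground-truth FODs as band-limited fiber deltas, synthesizes
shell signals by Funk–Hecke convolution with an axially symmetric tensor
kernel, and adds Rician noise (default SNR 20).

## Worked example

```r
library(sphfod)

# 5,000-voxel phantom at SNR 20, reduced 83-direction protocol
ph <- generate_phantom(5000, snr = 20, seed = 1,
                       split = c(train = 0.8, val = 0.1, test = 0.1))
ms <- fit_per_shell_sh(ph$dwi, ph$protocol)    # [5000 x 3 x 45] input
ds <- list(x = unclass(ms), y = ph$fod_sh, split = ph$split)

model <- scnn_model(nonlin_n = 96, seed = 2)
res <- train_model(model, ds, train_config(epochs = 20, seed = 3))

tst <- ph$split$test
pred <- fod_field(scnn_forward(res$best_model, unclass(ms)[tst, , ]))
evaluate_fields(pred, fod_field(ph$fod_sh[tst, ]), ssim = FALSE)
```

This two-minute run prints:

```
Global scalar:
  MSE   1.233056
  SSIM  NA
  PSNR  16.02 dB
FOD-wise:
  ACC            0.5751 +/- 0.2416
  Mean ang. err  14.29 +/- 16.10 deg
  Peak match     0.792 (20 deg)
500 voxels, 0 invalid, 0 ACC-excluded
```

Reading it: `MSE` is the mean squared SH-coefficient distance to the
simulated ground truth; `ACC` is the mean cosine similarity between
reconstructed FOD amplitude profiles (1 = identical shape); the angular
error is the antipodal angle between principal FOD peaks; `Peak match` is
the fraction of voxels whose principal peak lands within 20° of the true
fiber. Twenty epochs on 4,000 training voxels already recover the dominant
fiber in ~4/5 of voxels. The acceptance suite trains on 20,000 voxels for
20 epochs, reaching mean angular error ≈ 11.8° and peak match ≈ 0.86, and
compares against the 4×256 MLP baseline trained with 5× more batches
(see the methods vignette for what ACC can and cannot reach against sharp
delta-function ground truth).

The same pipeline is scriptable from the shell:

```sh
Rscript inst/cli/sphfod simulate --out data --n-voxels 2000 --seed 1
Rscript inst/cli/sphfod train --data data --out run --epochs 10 \
    --nonlin-n 96 --seed 2
Rscript inst/cli/sphfod predict --dwi data/dwi.nii.gz --bvals data/bvals \
    --bvecs data/bvecs --mask data/mask.nii.gz \
    --model run/checkpoint_best.rds --out pred.nii.gz
Rscript inst/cli/sphfod evaluate pred.nii.gz data/fod_gt.nii.gz \
    --mask data/mask.nii.gz --out report.json
```

## Further reading

`vignettes/fod-estimation-methods.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, what
the simulator does and does not emulate, numerical choices, and known
limitations.
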