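# grrdb

Denoising of terahertz (THz) reflectance images of grain with **G-RRDB**, a
dense-residual convolutional network that combines three module families
around an ESRGAN-style residual-in-residual dense block (RRDB) trunk:

* **Ghost-LKA** — large-kernel attention (5×5 depthwise → 7×7 depthwise
  dilated, dilation 3 → 1×1 pointwise, applied as a multiplicative
  attention map) fused with a ghost convolution (few "intrinsic" maps from
  a real convolution, the rest from cheap depthwise operations);
* **RRDB** — densely connected convolution blocks with inner and outer
  residual connections, each residual scaled by β = 0.2;
* **DAB** — a dual-attention block that gates spatial-attention and
  channel-attention branches against a convolutional feature branch:
  `W⊙s1 + Xout⊙(1−W) + W⊙s2 + Xout⊙(1−W)` with `W = sigmoid(local + global)`.

The intended users are researchers working on image-quality pipelines for
THz (or similar single-channel intensity) imaging who need a fully
inspectable, CPU-only reference implementation: the package ships its own
reverse-mode automatic differentiation engine with RcppArmadillo
convolution kernels, a synthetic wheat-kernel phantom generator with
calibrated noise models (real THz wheat data being confidential), PSNR and
SSIM (Gaussian window 11, σ 1.5, k₁ = 0.01, k₂ = 0.03) metrics, a training
loop (Adam, lr 10⁻³, batch 8, 9:1 stratified split), an ablation runner
(baseline / baseline+DAB / G-RRDB) and a graded-noise robustness harness
(20/30/40/50 dB).

## Worked example

Generate paired phantoms at 30 dB, train a desk-scale model (16 channels)
for 5 epochs, and evaluate on the held-out split:

```r
library(grrdb)

pairs <- generate_pairs(50, phantom_config(),
                        noise_spec("awgn_snr", snr_db = 30), master_seed = 1)
sp  <- split_dataset(pairs, ratio = 0.9, seed = 0)
ids <- vapply(pairs, function(p) p$id, character(1))

model <- build_grrdb(desk_config(), seed = 0)
fit <- grrdb_train(model, pairs[ids %in% sp$train_ids],
                   train_config(epochs = 5, seed = 0))

evaluate_model(NULL, pairs[ids %in% sp$test_ids])        # noisy input
evaluate_model(fit$model, pairs[ids %in% sp$test_ids])   # denoised
```

On this synthetic benchmark the two calls print

```
 mold_level n  psnr_db      ssim        # noisy input
          0 5 45.22987 0.9469323
          1 5 47.32904 0.9606994
          2 5 48.74159 0.9707572
          3 5 50.81548 0.9812649
 mold_level n  psnr_db      ssim        # denoised
          0 5 50.31211 0.9994218
          1 5 52.98918 0.9998151
          2 5 54.32370 0.9998153
          3 5 56.38951 0.9998243
```

The rows are the four mold-contamination grades (0 = normal … 3 =
seriously moldy; higher grades have darker kernel interiors, hence less
signal power and — at a fixed SNR — less absolute noise). The trained
network improves mean PSNR by ≈ 5.5 dB over the noisy input and lifts
SSIM from ≈ 0.96 to ≈ 0.9997. (The published results on the confidential
real THz wheat data — PSNR ≈ 35.9 dB, SSIM ≈ 0.98 — are not reproducible
from synthetic phantoms; the desk-scale experiment verifies the
architecture and training loop, not real-data performance.)

A command-line interface wraps the same functions:

```sh
inst/cli/grrdb generate --out data/ --n-per-level 25 --snr-db 30 --seed 1
inst/cli/grrdb train    --data data/ --out run/ --channels 16 --epochs 5
inst/cli/grrdb denoise  --checkpoint run/checkpoint.rds --in img.tif --out img_dn.tif
inst/cli/grrdb describe --channels 64
```

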