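# retinasr

Super-resolution and five-grade severity classification of retinal fundus
images, implemented as a pure R + Rcpp package with no external
deep-learning runtime.

## The problem

Diabetic retinopathy (DR) is graded on fundus photographs into the five ICDR
severity levels — no DR (0), mild (1), moderate (2), severe (3)
non-proliferative DR, and proliferative DR (4) — from lesions that are often
only a few pixels wide: microaneurysms, hemorrhages, exudates, and
neovascular tufts. `retinasr` implements a two-stage pipeline for this
problem:

1. **HLG-RetinaSR**, a hybrid local–global super-resolution network (×2):
   a point-wise/3×3/point-wise feature extractor feeds a stack of HLG blocks
   — each combining a deformable-convolution local path (ALM), an
   inter-pixel non-local attention path (IPGM), and a 2×2-patch transformer
   path (PSGM) — whose outputs are aggregated by 1×1
   compress–concatenate–fuse feature reuse and reconstructed through a pixel
   shuffle added to a bicubic upsample of the input. Trained with the MSE
   loss `L(θ) = (1/N) Σ_k ||I_k^HR − I_k^SR||²`. An SRCNN-style baseline
   (two 3×3/64 convolutions → 4×4 stride-2 transposed convolution → 3×3
   reconstruction, 224×224 → 448×448) is included.
2. **RefineNet-U**, a U-Net classifier: four conv/BN/ReLU encoder blocks
   (64/128/256/512 filters at full scale) with 2×2 max pooling, a 1024-filter
   bridge, a mirrored transposed-convolution decoder with skip
   concatenations, and a flatten → dropout(0.3) → dense(128, LeakyReLU) →
   dense(5) → softmax grading head, trained with categorical cross-entropy.
   A plain CNN baseline is included.

All forward *and backward* passes (convolution, transposed convolution,
batch normalisation, deformable bilinear sampling, non-local and multi-head
attention, pixel shuffle) are implemented in the package (R + Rcpp/BLAS),
verified against finite differences and brute-force oracles. A seeded
synthetic-fundus generator produces graded phantoms — vessel trees,
microaneurysms, hemorrhages, exudates, neovascular tufts — so the whole
pipeline trains and evaluates with no data download. Evaluation utilities
implement the 5×5 confusion matrix, accuracy/precision/recall/F1/specificity,
MSE/PSNR, global-moment SSIM, and one-vs-rest ROC AUC.

## Worked example

```r
library(retinasr)

# a graded synthetic fundus phantom (grade 3: many microaneurysms,
# hemorrhages and exudates)
rec <- generate_fundus(3, phantom_params(image_side = 192L), seed = 7)
rec$lesion_inventory
#> microaneurysm    hemorrhage       exudate     neovessel
#>            14            10             3             0

# build LR/HR pairs and train a tiny SR model (~100 optimisation steps)
pairs <- make_sr_pairs(lapply(1:88, function(i)
  generate_fundus((i - 1) %% 5, phantom_params(image_side = 192L),
                  seed = 5000 + 17 * i)), scale = 2)
st <- train_sr("hlg", pairs[1:80],
               config = list(epochs = 10, batch = 8, lr = 1e-3, crop = 32,
                             hlg = hlg_config(channels = 16, n_blocks = 2)),
               seed = 42)
round(range(st$loss_history), 5)
#> [1] 0.00750 0.00912               # per-epoch MSE in the [-1, 1] range

# the model against its own bicubic baseline, paired over 8 held-out images
gains <- sapply(81:88, function(i) {
  p <- pairs[[i]]
  enh <- sr_enhance(st, p$lr)
  bic <- gray_image(pmin(pmax(resize_image(p$lr, c(192, 192), "bicubic")$pixels,
                              0), 255))
  psnr(enh, p$hr) - psnr(bic, p$hr)
})
round(mean(gains), 4)
#> [1] 0.1319                        # dB; positive on every held-out image
```

The example above is real output from the code at the shown settings (the
per-image gains were 0.18, 0.14, 0.13, 0.11, 0.08, 0.14, 0.14, 0.13 dB;
mean held-out PSNR 28.638 vs 28.506 for bicubic). A note on honesty: the
five-grade classifier trains end to end the same way, but at the time budget
of the test suite it reaches ~0.57 test accuracy against the 0.85 acceptance
bar — see the methods vignette for the analysis.

## Command line

The `retinasr` script is installed under the package's `exec/` directory
(`system.file("exec", "retinasr", package = "retinasr")`); symlink it onto
your PATH or call `retinasr::retinasr_cli(c("synth", ...))` directly.

```sh
retinasr synth --n-per-grade 10 --side 448 --seed 1 --out data/
retinasr preprocess --in data/manifest.csv --out pre/ --config cfg.json
retinasr train-sr --model hlg --pairs pre/manifest.csv --seed 1 --out runs/sr
retinasr enhance --model-ckpt runs/sr/sr_model.rds --in pre/ --out enhanced/
retinasr train-clf --model refinenet_u --manifest enhanced/manifest.csv --seed 1 --out runs/clf
retinasr grade --model-ckpt runs/clf/clf_model.rds --in enhanced/ --out preds/
retinasr evaluate --pred preds/predictions.csv --truth data/manifest.csv --out report/
```

`--config` takes a JSON file with sections `preprocess`/`sr`/`classifier`/
`synth`/`eval` (no YAML parser is available in this environment).

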