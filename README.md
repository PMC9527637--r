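# cardioEM

Quantifying cardiomyocyte ultrastructure in 3D electron microscopy —
segmentation, generative modelling and morphometry, on one CPU.

Volume EM (FIB-SEM / SBF-SEM) shows the building blocks of heart muscle
cells — mitochondria, myofibrils and the thin Z-discs bounding each
~2 µm sarcomere — but the stacks are huge, low-contrast and costly to
annotate. `cardioEM` is an R implementation of a complete analysis
workflow for such data, built for method development and teaching at desk
scale:

1. **Phantom generation** — synthetic cardiomyocyte volumes
   (intensity + ground-truth labels) with periodic sarcomere banding,
   sparse Z-disc planes (< 1 % of voxels, matching the extreme class
   imbalance of real data) and ellipsoidal mitochondria between
   myofibrils. Every downstream stage is testable without any image
   download.
2. **Segmentation** — a modified U-net (four encoder and four decoder
   blocks around one densely connected bottleneck with trainable linear
   units; nine blocks in total) ending in a 4-channel softmax
   `p_n(x) = exp(a_n(x)) / Σ_n' exp(a_n'(x))` over background,
   mitochondria, myofibrils and Z-disc. The network and its
   backpropagation are implemented directly in R (im2col + BLAS) and
   verified against finite differences.
3. **Evaluation** — confusion-matrix metrics plus the border-thinned,
   foreground-restricted Rand and information-theoretic scores used in
   EM segmentation challenges.
4. **Generative modelling** — a label-conditioned style-based GAN over
   segmentation slices (mapping network, learned constant start, style
   modulation, per-convolution noise, slice-pair label embedding),
   trained unshuffled and monitored by Fréchet inception distance with a
   pluggable feature extractor; the minimum-FID checkpoint is returned.
5. **Assembly** — ordering generated slices into a 3D stack by
   minimizing consecutive Jaccard distance (exact Held–Karp optimum for
   ≤ 10 slices, greedy chain-extension beyond), e.g. 25 slices at 0.4 µm
   spacing into a 10 × 10 × 10 µm volume.
6. **Morphometry** — per-component volume, surface area, SA:V,
   compactness `C = 36πV²/S³`, sphericity `ψ = C^{1/3}`, elongation
   `√(λ1/λ2)`, flatness `√(λ2/λ3)`, spareness; sliding 4 µm / 0.4 µm
   mito:myo density kernels; one-way ANOVA comparison of shape-metric
   distributions between volumes.

## Worked example

```r
library(cardioEM)

## a phantom with ground truth (2 µm sarcomeres, 0.1 µm Z-discs)
ph <- generate_phantom(phantom_config(seed = 11))
print(ph)
#> <PhantomVolume>
#> <LabelVolume> 128 x 256 x 256 voxels (z,y,x), voxel size 0.02 x 0.02 x 0.02 um
#>   classes: 0:6747118 1:1163495 2:429765 3:48214
#>   Z-disc voxel fraction: 0.575%

## train a small U-net on 64 px patches and segment a held-out slice
fp <- extract_patches(ph$intensity, 64, 30, seed = 1)
ds <- patch_dataset(ph, fp, make_split(1:30, c(20, 5, 5), seed = 1)[[1]])
spec <- unet_spec(input_size = 64, base_channels = 8,
                  n_encoder_blocks = 2, n_decoder_blocks = 2,
                  dense_layers = 2, growth = 8)
fit <- train_unet(build_unet(spec, seed = 0), ds,
                  train_config(epochs = 15, seed = 0))
pred <- predict_volume(fit$net, vol_data(ph$intensity)[128, , , drop = FALSE],
                       tile = 64, overlap = 16)
1 - jaccard_distance(vol_data(pred$labels) > 0,
                     vol_data(ph$labels)[128, , , drop = FALSE] > 0,
                     "foreground")
#> [1] 0.93   # pooled-foreground Jaccard on the held-out slice

## shape statistics of the mitochondria
comp <- label_components(ph$labels, class_id = 1)
stats <- shape_stats(comp, voxel_size_um = ph$labels$voxel_size_um)
summary(stats$sphericity)
```

The printed numbers mean: the Z-disc class really is rare (0.58 % of
voxels — segmenting it alone is a heavily imbalanced problem), and the
small U-net recovers ~93 % of the pooled foreground on an unseen slice
after a minute of CPU training. `stats` holds one row per mitochondrion
with its volume, surface area, SA:V, compactness, sphericity, elongation,
flatness and spareness.

A GAN round-trip is one call chain away:

```r
recs <- build_slice_pair_records(slice_stack(vol_data(ph$labels)[, 1:32, 1:32]))
gcfg <- gan_config(resolution = 32, n_pair_labels = length(recs),
                   iterations = 200, seed = 0)
run <- train_gan(build_gan(gcfg), recs)       # FID-monitored, unshuffled
gen <- generate_model_volume(run$gan, n_seeds = 25)  # 10 x 10 x 10 um volume
```

A thin command-line wrapper for the phantom/eval/assemble/morpho/density
steps is installed at `inst/cli/cardioem.R`.

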