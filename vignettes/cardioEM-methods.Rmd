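---
title: "Models and methods behind cardioEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardioEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardioEM)
```

# The problem

Volume electron microscopy (FIB-SEM, SBF-SEM) resolves the ultrastructure
of cardiomyocytes — mitochondria, myofibrils and the thin Z-discs that
delimit sarcomeres — at nanometre resolution, but the stacks are large,
low-contrast and expensive to annotate. cardioEM implements a desk-scale
version of a workflow that (i) segments the three ultrastructure classes
plus background with a single multi-class U-net, (ii) learns the
statistical structure of the segmented slices with a conditional
style-based generative model monitored by Fréchet inception distance
(FID), (iii) reassembles generated 2D slices into 3D volumes by minimizing
the Jaccard distance between consecutive slices, and (iv) quantifies both
real and generated volumes with per-object 3D shape statistics and
sliding-kernel composition maps.

Everything runs on one CPU. Every stage is exercised end-to-end on
synthetic phantoms, so the package needs no external image data.

# The synthetic cardiomyocyte phantom

`generate_phantom()` builds a label volume and a matching intensity
volume:

* **Myofibrils** (class 2) are bundles of roughly 0.5 µm width running
  along the x axis, occupying `myofibril_fill_fraction` of the
  cross-section.
* **Z-discs** (class 3) are planes of thickness `zdisc_thickness_um`
  (default 0.1 µm, a realistic Z-disc width) repeating every
  `sarcomere_period_um` (default 2 µm, the canonical resting sarcomere
  length) along the fibril axis, present only inside myofibrils.
* **Mitochondria** (class 1) are axis-aligned ellipsoids with jittered
  semi-axes, rejection-sampled (at most 1000 retries each) into the
  inter-myofibril space; they never overwrite myofibrils or Z-discs.
* **Intensity** is the per-class mean from `contrast_map` plus clipped
  Gaussian noise. The default means are deliberately close together
  (background 0.55, myofibril 0.45, mitochondria 0.30, Z-disc 0.15 with
  noise SD 0.08) to emulate the low contrast of EM.

Because every sarcomere boundary carries one Z-disc plane, the Z-disc
voxel fraction is `fill_fraction × thickness / period`. With the fixed
2 µm period and 0.1 µm thickness this equals `fill/20`, so the default
fill fraction of 0.15 yields ≈ 0.75 % Z-disc voxels — reproducing the
< 1 % class prevalence that makes Z-disc segmentation a textbook
imbalanced-learning problem. That imbalance target, not volumetric
realism, drove the default: real cardiomyocytes have denser myofibril
packing, but a denser phantom could not keep the Z-disc class this rare
at realistic Z-disc geometry.

What the phantom does **not** emulate: anisotropic EM point-spread and
shot noise, membrane texture inside organelles, curved or branching
myofibrils, t-tubules/SR/nuclei, and registration artefacts between
slices. Tests passing on phantoms therefore demonstrate the correctness
and trainability of the machinery, not segmentation accuracy on real
tissue.

`degrade_labels()` (exact-count random class flips) and
`translate_slice_sequence()` (a slice sequence with uniform consecutive
Jaccard distance) provide controlled imperfect predictions and orderable
stacks for the evaluation and assembly stages.

# The modified U-net

`unet_spec()` defaults describe the full-scale architecture: 512 × 512
input, 64 feature channels in the first block, four encoder blocks, one
bottleneck and four decoder blocks (nine blocks in total), 2 × 2
max-pooling with stride 2, channel doubling per encoder block and halving
per decoder block, and a 4-channel softmax output
\(p_n(x) = e^{a_n(x)} / \sum_{n'} e^{a_{n'}(x)}\) over background,
mitochondria, myofibrils and Z-disc. The bottleneck is densely connected:
each of its convolutions consumes the concatenation of all previous
bottleneck features, and uses trainable linear units (TLUs) — per-channel
two-slope piecewise-linear activations that reduce to the rectifier when
the negative slope is 0 and to the identity when both slopes are 1.

Choices that the architecture description leaves open are fixed as
follows, as package defaults (all configurable):

* **Loss**: categorical cross-entropy — the canonical pairing with a
  multi-class softmax output.
* **Optimizer**: Adam at learning rate 1e-3, the standard choice for
  U-nets.
* **Dense bottleneck**: 4 layers with growth = `base_channels`,
  concatenative connectivity, followed by a 1 × 1 transition convolution
  to the doubled channel count.
* **TLU form**: two trainable slopes per channel (negative branch
  initialized at 0.25, positive at 1), the parametric-rectifier family.
* **Upsampling**: nearest-neighbour 2 × 2 followed by a 3 × 3
  convolution.
* **Skip merging**: channel concatenation (the U-net convention).
* **Tiling at prediction**: overlapping tiles with probability averaging
  before the argmax; inputs smaller than a tile require an explicit
  `pad = "reflect"` policy.

The network, including backpropagation, is implemented directly in R on
top of im2col + BLAS convolutions; gradients are verified against central
finite differences in the test suite. No data augmentation is applied.

Training runs in the tests use a reduced spec (64 px input, 8 base
channels, 2 encoder/decoder blocks, 2 dense layers) on 20 training
patches for 12–15 epochs — sized so a full train/predict/evaluate cycle
takes under a minute per seed on one CPU while still reaching ≥ 0.9
pooled-foreground Jaccard on held-out phantom slices.

# Segmentation evaluation

`basic_metrics()` reports accuracy, specificity, PPV, NPV, recall and
Jaccard from one-vs-rest confusion counts; a zero denominator yields
`NaN` plus a warning, never a silent 0.

The V-scores are the border-thinned, foreground-restricted agreement
scores standard in EM segmentation evaluation. The evaluation set keeps
ground-truth-foreground voxels farther than `radius` (Chebyshev) from any
ground-truth label interface; voxels adjacent to a differing label are at
distance 1, so radius 0 excludes nothing and radius 1 (the default)
strips exactly the one-voxel border zone where annotations are
untrustworthy. On that set,

* `v_rand_thinned()` is the Rand F-score over all ordered voxel pairs,
  \(\sum_{ij} n_{ij}^2 / (\tfrac12\sum_i a_i^2 + \tfrac12\sum_j b_j^2)\)
  from the joint label histogram, and
* `v_info_thinned()` is the normalized mutual information
  \(2I(P;T)/(H(P)+H(T))\), defined as 1 when both partitions are the
  same single segment.

Both equal 1 for identical segmentations, are invariant to permuting
segment ids, and are checked in the tests against brute-force
pair-enumeration and explicit-entropy oracles on small grids. Whether to
pool foreground classes or score per class is left to the caller (the
report pools; per-class calls are one `== k` away).

# Slice ordering and assembly

`order_slices()` minimizes the open-path objective
\(\sum_i d(s_{\pi(i)}, s_{\pi(i+1)})\) where `d` is the Jaccard distance,
either over the pooled foreground or as the unweighted mean of per-class
distances (the default; both conventions ship because the choice is
genuinely open). Two empty masks have distance 0 by convention.

The `exhaustive` method computes a certified global optimum by Held–Karp
dynamic programming over subsets — equivalent to scanning every
permutation (the test oracle does exactly that) but \(O(n^2 2^n)\), and
capped at 10 slices. Ties, including the unavoidable reversal degeneracy
of an open path, resolve to the lexicographically smallest optimal
permutation, which also puts the smaller slice index first. The `greedy`
method seeds the chain with the globally closest pair and extends either
end with the nearest unused slice; it is the scalable default and is
never better than the exact optimum (asserted over random instances).

`assemble_volume()` stacks slices in permutation order and records the
physical extent; 25 slices at 0.4 µm spacing with a 10 µm field of view
declare a 10 × 10 × 10 µm volume.

# 3D morphometry

Connected components are labelled by BFS under 26-connectivity by default
(6-connectivity available), with deterministic scan-order ids. Per
component, with \(\lambda_1 \ge \lambda_2 \ge \lambda_3\) the eigenvalues
of the population covariance of voxel coordinates (in µm, so anisotropic
voxels are handled by coordinate scaling):

* volume \(V\), surface area \(S\), ratio \(S\!:\!V\);
* compactness \(C = 36\pi V^2 / S^3\) and sphericity \(\psi = C^{1/3}\)
  (1 for a perfect ball);
* elongation \(\sqrt{\lambda_1/\lambda_2}\) and flatness
  \(\sqrt{\lambda_2/\lambda_3}\) (≥ 1);
* spareness: \(V\) divided by the volume of the covariance-matched
  ellipsoid with semi-axes \(\sqrt{5\lambda_i}\) (a solid ellipsoid's
  covariance is \(\mathrm{diag}(a^2,b^2,c^2)/5\)).

Components smaller than 4 voxels are flagged `unreliable` rather than
dropped. Degenerate moments (flat components) surface as `NaN`.

**Surface estimation.** The default estimator integrates the gradient
magnitude of a Gaussian-smoothed indicator function (the co-area
formula): for a smoothed binary interface \(\int |\nabla u|\,dV\) equals
the interface area up to a curvature bias of order \((\sigma/r)^2\). The
smoothing width (0.9 voxels) was calibrated once against the continuum
closed forms — on a digital ball of radius 20 voxels the estimate is
within 0.2 % of \(4\pi r^2\) and keeps \(\psi \le 1\); on a 40:20:10
ellipsoid it is within 1 %. A `voxel_faces` estimator (exposed face
counting) is also provided: it is exact for axis-aligned boxes (a digital
cube scores compactness exactly \(\pi/6\)) but biased high by ≈ 1.5× on
curved surfaces, which collapses sphericity — hence it is not the
default. A triangulated-mesh estimator would serve equally; the co-area
integral was chosen because it is accurate, dependency-free and a few
lines of separable filtering.

`density_map()` slides a physical window (default 4 µm per axis, stride
0.4 µm) over the volume and reports the mitochondria/myofibril voxel
ratio per fully interior window, computed exactly via a 3D integral
image. Windows with no myofibril voxels are undefined: they are stored as
`NA`, excluded from histograms, and counted — never imputed.

`compare_distributions()` is the statistical back end for asking whether
two volumes share shape statistics: one-way ANOVA (via `lm`/`anova`) for
means with an eta-squared effect size, plus a variance-ratio F test.

# The conditional style-based generative model

The generator keeps the defining features of the style family at desk
scale: a mapping network turns the latent z (concatenated with a learned
embedding of the one-hot slice-pair label) into an intermediate latent w;
synthesis starts from a learned constant tensor with 4 channels at the
output resolution (the scaled analogue of a full-scale 4 × 512 × 512
constant); each synthesis convolution is followed by style modulation
(per-channel scale and shift affinely predicted from w) and learned
per-channel noise injection; the output head is a 1 × 1 convolution to a
4-channel per-pixel softmax, argmaxed to a label slice. Style modulation
is applied without an explicit normalization layer — at two synthesis
convolutions the modulation itself is sufficient and keeps
backpropagation simple. Progressive growing, style mixing and perceptual
path length are deliberately out of scope.

Training is adversarial with the non-saturating logistic loss, one
discriminator and one generator step per record, consuming the slice-pair
records strictly in stack order (shuffling is disabled by construction —
the pair label carries through-plane position, which shuffling would
decouple). The discriminator sees the one-hot real slice or the
generator's probability output, conditioned by concatenating a label
embedding to its features.

**FID monitoring.** Convergence is monitored by the Fréchet distance
\(\lVert\mu_1-\mu_2\rVert^2 + \mathrm{Tr}(\Sigma_1+\Sigma_2-
2(\Sigma_1\Sigma_2)^{1/2})\) between Gaussians fitted to feature
embeddings of generated versus training slices. At desk scale the feature
extractor is a deterministic 8 × 8 average-pool of the label image
(pluggable, so a pretrained network can be slotted in at full scale — the
FID mathematics, not the embedding, is what the package contributes).
Covariances are population-convention by default (configurable). The
matrix square root uses the Denman–Beavers iteration with epsilon
regularization and clamping of numerical leakage; the tests cross-check
it against an independent eigendecomposition route. Evaluation latents
are drawn once and frozen, so FID snapshots are comparable across
iterations and constant under zero learning rates. The returned
checkpoint is the minimum-FID iterate, which also guards against
late-training mode collapse of the tiny adversarial system.

At generation time pair labels are cycled in order — the natural choice
when the labels encode consecutive positions and the stack is
reassembled afterwards. Generated volumes feed directly into the
assembly and morphometry stages
(`generate_model_volume()`); the z-extent scales linearly with the
number of seeds.

# Numerical and reproducibility choices

* All stochastic operations take explicit seeds and restore the global
  RNG state; identical seed + configuration reproduces outputs
  bit-identically on one machine.
* Max-pooling breaks ties deterministically (first view in scan order).
* Exhaustive-ordering tie comparisons use a 1e-9 cost tolerance so the
  floating-point cost of a path and its reversal compare equal.
* Softmax is always computed with max-subtraction; cross-entropy clamps
  probabilities at 1e-12.
* Undefined quantities (empty thinned foreground, zero-denominator
  metrics, myofibril-free density windows) are `NaN`/`NA` with warnings,
  never silently zero.

# Scale of the shipped experiments

The test suite trains the reduced U-net (three seeds) and a 32 × 32
conditional GAN (200 iterations), and compares shape-metric distributions
across five phantom pairs of ~1.2 M voxels with ~45 mitochondria each.
These sizes were chosen so the whole suite runs in minutes on a single
CPU while leaving each claim statistically meaningful; all of them scale
up by changing configuration values only.

# Known limitations

* The NN core is single-image (no batched BLAS calls) and CPU-bound;
  full-scale 512 px training is out of its intended envelope.
* The GAN is small enough that adversarial dynamics are noisy; the
  min-FID checkpoint, not the last iterate, is the usable artefact.
* The co-area surface estimator assumes objects a few voxels thick or
  larger; sub-voxel sheets will be under-measured (they are flagged by
  the `unreliable` column when small).
* HDF5 I/O is not provided; volumes exchange as multi-page TIFF with a
  JSON sidecar for voxel size.
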