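---
title: "Evaluating 3D plant reconstructions against laser-scan ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating 3D plant reconstructions against laser-scan ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantrecon)
```

## The problem

Image-based reconstruction methods — most recently radiance-field models
trained from smartphone video — produce dense point clouds of plants at a
fraction of the cost of a terrestrial laser scanner (TLS). Whether those
clouds are *geometrically* faithful is a separate question from whether the
renders look good, and answering it requires a reference: a TLS scan of the
same plant, registered into a common frame, compared point by point.
`plantrecon` implements that comparison end to end: cloud I/O and cleanup,
correspondence-based similarity alignment plus iterative-closest-point (ICP)
refinement, distance-threshold precision/recall/F-score with per-point
labeling, classical and perceptual 2D image metrics, and a plateau detector
that turns the perceptual metric into an early-stopping rule for
radiance-field training.

Everything is testable without captured data: a seeded synthetic module
generates plant-like surface clouds, degraded "reconstruction" copies under
known transforms, decay curves with engineered plateaus, and image pairs.

## Geometric evaluation

With a reconstruction cloud $R$ and ground truth $G$ in one frame, the three
summary statistics at a distance threshold $d$ (meters) are

$$P(d) = \frac{100}{|R|}\sum_{r \in R} I\!\left(\min_{g \in G}\lVert r-g\rVert < d\right),
\qquad
R(d) = \frac{100}{|G|}\sum_{g \in G} I\!\left(\min_{r \in R}\lVert g-r\rVert < d\right),$$

$$F(d) = \frac{2\,P(d)\,R(d)}{P(d)+R(d)},$$

precision measuring accuracy (how close reconstructed points sit to the
scan), recall measuring completeness (how much of the scan the
reconstruction covers), and the harmonic F-score collapsing to zero when
either fails. The indicator is strictly `< d`, following the definitions
literally. Nearest-neighbor distances come from a compiled kd-tree that is
bit-identical to exhaustive search (the accumulation order of the squared
distance is fixed), so the test suite can demand *exact* agreement with an
$O(NM)$ oracle rather than agreement within a tolerance.

Threshold defaults are `d = 0.005` m for indoor scenes and `d = 0.01` m for
outdoor scenes. The indoor value sits deliberately below the edge length of
a hypothetical $128^3$ unit evaluation grid ($1/128 = 0.0078125$): points
must agree at sub-voxel scale to count as distinct detail. Precision–recall
curves (`pr_curve()`) sweep $d$ to show the trade-off; the two
nearest-neighbor distance lists are computed once and re-thresholded, which
is identical by construction to re-evaluating per threshold.

Per-point labels follow the standard three-way color code. For the cloud
under test, with $\sigma$ the standard deviation of its nearest-neighbor
distance list: **correct** (gray) when the distance is below $d$;
**outlier** (black) when it exceeds $3\sigma$; **missing** (red) otherwise.
$\sigma$ is the population (ddof = 0) standard deviation, computed per
evaluation direction — the definition names "3 standard deviations" without
fixing the distribution, so this choice is explicit and surfaced in the
result object. When $3\sigma \le d$ no missing band exists; points at or
beyond $d$ are then outliers. Labeling the reconstruction against the scan
visualizes precision errors; labeling the scan against the reconstruction
visualizes what the reconstruction failed to cover.

## Registration

Alignment happens in two steps. First, a similarity transform (scale,
rotation, translation) is estimated from a handful of manually picked
correspondence pairs by the least-squares (Umeyama) closed form — exact for
noise-free correspondences, and the only place scale is estimated. Second,
point-to-point ICP refines rotation and translation with scale frozen:
the upstream reconstructions carry an arbitrary global scale that the
correspondences fix, and classical ICP formulations are rigid.
Point-to-point rather than point-to-plane residuals are used because the
pipeline never computes normals.

Two stage layouts are provided. The classical multiscale schedule runs three
stages: ICP at a voxel size and threshold, a restart at half the voxel size,
and a final restart at the original voxel size with a tightened threshold
(halved here; the tightening factor is not specified by the sources of the
schedule, so it is an explicit choice). The alternative keeps a *single*
stage but multiplies the iteration budget tenfold — for thin, repetitive
plant geometry the deep single-stage run is the variant that keeps
registration from collapsing. Defaults (voxel size twice the evaluation
threshold, 30 base iterations, multiplier 10) are engineering choices
exposed in `icp_config()`.

Numerical choices worth knowing:

* Both clouds are voxel-grid downsampled (cell centroids, first-occurrence
  order) before correspondence search. Setting the voxel below the cloud's
  sampling resolution makes downsampling lossless; the transform-recovery
  tests use `voxel_size = 1e-4` m for this reason, and with exact copies the
  recovered transform is then correct to machine precision.
* The literal stopping rule "relative fitness change below tolerance" stalls
  immediately on well-overlapping clouds, because fitness saturates at 1
  while the alignment is still improving. Iteration therefore stops only
  when *both* the fitness and the inlier RMSE change by less than the
  relative tolerance (the standard dual criterion), default `1e-7`.
* The result is the evaluated iterate with the lowest inlier RMSE (ties to
  the latest), so refinement never reports a worse alignment than its
  initial transform, and identical inputs give identical results — there is
  no randomized step anywhere in registration.
* Finding no correspondence within the threshold at the start raises a stage
  error that carries the initial transform, rather than silently returning
  it.

## Image metrics

`mse()`, `psnr()` and `ssim()` implement the classical definitions;
PSNR returns `Inf` for identical images as a documented sentinel (serialized
as null with a flag, excluded with a count from averages). SSIM defaults to
the *global* form — the index applied once to the whole image, since that is
how the formula is written — with an 11×11 uniform-window average as an
option; stabilizers default to $k_1 = 0.01$, $k_2 = 0.03$ (community
convention; the source names the constants without values). Color images are
converted to grayscale by channel mean for SSIM; MSE/PSNR average over all
channels.

The perceptual distance is the layer-feature form

$$d(x, x_0) = \sum_l \frac{1}{H_l W_l} \sum_{h,w}
\left\lVert w_l \odot (\hat y^l_{hw} - \hat y^l_{0hw}) \right\rVert_2^2,$$

with features unit-normalized along the channel dimension at each spatial
location (epsilon $10^{-10}$ on the norm) and channel weights defaulting to
$w_l = 1/C_l$, the setting that reduces the summand to a cosine distance.
The network supplying the features is a pluggable contract
(`feature_backbone()`): any deterministic mapping from a raster to per-layer
$H_l \times W_l \times C_l$ stacks. The default, `conv_backbone()`, is a
fixed-seed multi-scale convolution bank (block-mean downsampling, 3×3
kernels frozen at construction, tanh) — deterministic, self-contained, and
sufficient for every property the metric must satisfy (zero at identity,
symmetry, scale invariance of raw features). Which pretrained network a
production training pipeline uses is deliberately out of scope; only the
distance computation is defined here, so absolute perceptual values from
different backbones are not comparable.

## Early stopping

During radiance-field training the geometric F-score cannot be monitored —
the ground truth is exactly what is missing — but the perceptual distance
between held-out validation images and their renders can, and it correlates
strongly (negatively) with the final F-score. The monitor therefore: (1)
computes the mean perceptual distance per checkpoint (`build_series()`);
(2) linearly interpolates the checkpoint series onto a uniform grid of 1,000
points spanning 60,000 iterations — checkpoints are typically exponentially
spaced — holding the last value constant beyond the final checkpoint, since
extrapolating a slope would fabricate phantom plateaus; (3) finds the first
index $i$ whose $C$ consecutive absolute successive differences all stay
below $\theta$ (defaults $\theta = 0.005$, $C = 6$); and (4) recommends
stopping at grid index $i + C$, the first moment an online monitor can
*confirm* the plateau. The plateau criterion is formalized here as absolute
successive differences on the interpolated grid; the windowing and sign
conventions admit variants, so the implementation keeps them explicit and
configurable. The criterion depends only on absolute differences, making the
detector invariant to shifting or negating the series, and a brute-force
window scan is the test oracle for minimality of the detected index.

`pearson_correlation()` (sample form) and `correlation_report()` reproduce
the metric-versus-F-score correlation analysis on per-run tables; an exactly
affine relation between the perceptual metric and the F-score yields
$r = -1$ exactly, which the tests assert.

## The synthetic module

The generators define the study conditions for every test:

* **Plant clouds** (`generate_plant_cloud()`): a cylindrical stem (default
  1.2 m × 2 cm radius, matching a late-vegetative corn plant) with 8
  parabolic leaf ribbons of 0.5 m attached at evenly spaced heights and
  golden-angle azimuths, sampled uniformly by surface area at
  2×10⁴ points/m² — mean point spacing ≈ 7 mm, the working resolution of the
  TLS scans being emulated. Leaf geometry is the simplest shape with
  curvature and overlap; botanical realism is a non-goal. Poisson counts per
  component make the total count testable against density × area; two
  deterministic anchor points close the stem so the z-extent bound
  (stem height ≤ extent ≤ stem height + leaf length) is exact.
* **Degraded copies** (`degrade_cloud()`): similarity transform, then
  Gaussian jitter, then independent dropout, then uniform outliers in an
  inflated bounding box — the failure modes of radiance-field exports
  (default jitter 2 mm, dropout 0.2, outliers 1%). Every stage is seeded;
  the whole generator is a pure function of parameters and seed.
* **Training curves** (`generate_training_curve()`): exponential decay whose
  amplitude falls to 10⁻³ of itself at the engineered plateau iteration, so
  the curve is flat on the scale of typical thresholds from there on, plus
  optional Gaussian noise.
* **Image pairs** (`generate_image_pair()`): a fixed sinusoidal texture with
  integer intensities in [0, 250] plus a degraded copy; the intensity-shift
  degradation is exact for shifts ≤ 5, making MSE/PSNR identities testable
  without tolerance.

What passing tests on these fixtures do **not** show: robustness to
structured TLS artifacts (occlusion shadows, mixed pixels, registration
seams between scan positions), to wind-driven deformation between capture
and scan, or to the density inhomogeneity of real radiance-field exports.
The fixtures validate the *mathematics and mechanics* of the pipeline, not
sensor physics.

## Problem sizes and reproducibility

The test suite runs synthetic clouds of roughly 500–5,000 points and images
of 16–64 pixels per side — large enough to exercise every code path and the
statistical bounds (binomial dropout recovery, Gaussian-tail precision,
20-cloud transform recovery), small enough that the whole suite completes in
well under a minute. `scripts/acceptance.R` re-derives the package's
headline quantities at the same scale from a single `--seed`. All
randomness flows through explicit seeds; identical inputs give identical
outputs everywhere, including ICP.

## Known limitations

* PLY support covers `element vertex` with float/double x/y/z and optional
  uchar RGB (ASCII and binary-little-endian) — the dialect the pipeline
  itself writes; meshes, normals, LAS/E57 are out of scope.
* The PCD writer stores color as a packed 24-bit integer printed as a
  decimal field; standard color-less `x y z` PCD files from other tools load
  fine.
* ICP is local: it refines a reasonable initial alignment and will not
  rescue a grossly wrong one (no global/feature-based registration).
* Scale is never re-estimated after initialization; scenes whose scale error
  exceeds what correspondences can fix need the reference-object calibration
  (`rescale_by_reference()`), which recovers physical dimensions to well
  under 1% in the synthetic sphere experiment.
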