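# plantrecon

Benchmarking 3D plant reconstructions against terrestrial-laser-scan (TLS)
ground truth.

Radiance-field models (Instant-NGP, TensoRF, NeRFacto and kin) can turn a
few minutes of smartphone video into a dense point cloud of a plant. Whether
that cloud is *geometrically* right — accurate enough for phenotyping, not
just pretty to render — has to be measured against a reference scan.
`plantrecon` is the measurement toolkit: it registers a reconstruction into
the ground-truth frame, scores it with distance-threshold
precision/recall/F-score, labels every point Correct/Missing/Outlier for
visualization, computes the 2D image metrics (MSE, PSNR, SSIM, and a
perceptual layer-feature distance with a pluggable backbone), and turns the
perceptual metric into an early-stopping rule for radiance-field training.
A seeded synthetic module (plant-like surface clouds, degraded copies,
decay curves, image pairs) makes the whole pipeline testable without GPUs
or captured data.

## The core statistics

For a reconstruction `R` and ground truth `G` in one frame, at distance
threshold `d` (meters):

    P(d) = 100/|R| * Σ_{r∈R} I( min_{g∈G} ||r−g|| < d )     (precision / accuracy)
    R(d) = 100/|G| * Σ_{g∈G} I( min_{r∈R} ||g−r|| < d )     (recall / completeness)
    F(d) = 2 P(d) R(d) / (P(d) + R(d))                      (harmonic F-score)

Defaults: `d = 0.005` m indoor, `0.01` m outdoor. Registration is a
least-squares (Umeyama) similarity fit on picked correspondences followed by
rigid point-to-point ICP — either the classical three-stage multiscale
schedule or a single stage with a 10× iteration budget. Early stopping
interpolates the per-checkpoint mean perceptual distance onto a uniform grid
(1,000 points over 60,000 iterations) and stops at the first window of
`C = 6` consecutive changes below `θ = 0.005`.

## Worked example

Generate a synthetic plant "scan", degrade it into a mock reconstruction
(2 mm jitter, 30 % dropout, 1 % outliers, unknown similarity transform),
register, and evaluate:

```r
library(plantrecon)

gt <- generate_plant_cloud(plant_params(seed = 1))
gt
#> <point_cloud> 7461 points
#>   extent x [-0.423, 0.4281]  y [-0.4294, 0.4221]  z [0, 1.302] m

known <- similarity_transform(scale = 0.95,
                              rotation = rbind(c(cos(0.1), -sin(0.1), 0),
                                               c(sin(0.1),  cos(0.1), 0),
                                               c(0, 0, 1)),
                              translation = c(0.05, -0.02, 0.01))
recon <- degrade_cloud(gt, degrade_params(jitter_sigma = 0.002,
                                          dropout_fraction = 0.3,
                                          outlier_fraction = 0.01,
                                          transform = known, seed = 2))

# four picked correspondence pairs fix scale and orientation, ICP refines
idx  <- c(10, 400, 2000, 5000)
init <- estimate_initial_transform(apply_transform(gt$points[idx, ], known),
                                   gt$points[idx, ])
reg  <- icp_refine(recon, gt, init,
                   icp_config(voxel_size = 0.005, distance_threshold = 0.05))
reg
#> <registration_result> fitness 0.9893, inlier RMSE 0.00345037 m, 5 iterations

aligned <- apply_transform(recon, reg$transform)
evaluate_reconstruction(aligned, gt, d = 0.005)
#> <geometry_report> d = 0.005 m: P 92.40  R 83.15  F1 87.53  (|R| = 5289, |G| = 7461)

table(label_points(aligned, gt, 0.005)$labels)
#> correct missing outlier
#>    4887     352      50
```

Precision stays high because the 2 mm jitter sits well inside the 5 mm
threshold (the 1 % injected outliers account for most of the loss); recall
reflects the 30 % dropout, partially recovered where surviving neighbors
cover the gaps. The labeled clouds can be written as colored PLY
(gray = correct, red = missing, black = outlier) with
`write_cloud(labeled_cloud(aligned, lab), "labeled.ply")`.

Early stopping on a training curve with a plateau engineered at iteration
20,000:

```r
curve <- generate_training_curve(20000, noise_sigma = 0.002, seed = 3)
recommend_stop(curve, plateau_config())$result
#> <plateau_result> plateau from index 51, stop at iteration 4307.31
```

(The reference threshold `θ = 0.005` confirms as soon as successive changes
stay below it — for this decay rate that happens well before the
engineered 10⁻³-amplitude point; a θ matched to the decay rate confirms at
the engineered plateau. Both are reported by the acceptance script.)

A thin CLI over the same functions is installed at `exec/plantrecon`
(subcommands `register`, `evaluate`, `prcurve`, `label`, `image-metrics`,
`monitor`, `simulate`; `--config file.yaml` supplies defaults).

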