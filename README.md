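# fieldpheno

Single-plant phenotyping of field crop populations from colored 3D point
clouds — for crop scientists and breeders who reconstruct breeding plots
(e.g. from smartphone video via Gaussian splatting) and need per-plant
traits without training data or manual annotation.

The package implements the full pipeline:

- **Splat sampling** — convert a trained 3D-Gaussian-splat scene into a
  dense colored cloud by drawing `x = mu + R S z`, `z ~ N(0, I)` from each
  anisotropic Gaussian (`Sigma = R S S' R'`) and rejecting draws with
  Mahalanobis distance `sqrt(z'z) > 3`.
- **Scene cleanup** — RANSAC ground plane, quaternion alignment
  `q = (cos(theta/2), sin(theta/2) k)` of the ground normal onto +z,
  statistical and bilateral denoising, and a hue-enhanced cloth simulation
  filter that splits ground surface (GS) from ground plants (GP), vetoing
  vegetation-hued points out of the ground class.
- **Localization** — DBSCAN over a bare-stem height layer `[L_l, L_h]`;
  each cluster's horizontal centroid at `L_h` is the plant's persistent
  localization point `A_pk` and registry identity.
- **Instance segmentation** — region growing from stem seeds under three
  joint constraints: distance `|p - q| < delta`, normal similarity
  `|n_p . n_q| >= tau_N`, and membership in the plant's *dynamic spatial
  constraint*, a cylinder of radius `r_k = R_hk tan(alpha)` that scales
  with the plant's own measured height `R_hk`. Points claimed by several
  plants are settled by local robust-plane distance and curvature
  consistency.
- **Traits** — cotyledon node height `FCNH = z_fn - z_gd` (lowest
  stem/branch line intersection above a local ground datum), plant height
  `PH = z_msv - z_gd`, leaf count, and per-leaf area from a
  support-trimmed height-field mesh.
- **Evaluation** — TP/FP/FN by greedy IoU matching, recall/precision/F,
  per-instance IoU and mIoU, convex-hull point densities
  (`D_sur = N/A_cs`, `D_vol = N/V_cv`).
- **Synthetic fields** — a seeded generator of 2 m x 2 m plots
  (0.66 m x 0.10 m precision-seeding grid, brown ground, green plants,
  additive sensor noise) with exact per-point labels and analytic trait
  truth, so the whole pipeline is testable without field data.

## Worked example

```r
library(fieldpheno)

# a seeded synthetic 3x3 plot with ground-truth labels and traits
fld <- generate_field(field_spec(rows = 3, cols = 3, seed = 7))
fld$cloud
#> point_cloud: 51000 points [labels] — 9 instances
#>   extent: x [-1.006, 1.005]  y [-1.005, 1.006]  z [-0.013, 0.356] m

res <- run_pipeline(fld$cloud, variety = "DEMO", plot = "a")
res$labeling
#> instance_labeling: 27000 points, 9 instances, 20 unassigned, 0 contested

m <- seg_metrics(res$full_labels, fld$cloud$labels)
#> TP 9  FP 0  FN 0 | r 100.00  p 100.00  F 100.00 | mIoU 0.999

head(res$traits[, c("plant_index", "fcnh_m", "ph_m", "leaf_count",
                    "leaf_area_total_m2")], 4)
#>   plant_index fcnh_m  ph_m leaf_count leaf_area_total_m2
#> 1           1 0.0775 0.352          5            0.00380
#> 2           2 0.0880 0.283          5            0.00355
#> 3           3 0.0730 0.318          5            0.00396
#> 4           4 0.0808 0.279          4            0.00248

head(truth_traits(fld$truths), 4)   # generator ground truth to compare
#>   plant_index   fcnh    ph leaf_count la_total
#> 1           1 0.0773 0.349          5  0.00376
#> 2           2 0.0893 0.282          5  0.00376
#> 3           3 0.0741 0.314          6  0.00464
#> 4           4 0.0820 0.280          4  0.00289
```

The nine plants are found exactly (no false positives or negatives, mean
IoU 0.999 against the generator labels); recovered heights track the
truth to a few millimeters, and leaf areas to a few percent (plant 3
fuses two touching laminae into one, a known failure mode of connectivity
clustering).

A thin CLI wraps the same functions
(`inst/cli/fieldpheno.R synth | sample | preprocess | localize | segment |
traits | evaluate | pipeline`):

```sh
Rscript inst/cli/fieldpheno.R synth --rows 3 --cols 3 --seed 7 --out field.ply --truth truth.csv
Rscript inst/cli/fieldpheno.R pipeline --in field.ply --out-prefix run1
```

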