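# trabecula

Quantitative analysis of trabecular architecture in porous skeletal
microstructure — built for the echinoid stereom, the calcite micro-beam
lattice that composes sea-urchin skeletal plates — from binary micro-CT
subvolumes.

Who it is for: morphologists and biomechanics researchers who have a
micrometre-scale CT scan of a porous skeletal element (or an Avizo
SpatialGraph export of one) and want per-beam architecture descriptors and
region comparisons; and methods developers who need a ground-truthed
synthetic beam-network generator to validate skeletonization pipelines.

## What it computes

From an 8-bit volume (TIFF stack or NRRD, default 3 µm/voxel) the pipeline
runs: edge-preserving contrast enhancement → inclusive band thresholding
(default 76–172) → small-component removal (default 1000 voxels, 26-conn.)
→ homotopic 3D thinning → spatial graph (nodes + polyline segments with
distance-transform radii) → cleaning (deduplication, spur pruning) → the
eight trabecular descriptors:

| descriptor | definition |
|---|---|
| chord length `l_c` | straight node-to-node distance |
| curved length `l_t` | arc length along the centerline |
| tortuosity `τ` | `l_t / l_c` (1 = straight) |
| radius `r` | mean of per-point radii (sub-voxel volume-equivalent refinement available) |
| slenderness `R_S` | `L / g_r`, with `g_r = d_t / 4` |
| inter-trabecular angle | `arccos(â·b̂)` for every segment pair at a node; ideal 120° (planar 3N), 109.5° (tetrahedral 4N) |
| node configuration | segments per node (3N, 4N, …) |
| theta / phi | chord inclination to the plate normal `[0°,90°]` / azimuth in the plate plane `[0°,360°)` |

Mechanics adds `I = πr⁴/4` and the critical Euler buckling force
`F_E = nπ²EI/L²` (two fixed ends, `n = 4`). The statistics layer provides
subsampled Wilcoxon rank-sum comparisons (n = 300 per group, 10000
iterations, mean p reported), Shapiro–Wilk, moment skewness/kurtosis,
χ² uniformity of phi, and rose-diagram binning, with ggplot2 figures
(`plot_rose()`, `plot_theta_histogram()`, `plot_ita_histogram()`).

## Worked example

A full synthetic round-trip: generate a stereom-like network, rasterize it
at 3 µm voxels, and run the whole pipeline.

```r
library(trabecula)

nw  <- generate_network(seed = 17)               # 90 µm cube ground truth
bin <- voxelize_network(nw, voxel_size = 3, bounds_um = 90)
vol <- as_voxel_volume(bin)                      # mid-band intensities

rep <- run_pipeline(vol, trab_config(subsample_n = 150,
                                     iterations = 200, seed = 1))
writeLines(render_report(rep))
```

```
## region: region1

variable            median     mad     min     max       N
chord_length          16.16    4.95    0.00   59.55     130
curved_length         17.61    6.79    3.00   90.43     130
tortuosity             1.04    0.04    1.00    4.62     129
mean_radius            2.39    0.43    1.33    8.92     130
slenderness           16.19    6.57    1.45   63.38     130
theta                 61.09   14.87    0.00   90.00     129
phi                  180.00   90.00    0.00  353.16     128
node_radius            1.50    0.00    1.50    6.99      54
mean_ita             107.25    8.09   70.74  120.00      54

node conf      total        3N      4N      5N      6N      8N
N                 54        36      12       3       2       1
fraction (%)  100.00     66.67   22.22    5.56    3.70    1.85

theta normality (Shapiro-Wilk): W = 0.965, p = 0.00223, N = 129
theta moments: skewness = -0.420, kurtosis = 2.636, N = 129
phi uniformity (chi-squared): X2(35) = 46.38, p = 0.0946, N = 128
```

Reading it: the median trabecula is short and stocky (chord ≈ 16 µm,
radius ≈ 2.4 µm), nearly straight (τ ≈ 1.04), two thirds of intersections
are 3-valent, node radii sit at the half-voxel floor (1.50 µm), and theta
peaks toward 90° (beams mostly lie in the plate plane, median ≈ 61°,
left-skewed and flatter than Gaussian). `N` differs between rows because
zero-chord loops carry no tortuosity or orientation. `recovery_report()`
compares any such run against the generator's ground truth; tortuosity
here differs from truth by ~0.01 and the valence fractions by a few
points.

Region comparisons take a named list —
`run_pipeline(list(center = vol1, margin = vol2), cfg)` — and report the
mean subsampled rank-sum p for every descriptor pair. Avizo users can skip
the image stages entirely via `read_avizo_spatialgraph("graph.am")`.

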