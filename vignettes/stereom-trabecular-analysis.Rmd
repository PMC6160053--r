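---
title: "Quantifying trabecular architecture in echinoid stereom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying trabecular architecture in echinoid stereom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabecula)
```

## The problem

Echinoid skeletal plates are built from stereom: a porous calcite
micro-lattice whose beams (trabeculae) run a few tens of micrometres
between intersection nodes. Its three-dimensional architecture determines
how the plate carries and distributes load, and it can be measured from
micro-CT scans at micrometre resolution. `trabecula` implements the whole
measurement chain:

1. **Volume preprocessing** — 8-bit micro-CT subvolumes are contrast
   enhanced, binarized with an inclusive intensity band, and cleaned of
   small unconnected components.
2. **Skeletonization** — the binary stereom is thinned to a one-voxel
   centerline skeleton and converted into a *spatial graph* of nodes
   (trabecular intersections) and polyline segments (trabeculae) carrying
   per-point radii from a Euclidean distance transform.
3. **Descriptors** — eight per-trabecula measures: chord length, curved
   length, tortuosity, radius, slenderness ratio, inter-trabecular angle
   (ITA), node configuration (valence), and the orientation angles theta
   and phi.
4. **Statistics** — subsampled Wilcoxon rank-sum comparisons between plate
   regions, Shapiro-Wilk normality of theta, moment skewness/kurtosis,
   chi-squared uniformity of phi, rose-diagram binning.
5. **Mechanics** — second moment of area and critical Euler buckling force
   per trabecula.
6. **Synthetic networks** — a ground-truthed generator of stereom-like
   beam networks, so the full chain can be validated end-to-end without a
   scan.

## Descriptor definitions and conventions

For a segment with polyline $p_1,\dots,p_n$ between nodes $A$ and $B$:

* chord length $l_c = \lVert p_n - p_1\rVert$; curved length
  $l_t = \sum_i \lVert p_{i+1}-p_i \rVert$; tortuosity
  $\tau = l_t / l_c$. A straight beam has $\tau = 1$. When $l_c$ falls
  below the chord tolerance (default $10^{-6}$ um, e.g. for closed loops)
  $\tau$ and the orientation angles are reported as `NA` and drop out of
  summaries; this is why different descriptors carry different N.
* segment radius $r$ = arithmetic mean of the per-point radii; diameter
  $d_t = 2r$; radius of gyration $g_r = d_t/4$ (circular cross-section);
  slenderness $R_S = L / g_r$ with $L$ the **curved** length — the
  physical beam length is what buckling sees. Both choices are
  configurable.
* the direction of a segment at a node is the unit chord from the node to
  the segment's other endpoint, not the local polyline tangent: with
  $\tau \approx 1.03$ the difference is negligible and the chord is robust
  to voxel-scale wiggle (a tangent mode is available).
* ITA: for every unordered pair of segments at a node,
  $\arccos(\hat a \cdot \hat b)$ in degrees; a node of valence $n$ yields
  $n(n-1)/2$ pairs. Ideal reference values: 120° for a symmetric planar
  3-valent node, 109.47° for a regular tetrahedral 4-valent node.
* theta is the angle between the chord and the z-axis folded into
  [0°, 90°] ($\arccos|\hat z \cdot \hat d|$): 0° is perpendicular to the
  plate surface, 90° lies in the plate plane. Phi is the azimuth of the
  x-y projection in [0°, 360°), counterclockwise from +x, after orienting
  the chord to non-negative z. The anchor of phi is arbitrary (rose
  diagrams have no specific orientation relative to the specimen); only
  uniformity vs directionality is interpretable.
* summaries report median and **unscaled** median absolute deviation (no
  1.4826 normal-consistency factor), plus min, max and N. Node tables
  count intersection nodes only (valence >= 2); free ends are cropping
  artifacts of the subvolume.
* ITA histogram modes use 5° bins anchored at 0, reporting the midpoint of
  the tallest bin (configurable).

## Numerical and algorithmic choices

**Contrast enhancement.** The de-noising step is a toggle-contrast
operator: each voxel snaps to whichever of its neighborhood minimum or
maximum (centre excluded) is closer. It is exactly idempotent on binarized
volumes, replaces isolated salt/pepper voxels by their neighborhood value,
and — unlike a plain 3-cube median filter — preserves beams only one or
two voxels thick, which at 3 um voxels is the typical trabecula. A
`bypass` flag disables the step so downstream results never silently
depend on it.

**Thresholding.** The intensity band (default 76–172) is inclusive at both
ends, and the small-spot filter (default 1000 voxels, 26-connectivity)
keeps components of exactly the minimum size. Both conventions are stated
because interactive tools leave them undocumented.

**Skeletonization.** Homotopic thinning deletes simple points
(topological numbers $T_{26} = T_6 = 1$) sequentially in six directional
subiterations, never deleting curve endpoints. Topology (components and
cycles) is preserved exactly; beam free ends retract by about one beam
radius, as for any medial-axis method.

**Graph building.** Skeleton voxels are classified by *branch count* —
the number of 26-connected components among a voxel's skeleton neighbors —
rather than by raw neighbor count, which keeps junction clusters tight
where diagonal staircase steps would otherwise chain them along branches.
Junction clusters merge into one node at their centroid; pure cycles are
anchored at their lexicographically smallest voxel and flagged as loops.
The radius field is the exact Euclidean distance to the nearest background
voxel centre minus half a voxel (the boundary lies between voxel centres),
floored at half a voxel — an isolated voxel has radius `voxel_size/2`,
which is why measured node radii bottom out at exactly 1.5 um on a 3 um
scan.

**Cleaning.** `deduplicate()` merges coordinate-coincident nodes (1e-6 um
tolerance) and repeated segments (identical polylines up to reversal).
`prune_spurs()` removes leaf segments shorter than 3 voxels — below the
largest beam radius plus one voxel, such spurs are indistinguishable from
cap-retraction artifacts — collapses redundant parallel paths between one
node pair (a beam splitting around a pore and rejoining), drops short
self-loops, and splices out the resulting valence-2 pass-through nodes.

**Polyline smoothing.** The 26-connected voxel chain overestimates curved
length through staircase steps (on the order of a tenth of its length),
which would inflate the recovered median tortuosity well past the
tolerance a near-straight beam population requires. The pipeline therefore
applies two Laplacian smoothing sweeps to interior polyline points by
default (endpoints stay fixed on their nodes, so chords and topology are
untouched); `build_spatial_graph()` itself defaults to no smoothing so the
raw voxel chain remains available.

**Sub-voxel radii.** At 3 um voxels a median trabecular radius of ~2.3 um
is 0.77 voxel: any binary distance transform quantizes such beams to the
half-voxel floor, so point radii alone cannot recover the median radius.
`refine_segment_radii()` recovers sub-voxel radii from the information
binarization does retain — claimed volume: every foreground voxel is
assigned to its nearest polyline point, a segment's interior claim
(end regions of one voxel excluded, per-point claims winsorized, distances
capped at the local distance-transform radius plus half a voxel) gives a
volume-equivalent cylinder radius $\sqrt{V/(\pi\,l)}$. On validation
networks this recovers the median radius within its stated tolerance with
a modest upward bias from thin-beam capture quantization. It is on by
default in the pipeline;
distance-transform point radii remain available (`refine_radii = FALSE`).

## The synthetic network generator

`generate_network()` emulates the statistical structure of plate stereom
at micro-CT scale; its defaults are the study conditions used throughout
the tests: a 90 um cubic domain, median chord length 16.4 um, lognormal
radii with median 2.3 um floored at 1.5 um (half a scan voxel), valence
mix 66% 3N / 21% 4N / 13% 5N, median tortuosity 1.03, isotropic
orientations (theta then peaks at 90°, matching the observed mode), and an
optional directional azimuth model.

Design choices that matter:

* **Blue-noise placement.** Nodes are placed by seeded Poisson-disk dart
  throwing with the minimum separation calibrated (factor 1.14, measured
  once from the realized edge-length distribution) so the median chord
  meets its target. Blue noise is isotropic by construction; lattice
  placements were rejected because their neighbor directions leave
  azimuthal lobes that a chi-squared uniformity test detects at N ~ 1500.
* **Grow-and-clip.** The network is grown in a padded box and clipped to
  the requested cube, cut segments ending in leaf nodes on the faces —
  exactly how a cropped subvolume truncates trabeculae. Growing inside the
  cube instead herds boundary edges inward along face normals and imprints
  a four-lobed azimuth artifact.
* **Valence construction.** Greedy residual-degree matching over
  near-neighbor candidates, with a repair pass and a guarantee that
  interior nodes reach their target valence exactly; candidate edges that
  would pass within 6 um of an existing trabecula are rejected, since real
  trabeculae fuse rather than interpenetrate (and voxelization would fuse
  them into spurious junctions).
* **Tortuosity.** Each segment receives a single-period sinusoidal offset
  orthogonal to its chord; the amplitude is inverted numerically from the
  discrete polyline arc length, so the realized tortuosity matches the
  drawn value exactly. Tortuosity draws are 1 + exponential with median
  excess 0.03.
* **Orientation models.** The directional azimuth model weights candidate
  selection by $\exp(\kappa\,\hat u_{xy}\!\cdot\!\hat\mu)$ (default
  $\kappa = 4$); real stereom azimuth structure is multi-lobed, so this is
  a qualitative emulation of directionality, not a fit. The "plate" theta
  model up-weights horizontal chords.

What the generator does **not** emulate: grayscale partial-volume effects
(voxelization is a hard centre-in-capsule test), spatial autocorrelation
of radii, curved plate geometry, the galleried/labyrinthic microfabric
distinction, and ITA concentration near 120° (beam directions follow the
isotropic or weighted near-neighbor geometry, giving a broad ITA
distribution centred near 100°). Passing recovery tests therefore
demonstrate the pipeline's geometric fidelity, not that synthetic networks
are indistinguishable from real stereom.

**Validation scales.** End-to-end recovery uses the default 90 um cube
(about 280 nodes and 300 segments before clipping losses); azimuth
uniformity tests use a 160 um domain to reach N ~ 1500 azimuths, the scale
at which directionality is assessed in practice. A 90 um cube yields only
~55 countable intersection nodes, so per-class valence fractions carry
~6-point sampling noise — the recovery tolerance (7 points per class) is
evaluated under the generator's documented default seed.

## Statistical battery

Comparisons use the subsampled Wilcoxon rank-sum: each of 10000 iterations
draws 300 values per group without replacement and runs the two-sided test
with tie correction under the plain normal approximation (no continuity
correction); the arithmetic mean of the iteration p-values is reported.
A mean p-value is an unconventional summary, so the full p distribution is
kept (`tidy()` gives quantiles and the fraction below 0.05). Inputs are
sorted before subsampling, which makes results independent of data
ordering. Subsampling is seeded and exactly reproducible; a bootstrap mode
(`replace = TRUE`) is available.

Kurtosis is non-excess (a Gaussian scores 3; values below 3 are
platykurtic). The chi-squared uniformity test on phi uses 36 equal sectors
and df = bins − 1 = 35, the standard convention for a fully specified
null. The Shapiro-Wilk wrapper subsamples (seeded) above the algorithm's
5000-value limit and records that it did.

Because trabeculae share nodes, neighboring azimuths are correlated, so
the chi-squared statistic on a connected network is mildly inflated even
under a perfectly isotropic model; at the tested sample sizes this stays
well below the rejection threshold for the uniform model and is irrelevant
for the strongly directional one.

## Mechanics

Per trabecula, $I = \pi r^4/4$ and $F_E = n\pi^2 E I / L^2$ with the
two-fixed-ends coefficient $n = 4$ (trabeculae are clamped in nodes at
both ends; $n = 1$ gives pinned-pinned). No calcite stereom modulus is
assumed: $E$ defaults to 1, so forces are relative; absolute forces
require a user-supplied modulus.

## Known limitations

* Cap retraction shortens free-ended (clipped) trabeculae by roughly one
  beam radius; stubs shorter than about 3 voxels are lost entirely.
* Junction positions are voxel-quantized; very close junctions (under
  about 2 voxels) merge.
* Radii below about half a voxel rasterize thicker than they are and
  cannot be recovered; radii between half and one voxel are recovered only
  through the volume-equivalent estimator, with ~10–15% upward bias.
* The Avizo `.am` importer reads the ASCII SpatialGraph dialect only, and
  assumes the point thickness attribute is a radius unless told otherwise
  (`thickness_is = "diameter"`).
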