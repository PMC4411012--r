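---
title: "Models and numerical methods in arraytomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in arraytomo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arraytomo)
```

This vignette documents the models, default parameters, and numerical
design choices behind `arraytomo`, and explains what the synthetic
scene generator does and does not capture. Units are stated throughout:
lateral voxel pitch in nanometres, positions in voxel coordinates
(1-based array indices for centers, 0-based half-open ranges for
cutouts), intensities in arbitrary 16-bit camera units (a.u.).

## 1. Imaging model and geometry

Array tomography physically sections tissue into ultrathin ribbons, so
the axial sampling is set by the microtome, not by optics. The default
voxel is **100 × 100 × 70 nm** (`voxel_size()`), giving
`physical_volume(nx, ny, nz)` = nx·ny·nz·7·10⁻⁷ µm³. Volumes are stored
as one 16-bit unsigned image stack per channel plus a JSON manifest
(`write_volume()` / `read_volume()`); 16-bit TIFF round-trips are
lossless, which the tests verify bit-for-bit.

Channel names follow the `<antibody>-<round>` convention
(e.g. `Synapsin1-1`, `vGluT2-2`): the suffix records which
elution/restain round produced the stain, which matters because
between-round registration and stain consistency are empirical
questions, not givens.

Cutouts use **0-based half-open** `[min, max)` ranges on all three
axes, so concatenating adjacent cutouts tiles a volume exactly and a
cutout of a cutout composes by offset addition. Resolution level *r*
halves x and y by 2×2 mean pooling *r* times (z is never pooled —
sections are already coarse axially). False-color composites assign up
to six channels to cyan, yellow, magenta, red, green, blue in that
order, with `"0"` reserving an unused slot; channels add in RGB and
clip at white.

## 2. Preprocessing

**Rolling-ball background subtraction** (`subtract_background()`) uses
a flat disc structuring element: background = dilation(erosion(image)),
i.e. a morphological opening, subtracted from the input. A flat element
(rather than a spherical cap) makes the operator positively homogeneous
— scaling the image by *c* scales the result by *c* — which is both a
convenient invariant for testing and the right behavior for data whose
gain is arbitrary. The default radius should exceed the largest feature
to preserve (puncta are 2–4 px across laterally at 100 nm pitch, so
radii of 10–50 px are typical).

**Richardson–Lucy deconvolution** (`deconvolve_rl()`) implements the
standard multiplicative EM iteration with a reflective image boundary.
The PSF is validated to be non-negative and is normalized to unit sum,
so total flux is conserved up to boundary effects (tested to < 1%).
Both 2D sections and 3D stacks are supported; the axial PSF in array
tomography is essentially the section thickness, so 2D per-section
deconvolution is usually the right call and 3D is provided for
completeness.

## 3. Rigid registration

All in-plane alignment is **rigid** (rotation + translation) with an
explicit center of rotation carried in the transform object
(`rigid2d(theta, dx, dy, center)`). Composition, inversion, and change
of center are exact algebra; resampling uses the inverse map
(out(p) = in(T⁻¹p)) with bilinear interpolation. Rigid-only is a
deliberate limitation: ultrathin sections mostly translate and rotate
on the coverslip, and admitting affine or elastic terms invites fitting
noise in sparse fields; see §8.

**Pairwise offsets** come from normalized cross-correlation over an
integer search window, refined by fitting a quadratic to the 3×3
correlation neighborhood (subpixel accuracy ≈ 0.1 px on realistic
content).

**Mosaic stitching** (`stitch_mosaic()`) estimates pairwise offsets on
overlaps and solves the global tile positions by least squares
(`stats::lsfit` under the hood, tile 1 fixed), which distributes
loop-closure error instead of accumulating it along a chain. Fusion
feathers linearly across overlaps.

**Session registration** (`register_session()`) aligns the same
section re-imaged in a different staining round: detect
scale-normalized Laplacian-of-Gaussian blobs in both images, get a
coarse translation from NCC on downsampled images to prune candidate
matches, match blobs by nearest neighbor, and fit the rigid transform
with 2-point RANSAC followed by a Procrustes refit on the inliers.
Transforms are centered at the image center so rotation and translation
estimates decouple.

**Stack alignment** (`align_stack()`) first chains neighbor-to-neighbor
offsets to the middle section as anchor. Chaining alone accumulates a
random walk of per-pair errors (≈ 0.1 px per link grows to ≈ 0.5–0.6 px
RMS over a dozen sections), so it is followed by leave-one-out
template refinement: each aligned section is re-registered,
translation-only with subpixel refinement, against the mean of all
*other* aligned sections, and the stack is re-anchored; two passes
(default `refine_passes = 2`) reduce residuals by roughly an order of
magnitude because the template averages away independent section noise.

## 4. Colocalization

`crosscorr_map(a, b, max_shift)` computes, for every lateral shift
(du, dv) with |du|,|dv| ≤ `max_shift`, the Pearson correlation between
channel A and channel B shifted by (du, dv), restricted to the
overlapping region, averaged over sections (by default the first 10 —
correlations stabilize quickly and this bounds cost on deep stacks).
The map is summarized (`summarize_peak()`) by its peak correlation,
peak offset, background level (the mean over the Chebyshev ring
[m−2, m] of the map border, far from any genuine structure), and the
**half-maximum contour diameter**: the area enclosed by the level set
halfway between background and peak, measured by exact linear
interpolation on a 4-triangle split of each map cell, converted to an
equivalent-circle diameter 2√(area/π). A single above-level map point
contributes the analytic area of its four quarter-triangles, 2/3 px².
Co-localized pairs show a tall narrow peak; pre/postsynaptic apposed
pairs show a lower, wider one — the tests assert exactly this ordering
on synthetic scenes.

## 5. Stain consistency between rounds

`percent_consistent(a, b)` thresholds both rounds (default 1000 a.u.,
strict `>`) and reports 100·|A∩B|/|A∪B| (a Jaccard index in percent).
The chance level is estimated by recomputing the same statistic against
the 180°-rotated second round (`rotate180()`, an exact involution):
rotation preserves every marginal image statistic while destroying
alignment. For independent masks with foreground fractions p_A, p_B the
rotated value approaches 100·p_A·p_B/(p_A+p_B−p_A·p_B), which the tests
confirm in closed form. `consistency_report()` bundles the consistency
percentage, the voxelwise correlation, their rotated nulls, and the
same quantities for the background (complement) masks.

## 6. Puncta segmentation

`segment_puncta()` runs four stages, defaults in
`segmentation_params()`:

1. **Detection floor**: median + 3·MAD of the volume — robust to the
   sparse bright puncta sitting on a camera baseline.
2. **Local maxima**: strict maxima over an ellipsoid neighborhood
   (default radii 2, 2, 1 voxels — set by the anisotropy of the PSF vs
   the voxel), implemented in C++; ties on plateaus break to the lowest
   linear index so results are deterministic.
3. **Marker watershed**: priority-flood from the maxima over the
   above-floor foreground, 6-connected, so touching puncta split along
   intensity ridges. Voxels equidistant between two markers go to
   whichever flood reaches them first in the deterministic queue order.
4. **Gaussian moment fit**: within each watershed region, the
   floor-subtracted intensity-weighted mean and covariance give the
   centroid and σ's; amplitude comes from matching the observed mass.
   Each punctum then reports its integrated intensity over the
   Mahalanobis ≤ 2 mask, together with the implied full model integral.

For an isolated noise-free Gaussian punctum, the within-mask intensity
fraction of the model integral should approach
P(χ²₃ ≤ 4) ≈ 0.7385. On the voxel lattice this converges from below as
the punctum widens: at σ = (2, 2, 1.5) voxels the lattice sum gives
≈ 0.716 (a ~3% voxelization bias), while at σ = (6, 6, 5) it reaches
≈ 0.7375, within 2% of the continuum value. The mass-consistency test
therefore uses a well-resolved punctum; this is a statement about
lattice sums, not a tunable tolerance.

## 7. Density statistics

**Neuropil mask** (`neuropil_mask()`): Otsu's threshold on the synapsin
channel (computed over the full 16-bit range), 3D dilation by an
ellipsoid (default radii 3, 3, 2 voxels ≈ the typical inter-punctum
gap) to bridge between puncta, then filling of enclosed holes up to
`max_hole_voxels`. Somata, nuclei, and vessels — synapsin-dark — stay
out of the mask, so densities are per µm³ of *neuropil*, which is the
biologically comparable quantity across layers.

**ROI densities** (`roi_density()`): a punctum belongs to an ROI if the
voxel containing its centroid is in the ROI-restricted neuropil mask;
density = count / neuropil volume, with the median per-punctum
integrated intensity reported alongside.

**Exact Wilcoxon signed-rank test**
(`exact_wilcoxon_signed_rank()`): zeros dropped, midranks for tied
|differences|, and the exact null distribution built by dynamic
programming over the (doubled, hence integer) midranks — valid *with
ties*, where the textbook no-ties tables are not. Two-sided p is
2·min(P(W ≤ w), P(W ≥ w)) capped at 1. Exact up to n = 25, beyond which
the normal approximation with continuity and tie corrections takes
over. The implementation is independently validated against full 2ⁿ
sign enumeration and against `stats::wilcox.test` in its exact regime.
For n = 7 paired ribbons the two-sided floor is 2/2⁷ = 0.015625
(all pairs concordant) and the next value up is 0.03125 (smallest-rank
pair discordant) — the values paired ribbon studies actually report.

**Across-ribbon comparison** (`compare_rois_across_ribbons()`):
densities are averaged over ROIs of each class within a ribbon, ribbons
missing a class are excluded with a warning, the paired exact test is
applied across ribbons, and the median per-ribbon percent difference
100·(g1−g2)/g1 is reported.

## 8. The synthetic scene generator: realism and limits

`generate_scene(scene_spec(...))` builds ground-truthed volumes from an
explicit generative model:

- Synapse loci: homogeneous Poisson process in the neuropil (default
  density 2 /µm³, a cortical order of magnitude), excluding soma
  interiors.
- Channels (`channel_model()`): each locus expresses a channel with
  probability `participation`; presynaptic channels jitter by ~50 nm
  around the locus, postsynaptic channels sit across the cleft at a
  150 nm offset in a random direction — so pre/pre pairs co-punctate
  and pre/post pairs appose, reproducing the qualitative
  colocalization signature of real data.
- Puncta: 3D Gaussians (default σ ≈ 150, 150, 100 nm), truncated at
  4σ, amplitudes log-normal.
- Nuclei: soft spheres with flat plateau tops in a DAPI-like channel;
  somata excluded from the synapse process.
- Camera: baseline 400 a.u. plus Gaussian read noise σ = 100 a.u.,
  rounded and clipped to 16 bits. All randomness flows through a single
  seed via `withr::with_seed`, so scenes are bit-reproducible.

What the generator deliberately does **not** model: tissue deformation
and section compression (hence rigid-only registration), depth- or
round-dependent staining efficiency, antibody background haze and
off-target binding, vasculature, chromatic shifts, and photobleaching.
It is a validation instrument — it makes ground truth available for
recall/precision, centroid error, transform recovery, and density-ratio
power — not a tissue simulator. Accordingly, measured effect sizes are
*attenuated* relative to planted ones (a planted 2× density ratio
yields median percent differences around 35%, not 50%, because masks,
matching, and Poisson sampling all dilute the effect), which mirrors
how measured differences in tissue understate underlying biology.

`simulate_density_cohort()` and `density_ratio_power()` extend this to
the study level: paired ribbons, two ROI classes, the total synapse
(synapsin) density held fixed while the counted marker's participation
carries the planted ratio — matching the tissue situation where overall
synapse density is roughly constant across layers but a subtype varies.
With 7 ribbons and a 2× planted ratio, essentially every cohort reaches
the exact-test floor p = 0.015625; null cohorts do not.

## 9. Problem sizes and performance

Defaults are chosen so that a full validation cycle runs in minutes on
a laptop: test scenes are 48–96 px laterally and 8–24 sections;
registration fixtures 140–160 px; cohort simulations 48 × 48 × 10 per
ribbon ROI. The algorithms themselves scale to full-frame sections
(2048–2176 × 3200–3328 px, 43–70 sections ≈ 200,000–355,000 µm³): the
C++ morphology kernels are linear in voxels, NCC search is bounded by
`max_shift`, and colocalization maps average over a capped number of
sections. The pipeline (`run_pipeline()`) writes a provenance record
(seed, config MD5, package version) with every run so that any figure
can be regenerated bit-identically from its config.
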