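---
title: "Assessing geometric equivalence of CT-derived bone models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing geometric equivalence of CT-derived bone models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonequiv)
```

## The question this package answers

Weight-bearing cone-beam CT (WBCT) images the knee under physiological
load, but before it can replace conventional multidetector CT (MDCT) for
3D bone modelling one must show that the two modalities produce the *same
bone surfaces* to within a clinically negligible margin. `bonequiv`
implements the full comparison pipeline: triangle meshes are extracted
from binary bone segmentations of each modality, the WBCT mesh is rigidly
registered onto its MDCT counterpart, signed vertex-to-surface distances
are computed over the anatomy covered by both scans, and the pooled
per-bone mean distances are subjected to an equivalence analysis (summary
intervals, normality checks, a one-sample TOST against a ±0.15 mm margin,
and a noncentral-*t* power analysis).

The geometric stages operate on four knee bones — distal femur, proximal
tibia, proximal fibula and patella — with the axial scan height of the
cone-beam system (200 mm) shorter than the MDCT's (376 mm), so the long
bones are truncated differently in the two scans while the patella is
always fully covered.

## Pipeline model and assumptions

1. **Isosurface extraction.** Masks are binary; surfaces are extracted by
   marching cubes at level 0.5 with vertices placed in physical mm
   (`origin + index * spacing`, axes x = column, y = row, z = slice).
   The implementation traces the per-cube intersection polygons from
   per-face segments, resolving ambiguous (diagonal) face configurations
   with a fixed inside-connected rule applied identically from both sides
   of every face; the mesh is therefore crack-free and consistently
   oriented by construction. One background voxel of padding closes masks
   that touch the array boundary — genuine field-of-view truncation is
   handled later by the FROI, not by leaving holes.
2. **Orientation.** A breadth-first winding pass plus a divergence-theorem
   volume sign makes normals point outward, which fixes the sign
   convention of all distances.
3. **Registration.** Iterative closest point with *exact
   closest-point-on-triangle* correspondences (bounding-volume hierarchy),
   a Kabsch/SVD rigid step with reflection exclusion, and classic
   transform-sequence extrapolation to accelerate the slow geometric tail.
   Strictly rigid: no scaling, no shear.
4. **FROI.** The focused region of interest keeps vertices whose axial
   coordinate lies in the intersection of both meshes' axial extents,
   shrunk by a 2 mm margin at each *cut* end (an end where the two extents
   differ, i.e. at least one scan truncated the bone there). Natural bone
   ends are kept whole, and the patella is exempt entirely.
5. **Signed distances.** For each retained WBCT vertex, the unsigned
   distance to the nearest point of the MDCT surface, signed positive when
   the vertex lies outside the closed target (WBCT model locally larger).
   Inside/outside comes from the winding parity of the closed target — a
   ray-parity test with a brute-force solid-angle winding number as
   reference and fallback — rather than from local normals, which are
   unreliable near thin structures such as the fibula. For non-watertight
   targets an explicit opt-in fallback signs by angle-weighted
   pseudo-normals at the closest surface feature.
6. **Statistics.** Per-scan summaries use the population (÷n) standard
   deviation and the population-spread interval mean ± 1.96 sd — the
   convention of the published summary tables this package reproduces.
   Inference uses the sample (n−1) deviation inside the TOST standard
   error. Equivalence is declared when both one-sided *t* tests against
   ∓0.15 mm reject at α = 0.05, equivalently when the 1−2α = 90% interval
   lies inside (−0.15, 0.15) mm; the two formulations are asserted to
   agree. The reported interval is the standard TOST 90% interval even
   though equivalence tables often label it "95% CI".

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| isosurface level | 0.5 | mask fraction | midpoint of a binary mask |
| pipeline pre-smoothing `smooth_mm` | 0.6 | mm (σ) | see below; ≈ one coarse voxel |
| ICP `tol` | 1e-6 | mm RMS change | far below voxel size; reached quickly with acceleration |
| ICP `trim` (pipeline) | 0.10 | fraction | discounts field-of-view cut caps |
| ICP init (pipeline) | identity | — | scans share a world frame; see below |
| FROI margin | 2.0 | mm | removes cut-edge artifacts observed along FROI borders |
| TOST margin Δ | 0.15 | mm | half the smallest voxel dimension (0.3 mm) |
| α | 0.05 | — | conventional |
| color range | ±1.0 | mm | per-scan sds span ≈ 0.26–1.24 mm |

## Numerical choices that mattered

**Binary masks bias raw marching-cubes areas and distances.** On a
binary-mask sphere the extracted volume is essentially exact (<0.1%
error) but the staircase surface overestimates area by roughly 9% and
pulls closest-point distances *low* by about 10% of the voxel size (a
rough target surface always has a protrusion nearer than the true
offset). A deterministic Gaussian pre-smoothing of the mask with σ = 0.6
mm — about one coarse voxel — removes both effects; a 0.30 mm concentric
offset is then recovered as 0.295–0.298 mm. The smoothing is specified in
*physical* units and applied to both grids: smoothing in voxel units
would erode the high-resolution grid less than the low-resolution one
(erosion ≈ σ²·curvature), leaving a systematic inter-modality offset of
0.02–0.03 mm. Raw-mask extraction (`smooth_sigma = 0`) remains the
default of `extract_isosurface()` itself and is what the volume oracles
test.

**Registration under asymmetric truncation.** Initializing ICP by
centroid alignment is wrong for this problem: because the cone-beam scan
is axially shorter, the two centroids differ by on the order of a
centimetre along the shaft, and ICP then locks into a slid pose along the
near-cylindrical shaft (a low-cost sliding mode). The pipeline therefore
starts from the shared world frame (identity) and trims the 10% worst
correspondences, which also discounts the flat caps that close the meshes
at the scan boundary. Centroid and principal-axes initializations remain
available for meshes in unrelated frames. A transform-sequence
extrapolation step (accepted only when it lowers the RMS) collapses the
slow geometric convergence tail; without it the 10-nm RMS-change
tolerance routinely needs more than 100 iterations.

**Inside/outside.** The winding parity of the closed target classifies
query points; the implementation casts rays along a fixed irrational
direction sequence, retries on edge grazes, and falls back to the exact
solid-angle winding number, so the result is deterministic without a
random-number stream.

**Kolmogorov–Smirnov conventions.** `ks_normal()` computes the standard
two-sided D against a normal with the sample mean and sample (n−1)
deviation, and converts it with the *asymptotic* Kolmogorov distribution
(no Lilliefors correction, no small-sample exact distribution) — the
convention with which the published D/p pairs are internally consistent.
Both shortcuts are anti-conservative and are documented as such. Note a
reproduction limit: D is a supremum statistic, and the per-scan means are
published rounded to two decimals; the ties introduced by rounding
inflate the recomputed D by ~0.006, so the published D values (computed
on unrounded data) are recovered only to about that accuracy — slightly
outside the ±0.005 one would hope for — while W, the group means, the
TOST p-values and the interval bounds all reproduce within printed
precision. The corresponding check in the test suite is intentionally
left at its nominal tolerance.

**Report formatting.** Summary values print with two decimals, extended
to three below 0.01 and four below 0.001, which reproduces printed values
such as "0.006" and "−0.0004".

**Power analysis.** Interpreted as a two-sided one-sample *t* test — the
only standard test family for which d = 0.5, α = 0.05 and power 0.80
give a minimum of 34 samples — with power computed from the noncentral
*t* distribution and verified against an independent chi-square-mixture
quadrature.

**Pooling caveat.** The published analysis pools all bones of all
subjects into one sample of 56 per comparison group, ignoring
within-subject correlation. The package reproduces this as published;
a mixed-effects treatment is out of scope and the caveat is deliberate.

## What the phantom emulates — and what it does not

The synthetic module replaces patient and cadaver scans with implicit
shapes: smooth blends (polynomial smooth-minimum) of ellipsoids and
capsules loosely evoking each bone, with seeded asymmetric surface bumps
so that rigid registration has a unique optimum. The two modalities are
emulated by voxelizing the same bone twice — spacings 0.30×0.30×0.60 mm
vs 0.49×0.49×0.625 mm, axial coverage in the 200/376 ratio so femur,
tibia and fibula are truncated but the patella never is — after applying
a known rigid misalignment, an optional uniform surface offset δ
(level-set shift; the systematic size difference between modalities), and
band-limited smooth surface noise (48 balanced-sign Gaussian lobes,
amplitude = σ_noise, near-zero surface average so the expected mean
distance stays δ). Defaults: δ = 0, σ_noise = 0.1 mm, within the 0–0.3 mm
range suggested by the published per-scan tables; bone scales femur 60,
tibia 55, fibula 40, patella 24 mm.

The phantom does **not** emulate CT physics (noise texture, beam
hardening, reconstruction kernels), cartilage or joint articulation,
segmentation-protocol variability, or realistic anatomy. Passing the
phantom tests therefore demonstrates that the *geometry and statistics
pipeline* is unbiased and accurate under known ground truth — not that
any particular scanner pair is equivalent. The published per-scan tables
enter as a packaged fixture; everything downstream of them (group
summaries, normality, TOST, power) is recomputed, while the per-scan
values themselves derive from real scans and cannot be recomputed here.

## Problem sizes

Full-scale phantoms (scale 1) produce grids of roughly 1–2.5 million
voxels and meshes of 10⁴–10⁵ vertices; one bone pair runs in a few
seconds on one core. The end-to-end recovery check uses 16 full-scale
pairs (4 subjects × 4 bones, δ ∈ {−0.2, 0, 0.2, 0.3} mm, σ_noise = 0.1
mm). Unit tests use reduced scales (0.4–0.6) and coarser grids, which
keeps the whole suite under a minute of geometry time; statistical
simulations (equivalence-decision agreement, type-I error at the margin,
power sanity) use 10³–5·10³ replicates.

## Known limitations

* δ-recovery accuracy is bounded by discretization at ~0.02–0.03 mm RMSE
  per pair — adequate against the 0.15 mm margin, but not arbitrarily
  small; it scales with voxel size.
* The FROI cut-end rule detects truncation by comparing the two meshes'
  extents; if both scans were cut at exactly the same axial level the end
  would be treated as natural. The per-bone exemption list covers the
  patella case explicitly.
* The signed-distance sign is undefined exactly *on* the target surface;
  such points have zero distance, so the product is unaffected.
* `ks_normal()` and the pooled TOST inherit the anti-conservative
  conventions discussed above by design, for comparability.
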