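# bonequiv

Geometric equivalence assessment of CT-derived 3D bone models.

Weight-bearing cone-beam CT (WBCT) images the knee while the patient
stands under load; multidetector CT (MDCT) is the established reference.
Before WBCT-based 3D bone models can be used for surgical planning, one
must show that the two modalities produce the *same bone surfaces* to
within a clinically negligible margin. `bonequiv` is for imaging
scientists and orthopaedic-engineering groups running exactly that kind
of modality-validation study.

## What it computes

For each bone (distal femur, proximal tibia, proximal fibula, patella)
segmented in both modalities:

1. **Meshing** — marching cubes on the binary masks at level 0.5, with
   vertices in physical mm (`origin + index × spacing`) and a
   face-consistent resolution of ambiguous cube cases, so surfaces are
   closed and consistently oriented.
2. **Registration** — iterative closest point (exact closest point on the
   target surface, Kabsch/SVD rigid step, acceleration of the geometric
   convergence tail); strictly rigid.
3. **FROI** — a focused region of interest restricts the comparison to
   the axial extent covered by both scans, minus a 2 mm margin at each
   cut end; the patella, fully covered by both scans, is exempt.
4. **Signed distances** — for every retained WBCT vertex `i`, the
   distance to the nearest point of the closed MDCT surface,

   `d_i = ± min_{y ∈ S_MDCT} ‖v_i − y‖`,

   positive when the vertex lies outside the target (WBCT model larger;
   inside/outside by winding parity). Per bone the package reports the
   mean `μ`, the population sd `σ`, and the spread interval `μ ± 1.96 σ`.
5. **Equivalence statistics** — pooled per-scan means are tested with the
   two one-sided tests (TOST) procedure: with margin `Δ = 0.15` mm
   (half the smallest voxel dimension) and `SE = s/√n`,

   `t_low = (x̄ + Δ)/SE`, `t_up = (x̄ − Δ)/SE`,

   equivalence is declared when both one-sided tests reject at
   `α = 0.05`, equivalently when the 90% (1−2α) t-interval lies inside
   `(−Δ, +Δ)`. Shapiro–Wilk and Kolmogorov–Smirnov checks, Q–Q points,
   and a noncentral-t power analysis (`d = 0.5, α = 0.05, power = 0.8 →
   n ≥ 34`) complete the layer.

A synthetic phantom module generates paired segmentations of all four
bones with known ground truth (rigid misalignment, uniform surface
offset δ, smooth surface noise, asymmetric fields of view at the 200/376
mm height ratio and the 0.30×0.30×0.60 vs 0.49×0.49×0.625 mm spacings),
so the whole pipeline is testable without scan data. A packaged fixture
(`inst/extdata/knee_mean_distances.csv`) carries the published per-scan
mean distances from which the statistics layer is reproduced.

## Worked example

```r
library(bonequiv)

# published per-scan mean distances: 4 patients + 10 single-leg cadavers
fx <- load_fixture_tables()
g1 <- fixture_group_means(fx, "patient+single")
tost_one_sample(g1, margin = 0.15, alpha = 0.05)
#> One-sample TOST: mean -0.06 mm (n = 56), margin +/-0.15 mm
#>   p(lower) = 1.62e-08, p(upper) = 5.99e-21
#>   90% CI [-0.08, -0.03] mm -> equivalent

power_sample_size(d = 0.5, alpha = 0.05, power = 0.80)
#> [1] 34

# one synthetic bone pair with a known +0.30 mm surface offset
spec <- phantom_spec("patella", delta = 0.30, sigma_noise = 0.1, seed = 7)
pair <- generate_bone_pair(spec)
res  <- compare_bone_pair(pair$grid_a, pair$grid_b, bone = "patella")
res$summary
#>      bone    n      mean         sd     lower     upper
#> 1 patella 8884 0.3107358 0.08975221 0.1348215 0.4866502
```

The TOST mean of −0.06 mm with a 90% interval of [−0.08, −0.03] mm sits
well inside the ±0.15 mm margin, so the pooled WBCT/MDCT surface
differences are statistically equivalent; the phantom pair shows the
geometric pipeline recovering a known 0.30 mm offset as 0.31 mm with a
sub-voxel spread.

Whole studies run through `run_study()` / `write_report()` (phantom mode,
a file roster of NIfTI/MetaImage masks, or fixture-only mode), or from a
shell via the thin wrapper `inst/cli/bonequiv.R`
(`simulate | compare | stats | run`). Colorized PLY meshes (blue =
MDCT larger, red = WBCT larger) and CSV/JSON tables are written per run.

## Vignette

`vignettes/bone-model-equivalence.Rmd` documents the model, its
assumptions, the parameter choices (smoothing, ICP initialization and
trimming, FROI margin, statistical conventions) and the phantom's scope
and limits.
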