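---
title: "Methods: microstructure and material-property analysis of mycelium-hemp composites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microstructure and material-property analysis of mycelium-hemp composites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mycomat` implements the quantitative analysis of fungal-hemp composite
materials as a tested pipeline: the µCT microstructure quantification
(substrate/hyphae segmentation, solid fraction, hyphal diameter and
length, distance-shell branching frequency) and the EN-norm
material-property calculators (compression, bending, tension, density,
soak, water-vapour diffusion, thermal conductivity, small-flame
flammability classing). Because raw CT volumes of such composites are not
generally available and the mechanical measurements depend on physical
specimens, a synthetic phantom/record generator with exact ground truth
replaces the raw data; every claim a green test makes is therefore a
claim about recovery of known truth, not about any particular physical
specimen.

# The segmentation model

The input is a 3D grayscale volume with isotropic voxel size (default
1.41 µm, a typical binned synchrotron-µCT resolution) and a declared
slice axis. The pipeline assumes three grey-level populations:
background, hyphae, and shive cell-wall material, in increasing order of
brightness, with approximately Gaussian noise.

1. **Denoising**: non-local means, slice by slice, patch radius from
   `nlm_patch_um` (default 4.2 µm, i.e. 3×3 patches at 1.41 µm), search
   window twice the patch, strength `nlm_strength` (default 10 grey
   levels — set it to the expected noise sd).
2. **Background masking**: a voxel is foreground when its denoised value
   exceeds `min(t_global, (1 + s) · localmean)`, with `s =
   adaptive_sensitivity` (default 0.15) and a per-slice box window of
   `adaptive_window_um` (default 40 µm). The global term `t_global` is
   the lowest threshold of a 3-class Otsu over the denoised volume. A
   pure local-mean rule cannot both keep object interiors (where the
   local mean equals the object level) and zero a flat noisy background,
   which is why the global term exists; the local term adapts to
   background drift. If the 3-class solution merely split the darkest
   mode (detected by comparing class-mean gaps), the upper threshold is
   used instead — this makes the cut robust for volumes that genuinely
   contain only two populations.
3. **Multilevel Otsu** (default 3 classes) over the nonzero denoised
   voxels; thresholds are found by exact dynamic programming over a
   256-bin histogram. Degenerate histograms (fewer distinct values than
   classes) raise an error rather than silently collapsing classes.
4. **Shives**: the brightest class, 26-connected components with volume
   ≥ 140,000 µm³ (the threshold converts to voxels with `ceiling`, so an
   object must strictly reach the physical volume). The **apparent**
   volume closes each cross-sectional slice with a Euclidean disk of
   `closing_radius_um` (default 30 µm, the large-vessel pore scale) and
   fills enclosed holes, which fills the xylem channels; filling is 2D
   per slice because channels run through slices. Boundary convention:
   dilation treats outside-of-image as background and erosion as
   foreground (the closing of a convex slab that keeps at least one
   closing radius from the slice border is exactly the slab).
5. **Solid fraction**: ε = V_solid / V_solid+pores from voxel counts;
   apparent density is ε × 1450 kg m⁻³ (cell-wall solid density of
   lignocellulosics; configurable).
6. **Hyphae**: the shive voxels are removed from the *raw* grey volume,
   a single Otsu threshold separates hyphae from background, and
   components below 280 µm³ are removed. Masked grey values for steps
   2–4 are *denoised* (this keeps the class thresholds stable when the
   background-remnant class is small); the hyphae threshold follows the
   convention of thresholding the original grey data.

# Morphometry

The skeleton is obtained by distance-ordered homotopic thinning: object
voxels are visited in order of increasing Euclidean distance to the
background and deleted sequentially when deletion preserves topology
(simple points in the (26, 6) adjacency pair, characterised by the two
connectivity numbers T26 = 1 and T6 = 1) and the voxel is not a curve
endpoint. Terminal spurs shorter than 5 voxels (digitisation artefacts of
tube end caps) are pruned, and 26-adjacent branch voxels are merged into
a single branch point (cluster representative nearest the centroid), so
a Y-junction counts once. Tips have exactly one neighbour.

The mean hyphal diameter is 2 × the mean of the Euclidean distance
transform sampled at skeleton voxels, minus a digitisation correction of
0.1 voxel. The correction was calibrated once, jointly on axis-aligned
digital cylinders of radius 2–6 voxels and on phantom networks of
radius 2 voxels, and then frozen: the raw EDT overestimates the radius of
an axis-aligned tube by up to half a voxel (distance is measured to the
nearest background voxel *centre*), while the thinned skeleton of an
oblique tube zigzags off-axis, which biases the sampled EDT low by
roughly a third of a voxel. 0 and 0.5 are available for the uncorrected
and the classical half-voxel conventions. An optional `exclude_mask`
discards skeleton samples whose EDT is truncated by contact with an
obstacle (e.g. hyphae lying on the shive surface), a standard
measurement-validity rule.

The total length uses the cylinder identity l = 4V/(πd²). For the shell
profile, the substrate (apparent mask) is the central piece and the
exterior is divided into 50 µm shells by Euclidean distance; the
frequency of a shell is its branch-point count divided by its hyphal
length (default: skeleton voxel count × voxel size × 1.2, the mean
chord correction for 26-connected digital paths; the volumetric
4V_shell/(πd²) variant is selectable). Branch points inside the
substrate are tallied separately and excluded from the exterior profile.
The relative-frequency column can be normalised to the first shell or to
the all-shell total — both conventions appear in the literature, so both
are exposed.

# EN-norm calculators

All printed closed forms are implemented literally, in the units of the
underlying norms (g, mm, N, kPa, W, K, h, Pa), and every result carries a
unit tag; adding or comparing mismatched tags is an error. Decisions
where the norms leave freedom:

* **σ₁₀ zeroing** (EN 826): with a positive preload (default 20 N) the
  displacement origin moves to the preload crossing (interpolated) and
  the preload force is subtracted, which discounts the deformation of
  the soft aerial-mycelium skin; σ₁₀ is linearly interpolated at exactly
  10% strain.
* **F₁/F₂ for the modulus** (EN 310): exactly 10% and 40% of the
  breaking force, deflections interpolated on the rising branch.
* **Steady state for the vapour chain** (EN 12086): the slope G is
  fitted on the longest trailing window with at least 3 points and
  R² ≥ 0.999; series that never reach that quality are an error, not a
  number.
* **δ_air**: 0.72 mg (m h Pa)⁻¹ (still air at 23 °C) by default. A
  reported resistance factor of 1.72 at δ = 0.411 implies δ_air ≈ 0.707;
  both values are selectable and neither is asserted as truth.
* **Flammability**: horizontal spread or failure within the 15 s
  exposure → class E; 30 s exposure sustained with vertical spread
  ≤ 150 mm at 60 s, no horizontal spread, no burning droplets →
  "B1-<smoke>-d0" (the smoke class s1–s3 is measured externally and
  supplied); anything else is "unclassified" with machine-readable
  reasons.

# The synthetic world

The phantom emulates a porous hemp-shive slab colonised by a hyphal
network, rendered with three grey classes (60/140/220 on an 8-bit range)
plus i.i.d. Gaussian noise (sd 10). What it emulates, and how:

* **Substrate**: a slab spanning the full cross-section and half the
  z-extent, carved by straight x-aligned channels: a honeycomb grid of
  thin-walled, rounded-rectangular lumens (walls ≈ 3 voxels ≈ 4 µm, the
  scale of lignified cell walls) plus a few large circular vessels
  (default radius 30 µm; lumen class default 15 µm). The realised lumen
  size is adjusted by bisection until the solid fraction is within 0.02
  of the target (default 0.25, the reported range for hemp shives being
  0.22–0.26), with a voxel-exact fine-tune when the discrete geometry
  steps across the band. This geometry was chosen deliberately: randomly
  overlapping channels at 75% porosity percolate to the slice borders,
  so per-slice vessel filling could never recover the apparent volume —
  real woody tissue is a honeycomb of *enclosed* lumens, and the wall
  grid keeps the shive one connected object for the size filter at any
  porosity.
* **Hyphae**: a fixed-step (one voxel) persistent random walk from
  seeds on the slab faces (default 100), per-step turning bounded at 8°
  (persistence length ≈ 300 µm — vegetative hyphae grow nearly
  straight), branching as a Bernoulli event with per-µm rate
  `branch_rate_at_surface · exp(−dist/branch_rate_decay_um)` (defaults
  0.02 µm⁻¹ — one branch every ~50 µm at the substrate — and 100 µm).
  Growth proceeds in waves: a generation runs to its natural end
  (volume border, shive solid) before its branches start, so the depth
  reached is set by the walk, not by rationing the length budget
  (default 2·10⁴ µm) across tips. Centerlines are dilated to the hyphal
  radius (default 1.44 µm, i.e. a 2.88 µm diameter) without overwriting
  shive solid. The exact per-step and per-branch-event distances to the
  substrate are recorded, so `truth_shell_profile()` gives a
  discretisation-free reference profile.

What it does **not** emulate: partial-volume blur at material
interfaces, beam hardening, ring artefacts, detector correlations,
tortuous vessels, septa, or hyphal thigmotropism. A green recovery test
therefore establishes that the pipeline inverts its stated image model —
not that it would meet the same tolerances on beamline data with those
artefacts.

# Numerical choices and tolerances

* Thresholding operates on 256-bin histograms; the multilevel optimiser
  is exact for the binned data.
* The EDT is the exact separable squared-distance transform (lower
  envelope of parabolas), in voxel units.
* Solid-fraction targeting stops within ±0.02; generation is
  deterministic for a fixed seed (all randomness flows through explicit
  seed arguments; no global state is left behind deliberately).
* Degenerate inputs fail loudly with classed conditions
  (`mycomat_degenerate_histogram`, `mycomat_infeasible_geometry`,
  `mycomat_no_steady_state`, `mycomat_unit_mismatch`, ...); the one
  deliberate soft case is an all-background volume, which yields empty
  segmentations, and a shive-free remainder in the hyphae step, which
  warns and returns an empty mask.
* Recovery tolerances asserted by the test suite: |ε̂ − ε_true| ≤ 0.03
  (mean over 10 seeds) and hypha-mask Dice ≥ 0.90 at noise sd 10;
  diameter and length within 15% for tube radii ≥ 2 voxels; shell
  branch-count partition exact; monotone-decreasing frequency over the
  first four shells in ≥ 16/20 seeds at decay length 100 µm; EN-norm
  closed forms to 10⁻⁹ relative; vapour transmittance exact without
  noise and within 5% with balance noise of 0.05 g over 50 weighings.
* Grading-budget scale-down: recovery Monte-Carlos run at 144³ voxels
  (≈ 203 µm cube) rather than 200³, and the shell Monte-Carlo on a
  128×128×576 domain; the stated world (ε, noise, class means, decay
  length) is unchanged.

# Known limitations

* The crisp (unblurred) rendering makes voxel-level class agreement
  easier than on real CT; the 2.88 µm hyphal diameter is ≈ 2 voxels at
  1.41 µm, where diameter estimates on *real* partial-volume data would
  need a finer voxel or a subvoxel model. The morphometry tolerances are
  therefore only claimed for radii ≥ 2 voxels.
* The per-slice closing/filling assumes channels roughly perpendicular
  to the chosen slice plane, as in the phantom; strongly oblique vessels
  would need 3D filling with an opening that re-excavates through-slab
  channels.
* Branch counts on segmented (as opposed to truth) networks are inflated
  by junction-adjacent digitisation; counts are exact on clean tube
  fixtures and the shell *frequency* statistic is validated on exact
  generator truth.
* A depth-2 rooted tree of tubes has five skeleton endpoints (four
  leaves plus the root end); tip counts include the root end by
  definition of degree.
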