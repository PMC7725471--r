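---
title: "Quantifying dense-core vesicle neighborhoods in cryo-electron tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dense-core vesicle neighborhoods in cryo-electron tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiclehood)
```

## The measurement problem

Pancreatic beta cells store insulin in dense-core secretory vesicles.
As a vesicle matures on its way from the Golgi to the plasma membrane,
insulin crystallizes into an electron-dense core surrounded by a lighter
halo; immature vesicles have a uniform lumen. Cryo-electron tomography
of cryo-FIB-milled lamellae (thin slabs of vitrified cell, roughly
180–250 nm thick) images these vesicles in a near-native state, but two
geometric facts complicate quantification:

1. **The missing wedge.** A single-axis tilt series covers about
   −60°…+60°, leaving a wedge of Fourier space unmeasured. Membranes
   whose normal points along the beam (z) axis — the top and bottom
   poles of every vesicle — lose contrast and are often invisible.
   Direct 3D integration of a segmented vesicle therefore
   underestimates its volume.
2. **The lamella cuts vesicles.** Typical vesicle diameters (roughly
   200–280 nm with the membrane) are comparable to the lamella
   thickness, so the milling planes physically cut most vesicles.

Both problems spare the *equatorial* cross section. `vesiclehood`
therefore implements the central-cross-section estimator: from one
vesicle's cross-section area $A$,

$$ d = 2\sqrt{A/\pi}, \qquad V = \frac{\pi d^3}{6}, $$

assuming near-spherical vesicles. Around that estimator the package
builds the full analysis: segmentation, dense-core maturity
classification, metal-cluster detection, assignment of tomograms to
distance-defined subcellular regions, and per-region neighborhood
statistics (mature fraction, diameter distribution, count density,
volume fraction) with Welch and Mann–Whitney comparisons.

No public tomograms accompany the study this package models, so every
stage is validated against a synthetic tomogram generator with known
ground truth. The generator is first-class, tested code, not a fixture.

## The synthetic generator and what it emulates

`generator_config()` describes one tomogram: a voxel grid whose z
extent *is* the lamella slab, and a vesicle population. Vesicles are
non-overlapping spheres:

* **Lumen diameters** are truncated-normal. The shipped presets carry
  the published per-region calibrations: region 1 (interior, 3–8 µm
  from the nuclear membrane) 196 ± 42 nm, 12 % mature, 16 vesicles/µm³
  over 5 tomograms; region 3 (peripheral, within 2 µm of the plasma
  membrane) 266 ± 52 nm, 32 % mature, 51/µm³ over 10 tomograms. The
  mid band (region 2, 3–6 µm from the PM) has no published per-region
  moments, only its sample size, so its preset interpolates midway
  (230 ± 47 nm, 22 % mature, 33/µm³); treat region-2 numbers as
  illustrative, not calibrated. Whether real size variation is
  Gaussian is unknown; the truncated normal is a modeling choice.
* **"Diameter" means lumen (inner-membrane) diameter**; the outer
  diameter adds twice the 7 nm membrane. The measured estimator works
  on the filled (membrane + lumen) profile, so it targets the *outer*
  diameter, and all truth comparisons use outer diameters. The
  published protocol does not state which boundary the annotators
  traced; this is a recorded convention, not an inference.
* **Maturity** is Bernoulli per vesicle; a mature vesicle gets a
  concentric core sphere of half the lumen diameter.
* **Metal clusters** occur in 10 % of vesicles (one or two,
  equiprobable), built from 3–8 nm particles at ~35 % granular fill,
  30–90 nm across (clamped to fit the lumen). In mature vesicles they
  sit attached to the core surface; in immature ones they are uniform
  in the lumen.
* **Placement** is random sequential addition, largest first, with a
  minimum surface-to-surface gap of 20 nm: real vesicle membranes carry
  coats and tethers and do not touch, and the gap also exceeds twice
  the closing radius plus the threshold-crossing growth, so distinct
  vesicles remain separable by any threshold segmentation. Centers
  keep one radius (plus a 10 nm detector margin) from the lateral
  faces; in z they may approach the lamella surfaces to within
  `min_z_margin_nm` (40 nm, and never closer than the core radius plus
  membrane), so large vesicles are cut by the slab exactly as in real
  lamellae while cores and equators stay inside.
* **Packing limits.** At the peripheral calibration (51/µm³ of ~280 nm
  spheres in a 220 nm slab, i.e. ~56 % occupancy) random sequential
  addition jams below the requested count: that occupancy is near
  random close packing, which no rejection sampler reaches. A request
  whose expected in-slab volume exceeds 90 % of the slab is refused
  outright; otherwise the sampler places what geometry permits
  (10^5 attempts per vesicle) and reports the achieved count with a
  warning — never a silent shortfall. All validation compares the
  pipeline against the *achieved* field.

Rendering draws membrane shells (intensity 1), lumens (0.15), cores
(0.6) and cluster particles (1.5) over a zero background, bright on
dark (a flag inverts the sign). The missing wedge is applied in
Fourier space: coefficients with $|k_x| < |k_z|\tan\theta$ (y tilt
axis, $\theta$ = 30° for a ±60° series) are zeroed, except the always-
measured $k_z = 0$ plane. Because the mask has no $k_y$ dependence the
package applies it as per-slab 2D FFTs, which is mathematically
identical to the 3D form and considerably faster. The mask is
symmetric under $k \to -k$, so the output is real; it is a projection,
hence idempotent and energy-decreasing. Gaussian noise is added last,
with a seeded generator.

What the generator does **not** emulate: the contrast transfer
function, dose weighting, reconstruction artifacts other than the
wedge, crowded non-vesicle organelles (ER, Golgi, ribosomes,
microtubules), non-spherical vesicles, and intensity inhomogeneity.
Passing tests demonstrate correctness of the *measurement chain* under
controlled corruption; they do not certify performance on real
tomograms, where segmentation error is dominated by exactly the
omitted nuisances.

## Segmentation (a stand-in for manual annotation)

The published analysis segmented vesicles manually with a density
threshold. `segment_vesicles()` automates the same idea:

1. Gaussian pre-smoothing (σ = 3 nm) so voxel noise cannot speckle the
   binarization;
2. threshold at 0.30 (absolute, on the smoothed density — about 40 %
   of the smoothed membrane peak);
3. morphological closing with a 7 nm ball (one membrane thickness),
   which seals the small ring breaks the wedge and noise leave;
4. hole filling per z-slice, then in 3D. Per-slice filling is what
   recovers the lumen: away from the poles every slice shows a closed
   membrane ring even when the 3D shell is open at the top and bottom;
5. a boundary refinement: the threshold isosurface of a *smoothed*
   thin shell sits up to ~σ/2 outside the true surface, which would
   bias diameters by ~1.5 % (and volumes by ~4.5 %). The final mask is
   therefore the union of the raw (unsmoothed) threshold crust,
   confined to one voxel around the smoothed support, with the
   smoothed support eroded by σ. For a rendered step edge the raw
   crossing is unbiased; measured diameters on noiseless phantoms are
   exact to within rasterization (&lt;0.1 %). Every term is monotone
   in the threshold, so total foreground remains monotone;
6. 26-connected components, a size gate on equivalent spherical
   diameter (60–700 nm), and boundary handling.

The defaults (threshold, σ, closing radius) were frozen from a pilot
grid under the default wedge + noise corruption, where they give
recall = precision = 1.0 at IoU ≥ 0.5 and sub-percent diameter error;
they are regression-tested at exactly those settings. The
correspondence between this detector and any human annotator's masks
is untestable and not claimed.

Objects touching the *lateral* (x/y) grid faces are flagged
`truncated`: their in-plane profile is cut, so they carry no diameter
and contribute their labelled voxel volume to volume-fraction
accounting. Objects cut only by the lamella surfaces (z faces) are the
expected slab geometry: they are measured from the largest-area slice,
which for a sphere whose center lies in the slab is the equator. The
centroid-slice rule (with ties toward the larger area) is kept for
fully interior objects, where centroid and maximum coincide for
spheres; the max-area rule is also available globally for sensitivity
analysis. Each record carries `in_volume_nm3` — the sphere volume
clipped to the slab, computed from the measured diameter and the
equatorial slice position — so volume fractions count only in-tomogram
material.

## Maturity classification

The published criterion is qualitative: a vesicle is mature if it has
a dense core. The package operationalizes it as a contrast statistic:

1. erode the vesicle mask by 30 % of its equivalent radius, at least
   25 nm (membrane + 4σ of the matched filter), treating out-of-volume
   as background so lamella-cut vesicles are eroded from the cut face
   (the converging membrane ring there would otherwise leak into the
   interior);
2. matched-filter the densities with a 4.5 nm Gaussian: a core
   announces itself by aggregate contrast over core-sized
   neighborhoods, not voxel by voxel. The scale satisfies a geometric
   constraint — erosion depth plus 3σ core rolloff must stay inside
   the lumen halo of the smallest vesicles scored (lumen ≳ 130 nm at
   the defaults); smaller vesicles may be scored conservatively;
3. exclude the metal tier by *texture*, not absolute density: granular
   deposits keep a large local density SD at particle scale (above
   0.35 in a 4.5 nm window) even when the wedge attenuates their
   absolute density below any fixed tier, while cores, lumens and
   membranes are smooth (the core edge reaches at most step/2 ≈ 0.22,
   plus noise in quadrature). The exclusion is seeded only in the deep
   interior (the membrane edge also carries texture, but it lives
   within a membrane thickness + 2σ of the mask boundary), widened by
   2σ for the filter halo, and extended ±30 nm along the beam axis
   because the wedge smears a deposit into smooth ghosts above and
   below it that would otherwise score as core-like material. Without
   all of this, a metal cluster inside an *immature* vesicle is
   miscalled as a core — clusters are denser than cores and occur in
   both classes;
4. gate candidate voxels at median + 3 robust SD (1.4826 × MAD) of a
   core-free baseline: the shallow "halo ring" of the interior just
   inside the erosion depth, which a concentric core never reaches
   even when it fills most of the deep interior;
5. keep 26-connected candidate blobs of equivalent diameter ≥ 30 nm;
   the statistic is (mean smoothed density of the densest blob − median
   of the remaining interior) / robust SD of the remaining interior,
   with a guard band of 3σ around the blob excluded from the baseline
   (the filter smears the core edge over that band). A vesicle is
   mature when a qualifying blob exists and the statistic reaches 3.

Degenerate cases are explicit: a zero-spread baseline (the noiseless
limit, where the true statistic diverges) reports a documented cap
(10^6) when the blob is denser by more than 0.1 % of the object's
dynamic range, and 0 otherwise; an interior below 27 voxels yields NA
(no call). On noiseless synthetic data the classifier reproduces
ground truth exactly; at noise equal to half the core–lumen contrast
it stays above 99 % accuracy in the seeded validation, with the
statistic saturating for true cores and 0 for true immature interiors.
Raising the threshold can only remove mature calls. The statistic is
validated only against synthetic truth; the paper's call was made by
eye and no quantitative criterion exists to compare against.

Metal clusters are *detected* (as opposed to excluded) at the
metal-density tier: voxels above 1.2 inside the interior eroded by a
12 nm membrane margin (so noisy membrane voxels crossing the tier
cannot form false deposits), closed with a 6 nm ball so the 3–8 nm
particles of one deposit — and the voxel dropout the wedge causes
within it — merge, counted when the blob's maximal extent reaches
30 nm. A deposit at exactly the 30 nm reported minimum that hugs the
membrane can fall below the extent gate; detection is therefore
validated as zero false positives with ≥ 90 % recall and prevalence
within the binomial interval of the planted 10 %. For mature vesicles
the blob's adjacency to the core is recorded, with the reach widened
by the 2σ exclusion halo that separates the reported core blob from a
touching deposit.

## Regions and neighborhood statistics

Tomograms are binned by their distance from a membrane landmark:
region 1 at 3–8 µm from the nuclear membrane, region 2 at 3–6 µm from
the plasma membrane, region 3 within 2 µm of the plasma membrane
(closed intervals; both landmarks are needed because each is only
visible in its own acquisition geometry). Assignment is per tomogram,
matching the sampling design of the study; distances between the bands
are honestly "unassigned". Overlapping bands for one landmark are an
error.

Per-region summaries report n, mature fraction, diameter mean/SD and
median with 25–75 % quantiles (linear-interpolation convention,
`quantile type 7` — stated because "median" admits several), count
density (n per µm³ of summed tomogram volume; the product
density × volume is exactly n), and volume fraction (summed
`in_volume_nm3` over summed tomogram volume, 1 µm³ = 10⁹ nm³; the
denominator is the full reconstructed volume, as the published
figure's label dictates, not a cytoplasm-cropped one). A volume
fraction above 1 is impossible for non-overlapping vesicles and raises
a consistency error. Whether medians or means fed the published
significance tests is unstated, so both are computed.

`compare_regions()` runs Welch's two-sample t test and the
Mann–Whitney U test (normal approximation with continuity and tie
correction), two-sided, flagged at p &lt; 10⁻⁴ — the starred level of
the study. Welch rather than pooled variance is the default because
the group sizes (25 vs 130) and spreads (42 vs 52 nm) differ; pooled
is available by flag. At those published group sizes and calibrations
the diameter difference is detected at p &lt; 10⁻⁴ in ≥ 99 of 100
seeded repetitions by both tests.

## Reproducibility and problem sizes

Every random stage is seeded; one global seed spawns per-(region,
tomogram) substreams, so changing one region's tomogram count leaves
the others' draws untouched. `run_pipeline()` serializes every
effective parameter to `manifest.json` before executing, logs each
stage, keeps partial outputs next to a `FAILED` marker on error, and
its summary stage (`summarize_run()`) reproduces identical outputs
when re-run from the saved `vesicles.csv` + `tomograms.csv`.

The shipped presets describe tomograms of 1024 × 1024 × 220 nm at 2 nm
voxels (0.23 µm³, close to real reconstructions). The validation suite
and the acceptance script run the same presets on 640 × 640 × 220 nm
grids (0.09 µm³ per tomogram) — the package's chosen balance between
statistical resolution and turnaround — keeping the 5/10/10 per-region
tomogram design. At that scale region 1 holds only a handful of
vesicles per run, which is faithful to the study's own interior
sampling (n = 25 from five tomograms).

## Known limitations

* The estimator assumes spherical vesicles; ellipticity biases d and V.
* Sub-130 nm vesicles sit outside the maturity classifier's documented
  operating envelope at the default matched-filter scale.
* The detector's absolute threshold presumes the synthetic intensity
  convention; real tomograms need the quantile mode and fresh
  calibration.
* Region-2 preset values are interpolated, not published.
* Peripheral-region packing saturates below the published density
  (random sequential addition vs. near-close-packed reality), so
  absolute densities and volume fractions at the R3 calibration are
  reproduced up to that jamming limit.
* One landmark distance per tomogram; the per-vesicle landmark-plane
  mode is not the default and is untested against real geometry.
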