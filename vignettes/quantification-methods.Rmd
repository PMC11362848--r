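---
title: "Quantifying immunohistochemistry in tumor-adjacent cortex: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immunohistochemistry in tumor-adjacent cortex: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcquant)
```

## The problem

Glioblastoma surgery often removes a rim of tumor-adjacent cortex, and in
older patients that cortex can carry Alzheimer's disease neuropathological
change (ADNC): amyloid-beta (Abeta) plaques, hyperphosphorylated-tau (pTau)
neurofibrillary tangles, and the accompanying microglial response. Mapping
how these deposits co-vary with tumor cell infiltration requires (i) turning
brightfield immunohistochemistry (IHC) whole-slide scans into per-mm^2
object density maps, (ii) aligning serial sections stained for different
markers onto a common grid, (iii) restricting the analysis to cortex drawn
by a neuropathologist, and (iv) a small battery of ordinal scores and
rank-based statistics. `ihcquant` implements that chain, together with a
synthetic slide generator so every stage can be validated against known
ground truth.

## Image model and coordinate conventions

Images are `h x w x 3` arrays of RGB values in [0, 255]. Pixel centers sit
at 0-based integer coordinates, origin at the top-left pixel center, `x`
rightward (columns), `y` downward (rows). All centroids, polygons and
transforms live in this frame; polygon membership uses the even-odd rule
evaluated at pixel centers. Stating the convention is not pedantry — the
rectangle-counting and closed-form transform tests only make sense once it
is fixed.

## Stain color model

Brightfield IHC has two relevant chromogens: the blue-purple hematoxylin
counterstain marking every nucleus, and the brown diaminobenzidine (DAB)
immunostain marking the antigen of interest. Staining intensity varies
strongly between slides, so the classifier is anchored per slide:

1. **Reference vectors.** The operator marks ~10 immunostained and ~10
   hematoxylin-stained pixels; `estimate_stain_vectors()` stores their mean
   RGB vectors. On synthetic slides `pick_reference_pixels()` plays the
   operator by sampling blob-core pixels from ground truth.
2. **Tissue mask.** A pixel is tissue iff its blue value lies below the
   image-wide blue mean (`tissue_mask()`): tissue absorbs, bare glass is
   bright. One erosion plus one dilation with a disk of radius
   `tissue_morph_radius_px` (default 3 px; the radius is an artifact choice,
   only the operation pair is prescribed by the method) removes speckle. A
   constant blue channel makes the threshold meaningless and is an error.
3. **Angle classification.** For each tissue pixel, `classify_pixels()`
   computes the angle between its RGB vector and each reference vector from
   the normalized dot product. A pixel is hematoxylin if its hematoxylin
   angle is within `angle_threshold_hema_deg` *and* no larger than the
   immunostain angle; symmetrically for the immunostain; otherwise
   unstained. Exact angle ties go to hematoxylin — a deterministic rule for
   a measure-zero event. Angles ignore vector length, so the labeling is
   invariant to uniform intensity scaling (tested). The two angle
   thresholds default to 15 degrees each; they are empirical knobs of this
   package, exposed in `classifier_params()`, not published constants.
4. **Projection segmentation.** `segment_nuclei()` restricts attention to
   pixels labeled hematoxylin, projects pixel *absorbance* (white point 255
   minus RGB) onto the stain's absorbance direction, min-max-normalizes the
   score over tissue pixels, and keeps scores above
   `hema_projection_threshold` (0.30). The binary result is eroded with a
   disk of radius 1 px and 8-connected components become one centroid each.
   `segment_particles()` is identical with the immunostain direction and a
   0.40 threshold. The projection is computed in absorbance space because a
   raw-RGB projection scores the bright background *above* dark stained
   pixels, which cannot be thresholded from above; absorbance makes "more
   stain" mean "higher score", which is what the 30%/40% cut-offs need.

Touching objects merged into one component yield one centroid; no watershed
splitting is attempted. That bias is visible in the tests: a slide with a
30% pairwise-overlap cap loses a few percent of nuclei to merging, which is
why the recovery tolerance is +-5%.

## Density maps

Centroids are binned to their nearest pixel (`centroid_count_map()`), and
the count map is convolved with a binary disk kernel — the rasterization is
a center-in-circle test — of radius `kernel_radius_px` (200 px in the
reference configuration). Dividing by the kernel's physical area (disk
pixel count x pixel area) yields objects per mm^2: a single isolated object
reads as exactly 1 / kernel-area across its plateau (with a 0.42 mm^2
kernel, 2.38 per mm^2). The divisor is a design choice of this package: the
upstream description reports per-mm^2 densities without stating the
normalization, and kernel area is the only divisor under which an isolated
object has that natural reading.

**Edge handling.** Zero padding alone under-counts objects near the frame
edge (part of their disk falls outside). We renormalize *per source*: each
centroid's kernel mass is divided by the in-frame pixel count of the disk
centered at that centroid. This keeps the map's integral exactly equal to
the centroid count — conservation holds to FFT round-off (~1e-12 relative)
and is asserted at 1e-6 in the interior regime — while per-*pixel*
renormalization (dividing each output pixel by its in-frame kernel
fraction) was measured to break conservation at the few-1e-3 level and was
therefore rejected.

Maps and masks are brought to analysis resolution by block-mean
downsampling (`downsample_map()`, factor 0.0125 in the reference chain;
partial edge blocks average what they contain), which preserves the
map-wide mean. Masks use the same grid with a 50% majority threshold. The
reference scale chain (0.5 x 0.5 primary, 0.0125 x 0.0125 map level, 73 um
map pixels, 5329 um^2 pixel area, 0.42 mm^2 kernel) is recorded in
`pipeline_scales()`; the printed reference values are not mutually
consistent as a single chain (a 200 px kernel covering 0.42 mm^2 implies
~1.83 um/px, under which a 0.0125 map factor gives ~147 um pixels, not 73
um), so micrometres-per-pixel is explicit configuration here and each
derived quantity is computed from the values actually supplied.

## Serial-section registration

Serial 2-um sections share tissue outline but are mounted with small
rotations and shifts. `rigid_register()` aligns the tissue-on-background
masks: it minimizes the mean squared difference between the transformed
moving mask and the fixed mask, with bilinear resampling so the objective
is smooth in the transform parameters. Initialization combines the
centroid offset with the principal-axis angle difference; eight rotation
starts spread around the circle guard against the 180-degree ambiguity of
principal axes. Optimization is Nelder-Mead on a resolution pyramid
(coarsest level capped at 128 px explores all starts; each finer level
refines the best solution). The identity candidate is always scored, so
the achieved Dice overlap never falls below the unregistered overlap.
Masks with under 0.1% foreground are refused ("insufficient backbone").

Transforms are rotation-about-center plus translation, with exact
`compose`/`invert` operations (tested to 1e-6 as a group). Density maps are
resampled bilinearly, masks by nearest neighbour; out-of-frame samples are
zero and flagged in a validity mask. Registration runs at the map level:
the level is configurable, and map-level grids (~10^2 px) are where the
mean-squares surface is cheap enough for multi-start optimization while
still recovering transforms to ~0.05 px in the recovery study.

## Cortex-restricted density vectors

Annotation polygons (GeoJSON canonically; a minimal reader for
scanner-style XML point lists is included) are rasterized with the
pixel-center even-odd rule. `extract_cortex_vectors()` emits one row per
map pixel with tissue = 1 and cortex = 1, one density column per marker in
a fixed order (tumor cells from the hematoxylin channel of the NeuN slide,
NeuN, Abeta, pTau, Iba1). Markers without a slide are absent columns, never
zeros — a zero would be a false density measurement.

## Semiquantitative scoring

The ordinal scales mirror standard neuropathology practice: CERAD neuritic
plaque scores (0/A/B/C at 0, 1-3, 5-10, >20 per high-power field; gap
counts take the nearest boundary class, 4 to A and 11-20 to B, preserving
ordinality without inventing categories), Braak & Braak stages grouped as
0 / I-II / III-IV / V-VI, ADNC categories (AT, T, A, vascular-only, none),
vessel and capillary cerebral amyloid angiopathy flags, tumor infiltration
grades (high above 70% nonneuronal cells; "approximately 1:1" medium is
operationalized as a nonneuronal fraction in [0.45, 0.70]), APP expression
(absent <1%, sparse 1-5%, moderate 10-30%, abundant >50%, gaps to the
nearest boundary) and axonal-spheroid scores (absent / 1-10 / 10-30 / >30
per high-power field). Combined ADNC severity is the rank sum of the Braak
group and CERAD ranks (0-6): the two staging systems are "combined" without
a published rule, and rank addition is the simplest monotone combination
with an interpretable zero. Prevalence tables round half-up to integer
percentages, matching how such cohorts are printed (22/205 prints as 11%);
raw fractions are retained. Cohen's kappa uses the standard
marginal-product chance correction; the all-constant degenerate cases are
defined (agreeing: 1 with a warning; disagreeing: NA, flagged) rather than
silently propagated.

## Statistics

`normality_gate()` applies Shapiro-Wilk at alpha = 0.05 and routes normal
pairs to Pearson and anything else to Kendall tau-b — pixel-level density
vectors are strongly skewed, so tau is the workhorse. Samples beyond the
test's 5000-observation limit are thinned to 5000 evenly spaced order
statistics (order-invariant, deterministic). Kendall tau-b uses the full
tie correction; S is computed in O(n log n) by merge-sort inversion
counting so 10^4-pixel tables are cheap. P-values use the exact permutation
null up to n = 8 (n! enumeration; the factorial wall is just above that)
and the tie-adjusted normal approximation beyond; the implementation is
cross-checked against an O(n^2) pair-count oracle and against
`stats::cor.test`. Fisher's exact test delegates to `stats::fisher.test`,
with an independent hypergeometric-enumeration oracle kept in the package
for verification. Group comparisons are one-way ANOVA followed by pairwise
t-tests with Bonferroni adjustment. Alpha defaults to 0.05 everywhere and
is exposed in the run config.

## The synthetic slide generator

`generate_slide()` renders what the classifier actually relies on — and
nothing more: a bright glass background (default RGB (245, 243, 240)), a
faintly absorbing tissue region bounded by a polygon (default
(228, 216, 206); its lower blue value is what makes the blue-mean tissue
threshold meaningful), anti-aliased disks with Gaussian-softened edges for
nuclei (hematoxylin-like (70, 60, 130), radii 4-7 px) and immunostained
particles (DAB-like (130, 80, 40), radii 5-10 px), per-blob Gaussian color
jitter (sd 6 RGB units) for staining variability, and mild per-pixel tissue
noise. Disks are the simplest shape whose centroid is analytically known,
which is what makes the +-2 px centroid-recovery assertion meaningful.
Placement is rejection sampling, uniform (optionally with a linear
placement gradient along x, used to construct density couplings with a
known sign) under a 30% pairwise-overlap cap and 10^4 attempts per blob;
saturation is an explicit error naming the achieved count. One RNG stream
per slide, seeded explicitly: identical specs give bit-identical images.

`generate_serial_section()` re-renders the reference scene under a small
rigid transform (limits: 20 degrees, 10% of the frame; more tissue than
10% pushed off-frame is an error), optionally with fresh particles for a
different marker, and records the transform in the ground truth.
`generate_cohort()` draws patient records i.i.d. from configurable ADNC
category prevalences — defaults are the observed cohort fractions 41/205
(AT), 37/205 (T), 22/205 (A), 7/205 (vascular-only) — with age ~ N(66, 12)
clamped to 27-92 years and conditional ordinal scores consistent with each
category.

What the generator deliberately does **not** emulate: nuclear shape
variation and chromatin texture, JPEG compression artifacts, stain
gradients within a slide, out-of-focus regions, tissue folds and
deformable (non-rigid) section distortion. Passing the synthetic suites
therefore validates the geometry, color algebra, bookkeeping and
statistics of the pipeline — not segmentation robustness on real tissue,
where touching-cell splitting and texture would dominate the error budget.

## Problem sizes and numerical tolerances

The validation suites run at deliberately modest sizes chosen to exercise
every code path: a 2048^2 slide with 500 nuclei and 120 particles for
segmentation recovery (counts within +-5%, mean centroid error <= 2 px);
20 random rigid perturbations (rotation within 10 degrees, shifts within
20 px) of a 256^2 tissue mask for registration recovery (median error
bounds 0.5 degrees and 1 px; observed errors are two orders of magnitude
smaller); mass conservation at 1e-6 relative (interior regime) and 1e-3
(renormalized edges); the tau-b oracle swept exhaustively over all vector
pairs of length <= 4 over {1,2,3} plus large seeded sweeps at lengths 5-6;
500 null simulations at n = 100 for the type-I error of the tau test; and
a two-marker end-to-end run (NeuN reference plus an Abeta serial section
at 1400^2, opposite placement gradients) whose cortex table exceeds 10^4
pixels and must detect the constructed negative Abeta-vs-tumor-density
coupling in sign and significance, not magnitude.

## Known limitations

- No watershed splitting: merged nuclei count as one object, biasing dense
  regions downward; the acceptance tolerances absorb this at synthetic
  densities, real tissue would need splitting.
- The angle thresholds (15 degrees) and the morphology radius are
  empirical defaults, not published values; per-batch tuning is expected.
- Rigid registration only: real serial sections also deform; residual
  misalignment blurs pixel-level correlations.
- The Shapiro-Wilk gate at n in the thousands declares tiny departures
  from normality significant, so pixel tables essentially always route to
  tau — consistent with the intended use, but worth knowing.
- Printed reference scales are accepted as configuration, not reconciled
  (see the scale-chain note above).
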