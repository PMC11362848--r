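# ihcquant

Quantification of immunohistochemistry (IHC) whole-slide scans of
glioblastoma-adjacent cortex, where Alzheimer's disease neuropathological
change (ADNC) — amyloid-beta (Abeta) plaques and hyperphosphorylated-tau
(pTau) tangles — can co-occur with tumor cell infiltration. The package
turns brightfield scans into per-mm² object density maps, coregisters
serial sections stained for different markers, restricts the analysis to
annotated cortex, and supplies the semiquantitative scoring scales and
rank statistics used on such cohorts. A synthetic slide/cohort generator
with exported ground truth makes every stage testable end to end.

## Method at a glance

For each slide with per-slide stain reference vectors
$\bar{c}_{hema}, \bar{c}_{immuno} \in \mathbb{R}^3$ (mean RGB over ~10
operator-marked pixels per stain):

- **Tissue mask** — pixel is tissue iff $b < \overline{b}$ (blue channel
  below its image-wide mean), then one erosion + dilation (disk, r = 3 px).
- **Classification** — per tissue pixel, the angle
  $\theta_s = \arccos\!\big(\tfrac{p \cdot \bar{c}_s}{\lVert p\rVert\,\lVert\bar{c}_s\rVert}\big)$
  to each stain; the smaller angle wins if within its threshold (15°),
  else the pixel is unstained.
- **Segmentation** — absorbance projection onto the stain direction,
  min–max normalized over tissue, thresholded at 30% (hematoxylin nuclei)
  or 40% (immunostained particles), eroded (disk, r = 1 px); 8-connected
  components → one centroid each.
- **Density maps** — centroid counts convolved with a binary disk kernel
  (r = 200 px in the reference configuration) and divided by the kernel
  area in mm²; an isolated object reads 1/kernel-area (≈ 2.38 per mm² for
  a 0.42 mm² kernel). Block-mean downsampling to the map grid
  (73 µm pixels, 5329 µm² each, in the reference chain).
- **Registration** — serial sections aligned to the NeuN slide by rigid
  registration (mean squares on tissue background masks, multi-start
  Nelder–Mead on a resolution pyramid).
- **Cortex table** — one row per map pixel with tissue = 1 and cortex = 1,
  holding tumor cell, NeuN, Abeta, pTau and Iba1 densities per mm².
- **Statistics** — Shapiro–Wilk gate (α = 0.05) routing to Pearson or
  tie-corrected Kendall τ-b; Fisher's exact test for 2×2 tables; ANOVA +
  Bonferroni pairwise t-tests; Cohen's κ for inter-rater agreement;
  CERAD / Braak-group / APP / axonal-injury ordinal scales and half-up
  percentage summaries for cohort tables.

See `vignettes/quantification-methods.Rmd` for assumptions, parameter
defaults and the design decisions behind each stage.

## Worked example

```r
library(ihcquant)

spec <- slide_spec(2048, 2048, nucleus_count = 500, particle_count = 120,
                   seed = 2024)
s    <- generate_slide(spec)                     # synthetic slide + truth
refs <- pick_reference_pixels(s, n = 10, seed = 1)
ref  <- estimate_stain_vectors(s$image, refs$immuno_px, refs$hema_px)
tis  <- tissue_mask(s$image)
lab  <- classify_pixels(s$image, ref, tissue = tis)
nuc  <- segment_nuclei(s$image, ref, tissue = tis, labels = lab)
prt  <- segment_particles(s$image, ref, tissue = tis, labels = lab)
nrow(nuc); nrow(prt)
#> [1] 491
#> [1] 119
```

491 of 500 nuclei and 119 of 120 particles are recovered (a handful of
touching nuclei merge into one component; mean centroid error 0.16 px).
The analysis drivers under `analysis/` run the full story in order:

```sh
Rscript analysis/01_simulate_slides.R    # slides + ground truth
Rscript analysis/02_segment_quantify.R   # segmentation recovery, density map
Rscript analysis/03_register_extract.R   # registration study, cortex table
Rscript analysis/04_cohort_stats.R       # prevalence, kappa, group tests
```

`03_register_extract.R` registers 20 random rigid perturbations back to a
reference mask (median error 0.017°, 0.05 px in the run shown in
`results/registration_recovery.csv`) and then runs the two-marker pipeline:
its cortex table (13,191 pixels) shows the constructed negative coupling
between Abeta load and tumor cell density (τ = −0.41, p < 2e-16).
`04_cohort_stats.R` reproduces the printed cohort percentages from the
published counts — 52% ADNC overall, 20% combined Abeta+pTau, 18% pTau
only, 11% Abeta only, 3% vascular-only.

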