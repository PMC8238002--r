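---
title: "Ear photometry and trial statistics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ear photometry and trial statistics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earpheno)
```

This vignette is the package's own account of the science it implements:
the image-analysis pipeline that turns photographs of dried maize ears
into 25 yield-component traits, the mixed-model statistics used to analyse
those traits across a replicated two-year testcross trial, and the
synthetic generators that stand in for field data. It states what each
stage assumes, which parameters matter and why their defaults were chosen,
and what the passing test suite does and does not demonstrate about real
imagery.

## 1. The imaging pipeline

### Pixel classification

Ears are photographed once, from above, against a uniform background.
Three pixel classes suffice to describe such a scene: background, exposed
cob, and kernel crowns. `fit_pixel_classifier()` trains a
nearest-centroid classifier from a small labelled template table
(`R,G,B,class` rows): exemplars are converted from sRGB to CIELAB and each
class is summarised by its centroid. CIELAB was chosen because Euclidean
distance there approximates perceptual colour difference, which separates
yellow crowns from red-brown cob far more reliably than raw RGB distance
under the colour jitter present in real photographs. Distance ties are
broken by the fixed order background < cob < kernel, so classification is
fully deterministic. `classify_pixels()` applies the classifier per pixel
and then smooths the integer label image with a median filter (radius
1 px by default, configurable) to remove isolated misclassified pixels —
the light spatial filtering any practical platform applies. The
supervision is entirely front-loaded into the template file; the pipeline
itself runs unattended.

### Calibration

All physical units come from one scale factor, pixels per centimetre,
measured from a separate photograph of a high-contrast bar of known
length (`calibrate_scale()`). The bar is located by Otsu thresholding of
the grey image, keeping the minority phase and its largest connected
component; its longest bounding-box extent divided by the known length
gives px/cm. A region with aspect ratio under 3 is rejected as not
bar-like rather than silently accepted.

### Ear extraction and alignment

Foreground (cob or kernel) pixels are closed with a disc of radius 3 px —
enough to bridge the 1-2 px crevices between touching structures without
merging neighbouring ears — and split into connected components. Components
smaller than 10 cm$^2$ (configurable) are discarded as debris; real ears
are an order of magnitude larger. Components are ordered left to right by
centroid so ear indices match the physical layout. Each ear is rotated so
the principal axis of its pixel coordinates is vertical (nearest-neighbour
resampling, which preserves the label partition exactly), and flipped if
needed so the tip points up. The tip is identified as the axial end whose
mean width over the outer 10% of the span is smaller, which is robust
because ears taper toward the tip. Pixels absorbed by the closing that
were not classified as kernel are assigned to the cob mask, so kernel and
cob masks always partition the ear mask — an invariant the tests check on
every extraction.

### Kernel delineation

Within the kernel mask of an aligned ear, `detect_kernels()` runs a
marker-controlled watershed: the Euclidean distance transform is smoothed
with a Gaussian (sigma 1 px at the 20 px/cm reference resolution, rescaled
with the actual calibration) and its regional maxima become markers;
maxima closer together than 0.6 x the expected kernel width (0.46 cm by
default) merge into one marker, which is the single knob controlling
over-segmentation of touching crowns. Seeded region growing constrained to
the kernel mask assigns every kernel pixel to a marker. Regions outside
0.05-1.5 cm$^2$ are discarded; the bounds are expressed in cm$^2$ so the
behaviour is resolution-independent. Per-crown geometry is measured from
the region pixels: area, moment-based major/minor axes, max/min Feret
diameters from the convex hull (the centre-to-centre hull span plus one
pixel, which compensates the half-pixel inset of pixel centres on each
side), and perimeter as the convex-hull polygon length plus $\pi$ — the
exact increment produced by offsetting a convex polygon outward by half a
pixel. On digitised ellipses these estimators are accurate to 1-3% at
20 px/cm; worst-case digitisation (a circle whose radius is an exact pixel
multiple) biases the Feret maximum by one pixel, which is why the tests
use off-grid radii.

### Trait computation

The 25 traits split into four families.

*Silhouette traits* come from the axial width profile (occupied column
span per pixel row, in cm): length `EARLGT`, maximum width `EARWTH`,
central width `EARCW` (mean over the central 10% of length), area, mask
perimeter, boxiness `EARBOX` = area / (length x width), and volume
`EARVOL` as a solid of revolution $\sum_i \pi (w_i/2)^2 \Delta x$. The
tip-shape ratios `EARTR` and `ETB` compare the mask area of the distal 20%
of length with the tip's bounding rectangle and with the rectangle built
on the width at the tip-region base, respectively. Volume is reported in
cm$^3$; treating the printed unit of ear volume in the field's trait
tables as a typographical slip is deliberate, since revolution volumes of
real ears (~370 cm$^3$) match the reported magnitudes.

*Fill traits* partition the ear area. `KERFIL` is the kernel-class share;
the tip-abortion length behind `TKERAB` is the contiguous run of rows from
the tip with no kernel pixels at all (interior gaps do not count as
abortion); `SCTTER` is the cob share outside that abortion zone, computed
as the complement `100 - KERFIL - abortion share` so that the three-way
partition identity holds algebraically (floating-point sums can still
round by one ulp, which is the tolerance the tests use).

*Kernel geometry traits* are means over detected crowns (`KERARE`,
`KERLEN`, `KERWTH`, `KERMAXD`, `KERMIND`, `KERMEAND`, `KERPER`), plus the
central count `KERCC`, the number of crowns whose centroid falls in the
middle 50% of ear length. Zero-kernel ears report missing geometry and
`KERCC = 0` rather than zeros.

*Count and yield traits* extrapolate from the single camera view, which
sees roughly half the kernel circumference. Visible rows are counted as
distinct transverse crown tracks crossing a central transect; the band
around mid-length is half a kernel width, widened to at least 0.6 x the
axial pitch so it cannot fall between kernel rows (a track is counted once
however many of its kernels enter the band). `PHTKR` doubles the visible
rows (`visible_to_total_factor = 2`). Kernels per row `PHTKPR` divide the
non-aborted length by the axial pitch, estimated as the median axial
centroid gap within tracks — the median is robust to the doubled gaps that
scatter sites create, and the centroid pitch (unlike the crown's own
axial extent) is an unbiased estimate of kernels per unit length for
non-touching crowns. When no track has two kernels the mean axial crown
extent is the fallback. `PHTKPE = PHTKR x PHTKPR x (1 - SCTTER/100)`
discounts scattered positions; `KERWGT = 0.8 g/cm^2 x KERARE` converts
crown area to weight (giving ~0.25 g for a typical 0.31 cm$^2$ crown);
and `PHTYLD = KERWGT x PHTKPE` holds exactly by construction. All
constants live in `trait_model_params()` and are calibratable; they are
transparent parametric stand-ins for a commercial platform's unpublished
prediction models, and their defaults were fixed once from typical dent
maize magnitudes.

Plot aggregation takes per-trait means over a plot's ears, excluding
missing values rather than zero-filling them, and records the
within-plot sample variance of `PHTYLD` (n-1 denominator; missing for
single-ear plots).

## 2. Trial statistics

### Thermal time

`daily_gdd()` caps the daily maximum and minimum temperatures into
[10, 30] degC independently and returns `(Tmax + Tmin)/2 - 10`, so daily
values are bounded in [0, 20]. Accumulation (`accumulate_gdd()`) sums
daily values from planting to the event date inclusive of both endpoints —
the endpoint convention is not standardised in the field, so it is
documented and fixed here; a one-day difference is ~1% of a typical
accumulation to anthesis. Gaps in the weather series are an error listing
the missing dates, never silently skipped. The anthesis-silking interval
is reported both in days and as the difference of the two accumulations.

### The mixed model and heritability

Each trait is analysed with the standard two-year testcross model
$Y_{ijk} = \mu + H_i + Yr_j + HYr_{ij} + R(Yr)_{jk} + \varepsilon_{ijk}$,
hybrid and hybrid-by-year random, year and rep-within-year fixed, fitted
by REML with `lme4::lmer`. BLUPs are predicted jointly across years
rather than per year, matching the practice of summarising a hybrid by one
value when the hybrid variance dominates the interaction. lme4 constrains
variance estimates to be non-negative, and singular fits (a component
estimated at zero) are legitimate outcomes rather than failures;
optimizer non-convergence is flagged on the returned object and never
silently replaced. With a single year the interaction is structurally
confounded with the hybrid effect and is fixed at zero. The grand mean is
computed as the average fixed-effect prediction over the observed design,
which equals the intercept under sum-to-zero contrasts in balanced data
and degrades gracefully otherwise.

Broad-sense heritability is computed on the entry-mean basis,
$H^2 = \sigma^2_H / (\sigma^2_H + \sigma^2_{HY}/y + \sigma^2_\varepsilon/(yr))$,
and the plot-mean basis, which omits the division by years and reps. The
entry-mean value can never be smaller than the plot-mean value for
$y, r \ge 1$, a property the tests assert over random components. In
balanced designs the REML estimates coincide with the closed-form
expected-mean-squares estimators, which the test suite uses as an
independent oracle. One calibration fact worth stating: the correlation
between BLUPs and true hybrid effects cannot exceed $\sqrt{H^2_{entry}}$,
about 0.85 at the simulated component values (2, 1, 1) with two years and
two reps — the simulation tests check agreement with this ceiling, not an
arbitrary threshold above it.

### Validation, group comparison and multivariate structure

`validate_prediction()` reports the Pearson correlation and least-squares
line between an image-predicted trait and its manual reference; when a
covariate such as stand count is supplied the model
`reference ~ predicted + covariate` is fitted and the correlation between
the reference and its fitted values is reported, removing yield variation
attributable to stand differences. Zero variance on either side flags the
correlation as undefined.

`compare_groups()` runs a one-way ANOVA of hybrid BLUPs across heterotic
groups and, when significant at $\alpha = 0.05$, a Tukey HSD with a
compact letter display. Letters are relabelled so that scanning groups in
descending mean order assigns "a" first, preserving the sharing
structure; groups sharing a letter are not significantly different.
Significance codes are ns / * / ** / *** at 0.05 / 0.01 / 0.001. The null
calibration (type-I error at the nominal level over 1,000 simulated null
trials, binomial tolerance) and the power at 10-sigma separation are part
of the acceptance suite.

`trait_pca()` standardises every trait to unit variance (after per-trait
mean imputation of missing values, reported; constant traits dropped with
a warning) and decomposes with `prcomp`, so percent variances sum to 100.
`cluster_traits()` clusters the *traits* (observations = traits, features
= standardised per-hybrid values, here BLUPs: multivariate analysis
follows BLUP prediction in the pipeline order) with Euclidean distance
and Ward's minimum-variance linkage in the `ward.D2` convention. The
Ball-Hall index
$BH(k) = \frac{1}{k}\sum_c \overline{\lVert x_i - \bar x_c\rVert^2}$
is evaluated on the nested partitions for $k = 1..k_{max}$ (default 10,
clamped to the trait count).

The number of clusters is chosen at the *elbow* of the index curve — the
$k \ge 2$ maximising the second difference $BH(k-1) - 2BH(k) + BH(k+1)$ —
with a zero-drop guard returning $k = 1$ for degenerate input such as
identical traits. The obvious alternative, taking the largest successive
drop $BH(k-1) - BH(k)$, was considered and rejected on analytical grounds:
for $g$ equally separated, equally sized groups the drop from $k=1$ to
$k=2$ is always the largest (for three orthogonal group directions the
index falls as $\tfrac{2}{3}c^2, \tfrac{1}{4}c^2, \approx 0$, so the
first drop dominates), which would select $k = 2$ regardless of the true
group count. The second difference instead peaks where a large drop is
followed by a small one, which is exactly the true $k$; on the synthetic
three-group construction it selects $k = 3$ in 100 of 100 seeded runs.

`within_plot_variance_test()` compares mean within-plot yield variance
between plot origins (temperate vs tropical testcrosses) with a two-sided
Welch test, each year analysed separately because the number of ears
sampled per plot differs between years; a year observed for a single
origin is skipped with a warning.

## 3. The synthetic generators

### Ear scenes

`ear_spec()` + `render_ear()` rasterise a stylised ear whose geometry has
closed forms, so ground truth carries no simulation error. The silhouette
is a half superellipse: half-width
$h(s) = \tfrac{W}{2}(1 - u^n)^{1/n}$ with $u = 1 - s/L$, which gives
area $= WL \cdot B(\tfrac1n, \tfrac1n + 1)/n$ and the analogous Beta-form
for the revolution volume (both verified against numeric quadrature in
the tests). The default taper exponent 8 portrays the near-cylindrical
shape of a dried dent ear; exponent 2 gives the semi-elliptical profile
used by the width-profile oracle test. Kernel crowns are ellipses on a
rows x kernels-per-row grid over the non-aborted span, first and last
crowns tangent to the abortion boundary and the butt so the measured
abortion length equals the specified fraction exactly. A seeded fraction
of sites is removed as scatter; the distal `abortion_frac` of length is
bare cob; seeded Gaussian colour jitter (sd 5/255, below the class
separation margin by construction) exercises the classifier. Layout
validity — crowns strictly inside the silhouette and pairwise non-touching
— is checked and violations raise an informative spec error rather than
rendering a scene whose ground truth would be wrong.

Two stylisations matter for interpreting test results. First, crown
ellipses are oriented with the 0.87 cm axis along the ear and the 0.46 cm
axis transverse; with eight visible row tracks on a ~5.2 cm-wide flat
projection, transverse spacing (~0.55 cm) cannot accommodate 0.87 cm-wide
non-touching crowns, and the non-touching property is what makes
watershed counts exactly checkable. Second, because crowns must not
touch, they cover only ~50% of the ear area, so default renders have
`KERFIL` near 50% and correspondingly large `SCTTER`, unlike real ears
where crowns tile ~90% of the surface. Passing recovery tests therefore
demonstrate correct geometry, counting and trait arithmetic on separable
crowns and calibrated scenes; they do not demonstrate segmentation of
densely packed, shadowed or husk-contaminated imagery, which would need
real templates and tuned smoothing.

Scenes (`render_scene()`) lay ears left to right with 1 cm margins, tips
up, and draw a mid-grey ruler bar of exactly `round(length x px/cm)`
pixels in a reserved bottom strip; the bar's grey is closer to the
background class than to cob in CIELAB, so it never extracts as a
spurious ear. The default resolution is 20 px/cm, about that of a
consumer DSLR imaging a 60 cm field of view.

### Trials

`simulate_trial()` draws balanced plot-level observations from the
generative form of the mixed model with Normal hybrid, interaction and
residual effects and fixed year and rep-within-year offsets. Defaults —
200 hybrids, two years, two reps, $\mu = 150$ g/ear and components
(2, 1, 1) — give an entry-mean heritability of $2/2.75 \approx 0.73$,
inside the range reported for ear traits in multi-year testcross trials.
The generator returns the drawn effects so recovery is checkable.

## 4. Numerical choices and problem sizes

- All randomness is seed-controlled; renders and simulations are
  byte-identical under a repeated seed, and the pipeline contains no
  stochastic step, so fixed config + seed reproduces output files exactly.
- Widths are measured in whole pixels, so a single row's relative width
  error is bounded by one pixel (0.05 cm at 20 px/cm); profile
  comparisons are made where that bound is below the stated tolerance.
- Degenerate inputs are contracts, not crashes: masks under 2 px of
  axial extent yield missing silhouette traits, empty kernel masks yield
  empty kernel tables, empty ear lists raise errors, single-ear plots
  have missing variance.
- The acceptance suite sizes were chosen to keep Monte-Carlo error well
  below the tolerances while completing in minutes on one CPU: 500
  simulated trials of 200 hybrids for variance-component recovery in the
  tests (200 in the standalone script), 50 scenes x 5 ears for imaging
  recovery (20 x 5 in the script), 100 seeded runs for cluster-number
  selection, 1,000 null trials for ANOVA calibration.

## 5. Known limitations

- The trait prediction constants (`weight_per_area`, the visible-to-total
  row factor) are fixed stand-ins; on real data they would be calibrated
  against shelled reference measurements per germplasm and year.
- `KERLEN` is defined here as the crown's major axis; if a platform
  instead predicts kernel depth (the dimension hidden from the camera),
  its values are not comparable.
- The watershed controls over-segmentation solely through marker
  separation; heavily fused crowns in real imagery may need shape-based
  splitting that is out of scope here.
- Single-view extrapolation assumes visible rows represent half the
  circumference; strongly asymmetric fill breaks that assumption.
- The renderer models neither lighting gradients, husk/silk debris, nor
  kernel colour segregation within an ear; classification accuracy on
  real images depends on template quality in ways the synthetic tests do
  not probe.
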