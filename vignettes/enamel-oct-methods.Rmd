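---
title: "Methods: OCT enamel analysis in enameloct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OCT enamel analysis in enameloct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enameloct)
```

`enameloct` quantifies tooth-enamel loss and abrasion from grayscale OCT
B-scans and volumes, the imaging problem that arises when orthodontic
brackets are bonded to and debonded from the enamel surface. This vignette
is the package's own account of the three image-analysis pipelines, the
group statistics, and the synthetic phantom that makes all of them testable
without clinical data.

## Image model and conventions

A B-scan is a non-negative intensity matrix with rows indexing depth
(shallowest first) and columns indexing the lateral position; an A-scan is
one column. All coordinates are 1-based and closed-interval (`roi(x0, x1,
z0, z1)` includes both endpoints), the native R convention; physical depth
below the top row is `(row - 1) * axial_pitch` µm.

Calibration: the default lateral pitch is 2.5 µm/px (a 5 mm scan split into
2000 A-scans) and volumes default to 10 µm between slices (500 B-scans over
5 mm). The axial pixel pitch of an OCT system is not derivable from its
quoted axial *resolution* (~16–25 µm in air for the class of swept-source
systems this package targets), so `axial_pitch` is always an explicit
argument; the phantom uses 5 µm/px. No refractive-index (optical-path)
correction is applied — thicknesses are in optical path length unless the
caller rescales.

## Depth-intensity profile analysis

For a rectangular ROI the analysis tiles lateral windows of
`window_size = 10` A-scans (a final partial window is kept when at least
half full) and for each window:

1. **Peak detection per A-scan.** Local maxima (plateaus report their first
   index) that reach `min_height` (default 0.2 of the A-scan maximum) and
   survive a `min_separation` of 5 px, taller peak winning. The *first
   peak* — the surface — is the shallowest local maximum that additionally
   clears a robust noise floor, `median + 3·MAD` of the A-scan. The noise
   floor presumes the usual OCT geometry in which most of the depth range
   is dark background; it is not meaningful for crops that are mostly
   tissue.
2. **Flattening.** Each A-scan is shifted up so its first peak sits at
   index 1; samples above the surface are discarded and the tail is
   zero-padded (no signal exists beyond the acquisition depth — padding is
   never circular). A-scans with no detected peak are excluded and counted;
   missing peaks are recorded, never interpolated.
3. **Averaging and normalization.** The used A-scans are averaged
   column-wise and divided by the maximum, so the profile peaks at exactly 1
   whenever any signal is present. Peaks are re-detected on the averaged
   curve with the same parameters.
4. **Thickness readout.** The surface is the index-1 peak. The
   dentinoenamel junction (DEJ) is the *highest-amplitude* remaining peak
   deeper than `min_separation`, where amplitude is measured **above the
   trailing baseline**: the mean profile over `peak + 5 .. peak + 30` px.
   The DEJ is the bright interface resting on much dimmer dentin, so its
   trailing contrast is large; residual speckle ripples riding on the
   bright, attenuating shallow enamel have raw heights that can exceed the
   attenuated DEJ bump but almost no trailing contrast. Raw-height
   selection mis-locates the DEJ by >100 px under realistic speckle;
   peak-prominence selection also fails (under a monotone decay the
   shallowest large ripple is maximally prominent); trailing contrast keeps
   both the noise-free and the worked-example behaviour while remaining
   robust. Thickness is `(dej_index - surface_index) * axial_pitch`.

Sub-pixel localization is deliberately out of scope; with the default
1.5-px axial point-spread blur the apex of an interface peak shifts by
1–2 px toward the brighter side, which is the dominant term in the ±2 px
median error observed on speckled phantoms. Typical premolar enamel is
1000–1500 µm thick; thicknesses outside that band set a QC flag
(`qc_in_band`), never an error, since treated or sectioned samples can be
legitimately thinner.

## Structural connectivity (enamel loss and abrasion)

The pipeline: rotationally symmetric Laplacian-of-Gaussian filtering (5×5,
σ = 0.5, sum-zero kernel, symmetric border padding) → global Otsu
binarization → 8-connected component tracing with components < 20 px
discarded → morphological opening (box, radius 1) → Sobel edge overlays
(cutoff 0.1 of the maximum gradient) → morphological closing with
total-enamel accounting → abrasion-site detection.

Two numerical choices deserve explanation:

* **Binarization scale.** Otsu's threshold is computed on the
  log-transformed histogram of the min-max-rescaled |LoG| response.
  Gradient magnitudes of speckled images are heavy-tailed; on the raw
  histogram the cut lands inside the tail and keeps only ~38% of the
  enamel texture — below the 8-connectivity percolation threshold, so the
  band shatters into sub-`min_component_px` fragments. On the log scale the
  cut falls between the background and texture modes (~84% of enamel
  retained, one giant component). The transform is monotone, so
  well-separated bimodal images binarize exactly as plain Otsu would.
* **Closing radius.** The default radius 2 is the smallest closing that
  bridges the inter-speckle gaps left at ~84% fill; with it the closed-mask
  area tracks the true enamel area within ±5% at speckle shape k = 16. For
  abrasion analyses a radius of about half the widest notch to be bridged
  is required (the worked analyses use 10 px).

**Total enamel** is the sum of source intensities (and the pixel count)
over the closed mask. On a noise-free, piecewise-constant image the LoG
response is zero inside uniform regions, so the binarized mask is an edge
set and its area is not a tissue area; the LoG-texture route measures
enamel area only in the speckled regime it was designed for. Noise-free
area accounting goes through the intensity classes of the layer
segmentation instead.

**Abrasion** is formalized as closing-induced growth of the tooth surface:
protrusion pixels are those gained by closing that lie *above* the local
detected surface (within `surface_band_px = 15`). At an abrasion the
surface line dips and the closing bridges the dip from neighbouring
columns; growth deeper than the surface is ordinary hole-filling and is
ignored. Per-column protrusion counts are smoothed with a 7-column running
median (single-column boundary raggedness is uncorrelated laterally,
whereas a real notch spans many columns) and a column protrudes when it
exceeds the image-wide median growth by `min_excess_px = 3`; runs of
protruding columns (gap tolerance 2) become sites ranked by area.
*Limitation:* at speckle k = 16 with the 1.5-px point spread, a 5-px
(25 µm) notch sits at the detection floor (~80–85% detection); the
stochastic detection studies therefore use a 10-px (50 µm) notch, the
scale of clinically reported post-debonding loss, where detection is
essentially certain. The noise-free exactness contract is kept at the
5-px scale.

## Intensity-based layer segmentation

Median filtering (5×5, symmetric padding) → multilevel Otsu thresholds →
class quantization and colorization → per-class structures → composite
overlay.

* **Multilevel Otsu** maximizes the between-class variance over the
  256-bin histogram by dynamic programming, so the optimum over all
  threshold placements is exact at bin resolution; class *i* holds
  intensities in `(t[i-1], t[i]]`. The default is 3 thresholds (4 classes:
  background, dentin, enamel, bright interfaces) with a navy/green/red/
  magenta palette, both configurable — the number of meaningful intensity
  classes in real scans is a display choice, not a physical constant.
* A **global Otsu foreground mask** on the median-filtered image is stored
  alongside the class map and used to flag background (lowest class outside
  the foreground). It re-binarizes nothing.
* **Per-class structures.** Edge detection (LoG, then Sobel at each class's
  own threshold, default 0.1) runs on the class-masked grayscale
  intensities, so the filters see real gradients rather than 0/255 steps.
  Connected components, opening, closing, and intensity accounting run on
  the extracted class channel itself, using the connectivity module's own
  functions — on a single-class image the two modules are identical by
  construction, which the tests assert literally. Outputs never mix
  classes.
* **Overlay.** Closed per-class structures are alpha-blended over the
  grayscale source, lowest class first, so overlaps show the higher class;
  the source stays visible where no class is drawn.

**En-face extraction** reads, for every (slice, column), the intensity at
`surface_row + round(depth_um / axial_pitch)`, with the surface detected
per column by the depth-profile module's first-peak rule. Measuring from
the detected surface (not a flat row) is what makes "500 µm below the
tooth surface" well defined on curved teeth. Columns with no surface are
zeroed and flagged; if more than half the positions fall outside the
acquisition the call errors.

## Enamel quantification and group statistics

The per-sample metric runs the connectivity accounting on an en-face image
and sums the source intensities over the closed connected mask ("total
pixel intensities in continuity"). The mapping from summed intensities to
µm is instrument- and normalization-specific; `calibration_scale` is an
explicit knob (µm per intensity unit) and defaults to 1 with a warning, so
uncalibrated metrics are clearly labelled. The published four-group
arithmetic is checked on the reported stage means themselves (765.70,
640.30, 567.80, 498.13 µm), whose pairwise differences reproduce the
reported losses of 125.40, 69.67 and 267.57 µm; the source narrative also
once states 115.40 µm for the first of these, which is inconsistent with
its own table arithmetic — this package implements the table-consistent
125.40.

Statistics over a complete subjects × stages matrix:

* **Repeated-measures ANOVA**, one-way within-subject: the subject effect
  is removed from the error term, `F = MS_treatment / MS_error`,
  `df = (k-1, (k-1)(n-1))`. No sphericity (Greenhouse–Geisser) correction
  is applied, matching the plain RM-ANOVA convention of standard SPSS-style
  reports; that is a documented limitation, not an oversight.
* **Bonferroni post-hoc**: paired t-tests on all 6 stage pairs with
  `p_adj = min(1, 6 p)`.
* **Kolmogorov–Smirnov normality**, Lilliefors-style: the reference normal
  uses the sample mean and SD, and `D = sup |ECDF − CDF|` is evaluated on
  both sides of every jump. The p-value uses the asymptotic Kolmogorov
  distribution, which is conservative when parameters are estimated; it is
  a screening value. SDs are sample SDs (n − 1) throughout.

## The synthetic phantom

The generator emulates the layered appearance of a premolar B-scan: a 1-px
specular surface line (relative reflectivity 2.0) blurred by a Gaussian
axial point spread (σ = 1.5 px, about one resolution element), an enamel
band (0.45) with lateral Hunter–Schreger-like sinusoidal banding (period
60 px, amplitude 0.15), a DEJ reflectivity band (1.2, 3 px thick — about
one axial resolution element), dimmer dentin (0.15), exponential depth
attenuation below the surface (µ = 0.003 /px), mean-1 multiplicative gamma
speckle (shape k = 16, i.e. 25% contrast, the regime of moderately
averaged OCT magnitude images) and an additive Gaussian noise floor
(σ = 0.01). Defect models: abrasion notches (surface deepens, enamel
removed), adhesive patches (bright band on the surface, multiplicative
shadowing of everything deeper), micro-crack lines (thin multiplicative
darkening), and an optional thin bright bonding-agent band for the
bonding stage. The reflectivity levels were fixed once so that every
noise-free contract holds by construction (surface carries the per-column
maximum after blurring; the attenuated DEJ stays above the 0.2
height fraction for 150–250 px enamel).

A treatment series applies per-stage thickness reductions (plus optional
stage defects and the bonding band) to per-subject baselines with seeded
jitter. For cohort-level statistics, `simulate_enamel_metrics()` draws
subject × stage metrics directly: baseline 765.70 µm, stage effects (0,
−125.40, −197.90, −267.57) µm, between-subject SD 80 µm and residual SD
110 µm — the pooled per-stage SD ≈ 136 µm, comparable to the reported
group SDs (107–168 µm). Simulating 100 cohorts of 12,000 rendered images
each would test the renderer, not the statistic, so the power study runs
at the metric level by design.

What the phantom does **not** capture: logarithmic display compression,
real Hunter–Schreger prism geometry (the banding here is a lateral
sinusoid), occlusal curvature beyond tilt/sine surfaces, refractive-index
steps, wet-sample artefacts, bracket metal, and spatially correlated
speckle. Tests passing on the phantom therefore demonstrate that the
algorithms implement their stated contracts and recover known ground truth
under a realistic noise family — not that any specific clinical accuracy
carries over.

## Problem sizes and determinism

The test suite and the acceptance script regenerate everything from code
at fixed seeds: 100 full-geometry (1407 × 2000) speckled phantoms for
thickness recovery (median |error| ≤ 2 px; exact recovery noise-free), 50
speckled phantoms (300 × 260) for abrasion detection, 10 for closed-mask
accounting and speckled class recovery, 6-slice volumes for the en-face
series, and 100 simulated cohorts for the ANOVA power study. Each
generator call is bit-reproducible from its seed; series draw from one
seeded stream so whole experiments replay identically.

## Known limitations

* Thickness is optical path length; no refractive-index correction.
* The DEJ readout assumes dentin is darker than enamel at the junction;
  heavy adhesive shadowing can invert that locally.
* Abrasion detection is resolution-limited (see above) and reports lateral
  extent, not notch depth.
* The KS p-value is conservative for estimated parameters; use it for
  screening, not inference.
* RM-ANOVA assumes sphericity; with 4 stages and strong heterogeneity the
  nominal p-values can be optimistic.
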