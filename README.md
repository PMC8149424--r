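# enameloct

Quantitative analysis of tooth enamel in optical coherence tomography
(OCT) images: how much enamel is present, how thick it is, and where the
surface has been abraded — the questions that arise when orthodontic
brackets are bonded to and debonded from teeth and the enamel must be
assessed non-destructively at each treatment stage.

The package is aimed at dental-imaging researchers working with grayscale
OCT B-scans (depth × lateral intensity images) and C-scan volumes. It
implements three image pipelines plus the group statistics to compare
treatment stages, and ships a synthetic tooth-phantom generator with full
ground truth so every stage is testable without clinical scans.

## Methods at a glance

**Depth-intensity profile analysis.** Within a lateral window of 10
A-scans, each A-scan's first intensity peak (the air–enamel surface) is
detected and the A-scans are shifted so all surfaces align at depth index
1 ("flattening"); the window is averaged and max-normalized, giving a
profile *I(z)* with *max I = 1*. The surface peak sits at *z = 0* and the
dentinoenamel junction (DEJ) appears as the strongest remaining peak, so
enamel thickness is

&nbsp;&nbsp;&nbsp;&nbsp;*T = (z<sub>DEJ</sub> − z<sub>surface</sub>) · Δz*,

with Δz the axial pixel pitch in µm.

**Structural connectivity.** Laplacian-of-Gaussian filtering → global Otsu
binarization → 8-connected component tracing → morphological opening →
Sobel edge overlays → morphological closing. The *total enamel* is the sum
of source intensities over the closed connected mask; closing-induced
growth above the local surface marks **abrasion sites**.

**Intensity-based layer segmentation.** 5×5 median filtering → multilevel
Otsu thresholds *t₁ < … < tₙ* maximizing the between-class variance →
per-pixel intensity classes → per-class connected structures and closing →
colour overlay. En-face slices are extracted at a fixed depth below the
per-column detected surface (e.g. 500 µm).

**Group statistics.** Per-stage summaries (mean, SD, min, max), one-way
within-subject (repeated-measures) ANOVA with
*F = MS<sub>treatment</sub>/MS<sub>error</sub>*, Bonferroni-corrected
paired t-tests over all stage pairs, and Lilliefors-style
Kolmogorov–Smirnov normality checks.

## Worked example

Measure enamel thickness on a synthetic speckled B-scan (2000-A-scan
geometry scaled down; truth thickness 200 px at 5 µm/px = 1000 µm):

```r
library(enameloct)

sp  <- phantom_spec(shape = c(700, 120), surface = 80, thickness = 200, seed = 42)
out <- generate_bscan(sp)
res <- depth_profile_analysis(out$bscan, roi(1, 120, 1, 700), window_size = 10)
res[1:4, c("window", "x_start", "x_end", "thickness_um", "dej_found")]
#>   window x_start x_end thickness_um dej_found
#> 1      1       1    10          995 TRUE
#> 2      2      11    20          995 TRUE
#> 3      3      21    30         1000 TRUE
#> 4      4      31    40         1005 TRUE
median(res$thickness_um)
#> [1] 1000
```

Each row is one 10-A-scan window; the per-window estimates scatter by a
pixel or two around the truth because of speckle, and their median
recovers the 1000 µm ground truth exactly.

Group statistics over a simulated 30-subject, four-stage cohort at the
published effect sizes:

```r
gs <- run_group_stats(simulate_enamel_metrics(seed = 7))
gs
#> # A tibble: 4 × 6
#>   stage                                mean    sd   min   max     n
#> 1 Baseline (Control)                   812.  111.  624. 1026.    30
#> 2 After Pumice, Etch, & Bonding Agent  683.  150.  463. 1089.    30
#> 3 After First Debonding                599.  106.  454.  882.    30
#> 4 After Second Debonding               546.  142.  257.  775.    30
#> Repeated-measures ANOVA: F(3, 87) = 47.77, p = 2.415e-18
```

The F statistic tests whether the stage means differ within subjects
(df = 3 treatment, 87 error); `tidy(gs)` returns the six
Bonferroni-corrected pairwise comparisons and `autoplot(gs)` draws the
per-stage box plot.

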