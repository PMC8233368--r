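---
title: "Quantifying nerve and muscle ultrasound: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nerve and muscle ultrasound: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SonoQuant)
```

## The measurement model

SonoQuant quantifies two complementary aspects of a traumatized
peripheral nerve from transverse ultrasound stills, inside an
operator-drawn region of interest (ROI):

**Morphology (B-mode).** The fascicular ratio FR is the fraction of the
nerve cross-section that is hypoechogenic. The pipeline is: convert to
8-bit grayscale (unweighted channel mean), invert (so the dark
fascicles become the bright foreground), subtract the rolling-ball
background estimate, build the intensity histogram of the ROI pixels,
binarize at the Kapur maximum-entropy threshold, and report
FR = 100 · foreground / ROI in percent. The cross-section area is
CSA = ROI pixels × pixel area (mm²), and the cross-section ratio
CSR = mean(affected CSA) / mean(unaffected CSA) per patient.

**Vascularity (color Doppler).** Color-Doppler overlays encode flow
direction in hue (blue away from, red toward the transducer) and speed
in lightness. Subtracting channels classifies overlay pixels into four
classes — light blue = sat(G−R), dark blue = sat(B−G), light red =
sat(G−B), dark red = sat(R−G), with sat clamping negatives to zero —
and leaves every grayscale pixel (R=G=B), i.e. the B-mode tissue under
the overlay, at exactly zero in all four maps. Because direction is
clinically irrelevant here, the light pair and the dark pair are merged
by pixel-wise maximum projection into one high-velocity and one
low-velocity map. Each merged map is binarized at the maximum-entropy
threshold of its ROI histogram and filtered by particle analysis
(8-connected components of at least `minParticlePx` pixels). The
low-velocity maps also respond to high-velocity pixels (a cyan pixel
has B−G > 0), so the low mask is corrected by set difference
low \\ high. The vascular ratio is
VR = 100 · |high ∪ corrected low| / |ROI|; on muscle frames the same
number is called the muscle perfusion ratio MPR. The high-velocity
proportion |high| / |total| is reported as a fraction in [0, 1], and is
undefined (NA) when there is no signal at all.

### The maximum-entropy threshold

For a 256-bin histogram with probabilities $p_i$, the Kapur criterion
evaluates, for every candidate $t \in [0, 254]$,

$$H_b(t) = -\sum_{i \le t} \frac{p_i}{P_t}\ln\frac{p_i}{P_t}, \qquad
  H_f(t) = -\sum_{i > t} \frac{p_i}{1-P_t}\ln\frac{p_i}{1-P_t},$$

with $P_t = \sum_{i \le t} p_i$, zero-probability bins contributing
nothing, and picks the $t$ maximizing $H_b + H_f$. Numerical choices,
each covered by a test:

- foreground is *strictly above* t;
- ties break toward the smallest t, so results are platform-independent;
- natural logarithm (the base cannot change the argmax);
- candidates where either class is empty are excluded;
- all 256 bins participate, including the saturated ones;
- a histogram with fewer than two occupied bins is *degenerate*: the FR
  pipeline then reports FR = 0 with a flag (a uniform ROI has no
  fascicle/epineurium contrast to measure), and Doppler signal
  selection returns an empty mask with a flag (absent flow is a valid
  clinical observation, not an error).

The implementation is verified against an independently coded
brute-force scan over all 255 candidates on hundreds of random mixture
histograms, including tie behavior.

### Geometry conventions

Pixels are addressed as x = column, y = row, origin at the top-left,
zero-based; pixel (x, y) covers [x, x+1) × [y, y+1). A pixel belongs to
a rasterized polygon iff its center (x+0.5, y+0.5) lies strictly inside
(boundary excluded); the rasterizer is tested against a brute-force
point-in-polygon check over every center. ImageJ `.roi` polygon files
use the same convention and are read without coordinate shifts. 16-bit
images are rejected rather than rescaled, since silent rescaling would
move every threshold.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `radius` (rolling ball) | 50 px | Disk radius of the grayscale-opening background estimate. Structures wider than ~2·radius are treated as background; the default is the customary background-subtraction default of raster tools and comfortably exceeds fascicle diameters at typical HRNS scales. |
| `minParticlePx` | 1 px | Particle-analysis size filter on Doppler signal components; 1 keeps everything (no size filter is part of the core method). |
| `pixelArea` | — | mm² per pixel; required for CSA (no silent default; the reference probe setting is 0.004017 mm²). |
| `correctIntensities` | FALSE | Alternative reading of the low-velocity correction: subtract the merged high *intensity map* from the low map before thresholding, instead of (only) the mask set difference. Kept for sensitivity analysis; the mask-domain difference is always applied last, which guarantees the partition high + corrected low = total. |

The order of operations in the FR pipeline — invert first, then
background-subtract — follows the stated acquisition workflow; both
orders are available to a caller by composing `invertFrame()` and
`rollingBallBackground()` directly. Thresholds are always computed from
ROI histograms, not whole frames, matching the manual-ROI workflow; the
building blocks accept any mask, so whole-frame thresholding is a
one-line variant.

## The synthetic-frame generator

Clinical frames cannot ship with the package, so every claim about the
pipelines is established on generated frames with exact ground truth.

**What is emulated.** B-mode: a bright speckled background
(epineurium/surrounding tissue, mean 200) with dark fascicle blobs
(mean 40) painted inside the ROI; random ellipses are drawn first and
the blob frontier is then grown or trimmed pixel-by-pixel so the union
covers *exactly* `round(fraction · ROI)` pixels. Doppler: a grayscale
speckle background (R=G=B, mean 90) with vessel-like blob overlays in
the four palette classes, with exact class areas. The speckle is a
spatially correlated Rayleigh-shaped field (i.i.d. Rayleigh smoothed to
~1 px grains, standardized) applied with constant depth on the display
scale (default 0.06·255 ≈ 15 gray levels); displayed ultrasound is
log-compressed, which flattens the raw multiplicative speckle to
roughly constant display-scale depth, and the spatial correlation is
what makes a morphological background estimate meaningful at all —
pointwise-independent noise would drive the opening to extreme order
statistics.

**Palette design.** Overlay colors are idealized class anchors — cyan
(15, 190, 230) and deep blue (30, 22, 200) for flow away, their exact
R↔B mirrors (230, 190, 15) and (200, 22, 30) for flow toward — plus
per-pixel *common-mode* jitter: the same offset on all three channels,
modeling the underlying echo brightness shining through the overlay.
Common-mode jitter preserves every class-defining channel ordering
strictly (light blue G>R, dark blue B>G, light red G>B, dark red R>G)
and leaves the channel *differences* at their anchor constants. This is
a deliberate choice with a quantitative reason: the Kapur criterion,
applied to a histogram consisting of a large zero spike plus a class
spread over k bins, prefers to *split* the spread class once it covers
more than roughly a third of the ROI — for any k ≥ 3 — which would
bias VR downward by 10–20 points on heavily vascularized frames.
Vendor palettes are narrow color ramps, and the degenerate-width class
model keeps the generator inside the regime where the published method
is a consistent estimator. Independent per-channel noise is therefore a
known, documented blind spot of the test bed, not an oversight. Note
also that the *high→low* bleed-through (cyan's B−G residue) is retained
— it is exactly what the correction step exists for — while dark
classes are built with no *dark→high* cross-talk (G ≤ R for deep blue),
which the method has no mechanism to remove and which real deep-blue
palette entries (R ≈ G ≈ 0) do not produce.

Red-class pixels being exact channel mirrors of blue-class draws makes
the merged maps — and hence VR and the high-velocity proportion —
bit-identical under changes of the toward/away mix, which is how the
direction-independence of the method is tested exactly rather than
statistically.

**What is not emulated.** Point-spread-function blur across tissue
boundaries, attenuation and depth-dependent gain, palette gradients
within a velocity class, independent chroma noise, compression
artifacts, and UI chrome (color bars, annotations) inside the ROI.
Passing recovery tests therefore demonstrates correctness of the
*algorithmic chain* under controlled class structure, not robustness to
every acquisition artifact of clinical frames.

**Known estimator bias.** On speckled B-mode frames the entropy
threshold's position depends on the fascicle/background class
proportions, producing a small regression-to-center bias in FR —
positive at low fascicle fractions, negative at high ones, of order 3
points, independent of speckle depth. The recovery tests bound the
absolute error at 5 points per frame; a sign-free bias across fractions
is *not* claimed.

## The cohort statistics layer

Per-frame measurements are averaged per subject and site before
testing (the acquisition protocol takes six frames per site).
`compareGroups()` then applies the study's decision tree:

- normality per group: D'Agostino–Pearson K² for n ≥ 8 (verified to
  ~10 decimals against an independent reference implementation),
  Shapiro–Wilk for 3 ≤ n < 8; groups with n < 3 or zero variance force
  the nonparametric branch (no normality test is defined there, and
  fully tied data carry no evidence — such comparisons report p = 1);
- all groups normal → one-way ANOVA with Tukey's post-hoc; otherwise
  Mann–Whitney (2 groups) or Kruskal–Wallis with Dunn's post-hoc,
  Bonferroni-adjusted (the conventional default for "Dunn's multiple
  comparison"); the gate decisions are echoed in the report's `notes`;
- stars code p ≤ 0.05 (*), ≤ 0.01 (**), ≤ 0.001 (***), boundaries
  inclusive.

Two calibration facts are worth knowing when planning small studies
with this tree. First, the gate keeps the overall type-I rate at the
nominal 5% (the suite measures it over 1000 null cohorts at the
study's group sizes, 9 vs 4). Second, exact rank tests have a floor on
attainable p-values: Mann–Whitney with n = 9 vs 4 can never reach
p ≤ 0.001 (the floor is 2/C(13,4) ≈ 0.0028), so a fixed "p ≤ 0.001"
claim for a two-group design of that size fails in the ~10% of runs
where the gate goes nonparametric — with three groups (Kruskal–Wallis)
or larger groups the floor disappears. The power checks in the suite
use the study's actual designs: the three-group nerve comparison and
the 9-vs-9 muscle comparison.

## Problem sizes used by the test suite

Recovery properties run on 128×128 frames with a 16-gon ROI of radius
44 px (5956 px): the Doppler grid covers painted fractions
{0.05, 0.15, 0.45} × high-class mixes {0.16, 0.33, 0.56} × 10 seeds,
the B-mode grid fascicle fractions {0.2, 0.5, 0.8} × 20 seeds. The
type-I calibration uses 1000 reseeded null cohorts and the power check
200 reseeded cohorts at the reference group means, drawn at the
subject level — the imaging stage reproduces generator truth exactly
(the Doppler recovery error is zero to machine precision), so
re-rendering tens of thousands of frames would add cost but no
information; one rendered cohort is nevertheless measured end to end,
images to statistics. The acceptance script renders the full-size
cohort (9/9/4 nerve subjects, 9/9 muscle subjects, six frames per
site).

## Limitations

- ROIs are operator-supplied; no automatic nerve segmentation.
- The color palette is treated as a categorical encoding; no velocities
  in cm/s, no spectral Doppler.
- Frame selection from cine loops is manual and upstream of the
  package.
- The FR estimator inherits the proportion-dependent threshold bias
  described above; comparisons between groups are unaffected in
  practice because the bias is shared, but absolute FR values near the
  extremes are compressed by a few points.
- Reported clinical group means are used only as generator defaults;
  nothing in the package re-derives clinical results from patient data.
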