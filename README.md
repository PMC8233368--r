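# SonoQuant

Pixel-based quantification of high-resolution neurosonography (HRNS) for
peripheral nerve trauma. After a nerve injury, the damaged segment
(neuroma) changes both its morphology and its vascularity: the
hypoechogenic (fascicular) area fraction rises, the cross-section area
grows, and the intraneural blood-flow signal seen in color Doppler
increases, while the perfusion of the denervated target muscle drops.
SonoQuant turns still ultrasound frames plus hand-drawn regions of
interest into the four quantitative parameters that capture these
changes, for clinicians and researchers assessing nerve lesions:

- **FR (fascicular ratio)** — percentage of the nerve cross-section that
  is hypoechogenic. A B-mode frame is converted to 8-bit, inverted,
  contrast-enhanced by rolling-ball background subtraction, and
  thresholded inside the ROI with the Kapur maximum-entropy criterion;
  FR = 100 · (foreground px) / (ROI px).
- **CSA / CSR (cross-section area / ratio)** — CSA = (ROI px) · (mm²
  per px); CSR = mean affected CSA / mean unaffected CSA per patient.
- **VR (vascular ratio)** and **MPR (muscle perfusion ratio)** —
  percentage of the ROI covered by color-Doppler flow signal. The RGB
  frame is split into channels and decomposed by saturating channel
  subtraction into four velocity/direction classes (light blue = G−R,
  dark blue = B−G, light red = G−B, dark red = R−G, negatives clamped
  to 0). Light (high-velocity) and dark (low-velocity) classes are
  merged as pixel-wise maximum projections, each merged map is
  binarized by the maximum-entropy threshold of its ROI histogram and
  passed through particle analysis, the low mask is corrected by
  subtracting the high mask (the low-velocity maps also respond to
  high-velocity overlay pixels), and VR = 100 · |high ∪ corrected
  low| / |ROI|. The **high-velocity proportion** |high| / |total| is
  reported alongside.

The maximum-entropy threshold t* maximizes H_b(t) + H_f(t), the sum of
the Shannon entropies of the normalized histogram below and above the
candidate threshold; foreground is strictly above t*, ties break to the
smallest t.

Because clinical ultrasound frames cannot be redistributed, the package
ships a synthetic-frame generator with exact ground truth (speckled
B-mode nerve sections and four-class Doppler overlays) and a cohort
statistics layer (normality-gated ANOVA/Tukey or Mann-Whitney /
Kruskal-Wallis + Dunn, Pearson correlation), so the entire method is
testable end to end.

## Worked example

```r
library(SonoQuant)

roi <- circularRoi(128, 44)                      # 16-gon ROI, r = 44 px
sim <- simulateDopplerFrame(roi, dopplerFraction = 0.43,
                            highClassFraction = 0.36, seed = 42,
                            dim = c(128, 128))
computePerfusion(sim$frame, roi)
#> PerfusionResult: VR/MPR 43.00% (total 2561 / ROI 5956 px)
#>   high 922 px, corrected low 1639 px, high-velocity proportion 0.360

nerve <- simulateBmodeNerve(roi, fascicleFraction = 0.88, seed = 42,
                            dim = c(128, 128))
computeFR(nerve$frame, roi)
#> FascicleResult: FR 84.91% (5057 / 5956 px), threshold 177
```

The Doppler pipeline recovers the painted 43% overlay fraction and the
0.36 high-velocity mix exactly; the B-mode pipeline recovers the 88%
fascicular fraction to within a few points (speckle and the
proportion-dependent placement of the entropy threshold cost ~3 pp at
extreme fractions).

A full synthetic cohort, measured end to end and compared between
sites:

```r
man <- simulateCohort(framesPerSite = 3L, seed = 7, frameSize = 96L,
                      roiRadius = 32)
tab <- aggregatePerSubject(measureCohort(man))
cmp <- compareGroups(tab, "vr", c("neuroma", "unaffected", "healthy_control"))
#> Kruskal-Wallis + Dunn (Bonferroni): statistic = 16.5, p = 2.62e-04 ***
```

Frames read from disk work the same way: `readFrame("frame.png")`,
`readRoi("nerve.roi")` (ImageJ polygon `.roi` or JSON), then
`computeFR()` / `computePerfusion()`. A command-line front end wrapping
these functions is installed at
`system.file("scripts", "sonoquant-cli.R", package = "SonoQuant")` with
subcommands `fr`, `vr`, `mpr`, `csa`, `csr`, `simulate` and `report`.

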