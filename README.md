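# thighMAT

Quantification of thigh muscle and adipose tissue from axial T1-weighted
MR image stacks, for researchers studying muscle atrophy, disuse and
exercise interventions. Given a stack of axial slices with traced muscle,
deep-fascia and femur outlines, the package measures, per subject and
session, the volume of each of the 13 thigh muscles and of three adipose
depots — intramuscular (IntraMAT, adipose pixels inside a muscle's
boundary), intermuscular (InterMAT, sub-fascial adipose outside all
muscles) and subcutaneous (SAT) — and runs the longitudinal statistical
battery such studies report. Because studies of this kind rarely deposit
images, a synthetic thigh-phantom generator with exact ground truth is a
first-class part of the package: every stage is validated against
phantoms whose true composition is known to the pixel.

## The method

1. **Bias-field correction.** Surface-coil nonuniformity multiplies the
   image by a smooth field *f*. The field is estimated per slice by
   iterative histogram sharpening: the log-intensity histogram of signal
   pixels is deconvolved (Wiener filter) of a Gaussian kernel of full
   width at half maximum 0.15, each pixel is mapped to its expected true
   log intensity under the sharpened distribution, and the residuals are
   smoothed with a tensor-product cubic B-spline (control points every
   25 mm) and accumulated until the coefficient of variation of the
   between-iteration field ratio falls below 10⁻⁴ (at most 100
   iterations; signal threshold 1; subsampling factor 4; Wiener noise
   constant 0.01). The slice is divided by the field, preserving the
   mean over signal pixels.
2. **Threshold segmentation.** Three regions of interest in muscle
   tissue and three in SAT are pooled; the muscle/fat threshold is the
   intensity at the base of the first peak of the pooled bimodal
   histogram — the first local minimum after the lowest-intensity mode
   of the smoothed histogram. The analysis is repeated three times with
   re-jittered ROIs and the thresholds averaged. Within each traced
   muscle, pixels below the threshold are muscle tissue and pixels above
   it IntraMAT; above-threshold pixels inside the fascia but outside
   every muscle are InterMAT; the region between the fascia and the skin
   is SAT.
3. **Volumetry.** CSA (cm²) = pixel count × (FOV/matrix)²; at the
   default geometry (450 × 270 mm FOV, 320 × 192 matrix) one pixel is
   (45.0/320)² = 0.019775 cm². Volume (cm³) = Σᵢ eᵢ × CSAᵢ over slices,
   with eᵢ the 24 mm centre-to-centre slice distance. Muscles aggregate
   into quadriceps (QF), hamstrings (HM), adductors (AD) and the whole
   thigh. IntraMAT content (%) = IntraMAT/(muscle + IntraMAT) × 100.
4. **Statistics.** Two-factor mixed repeated-measures ANOVA
   (time × group) with partial η² = SS_effect/(SS_effect + SS_error),
   Bonferroni post-hoc tests with Cohen's *d*, within-group changes with
   t-based 95% CIs, Aspin–Welch unequal-variance comparison of
   percentage changes, Pearson correlation with post-hoc power (Fisher
   *z* with small-sample bias correction), and ICC(2,1) with the
   standard error of measurement for reproducibility.

## Worked example

An 8-slice four-muscle phantom at muscle signal-to-noise 20 with a 20%
bias field and known IntraMAT fractions 0.05/0.10/0.15/0.20:

```r
library(thighMAT)
fr   <- c(RF = 0.05, VL = 0.10, VI = 0.15, VM = 0.20)
spec <- defaultPhantomSpec(nSlices = 8, muscles = names(fr),
                           intramatFraction = fr, seed = 11)
ph   <- generatePhantom(spec)                      # stack + ground truth
co   <- correctStack(ph$stack)                     # bias correction
seg  <- classifyStack(co$corrected, ph$outlines, seed = 2)
vols <- volumeTableFromCSA(labelCSATable(seg$labels), spec@geometry)
subset(vols, structure %in% c(names(fr), "QF"),
       select = c(structure, tissueVolume, intramatVolume, intramatContent))
#>    structure tissueVolume intramatVolume intramatContent
#> 3         QF       2075.4         296.16          12.488
#> 4         RF        563.1          29.62           4.997
#> 8         VI        503.8          88.85          14.990
#> 9         VL        533.8          59.23           9.987
#> 10        VM        474.6         118.46          19.974
```

The recovered IntraMAT contents (5.0%, 10.0%, 15.0%, 20.0%) match the
generating fractions, and the quadriceps volume equals the ground truth
(`ph$truth@volumes`) to the pixel. The statistical battery runs on any
long volume table with subject/group/session columns
(`cohortStats(volumes)`); individual pieces are exported, e.g. the
post-hoc power of a correlation test at an observed effect size:

```r
correlationPower(-0.626, n = 13)   # two-sided, alpha = 0.05
#> [1] 0.6690571
```

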