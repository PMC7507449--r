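---
title: "Quantifying thigh muscle and adipose tissue: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thigh muscle and adipose tissue: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the engineering decisions behind
thighMAT: what each stage assumes, which tunables matter and why their
defaults are what they are, what the synthetic phantoms do and do not
emulate, and where the design was genuinely open.

# The measurement model

An axial T1-weighted slice is modelled as

$$ I(x) = f(x)\,S(x) + \varepsilon(x), $$

where $S$ is the true tissue signal — approximately two-valued, with a
low muscle mode and a high adipose mode — $f$ is a smooth multiplicative
bias field caused by coil nonuniformity, and $\varepsilon$ is noise. The
pipeline inverts this model in three steps: estimate and divide out $f$,
find the muscle/fat intensity threshold from bimodal region-of-interest
histograms, and classify pixels within manually traced anatomical
outlines. Areas and volumes are then pure bookkeeping:
$\mathrm{CSA} = \text{count} \times (\mathrm{FOV}/\mathrm{matrix})^2$ and
$V = \sum_i e_i\,\mathrm{CSA}_i$ with $e_i$ the centre-to-centre slice
distance.

Assumptions worth making explicit: the bias field is smooth at the scale
of the spline control-point distance (25 mm) and is the only
multiplicative disturbance; the within-tissue intensity distribution is
unimodal per tissue so the pooled muscle + SAT histogram is bimodal; the
traced outlines are correct (tracing is an input, not something the
package does); and slices are far enough apart (24 mm centre-to-centre)
that correction and segmentation are sensibly done in 2-D per slice.
That last point resolves an ambiguity — nothing in the acquisition
states whether nonuniformity correction ran per slice or on the 3-D
stack — and per-slice is the defensible reading given the 12 mm gap.

# Bias-field estimation

`estimateBiasField()` implements the iterative histogram-sharpening
scheme. Per cycle: form the histogram of corrected log intensities of
signal pixels; sharpen it by Wiener deconvolution of a Gaussian kernel;
map every pixel to its conditional expected true log intensity; smooth
the residuals with a tensor-product cubic B-spline; accumulate; stop
when the coefficient of variation of the ratio between successive fields
drops below the end tolerance.

The seven tunables (defaults in parentheses) are the ones practitioners
of this correction know: end tolerance (10⁻⁴, dimensionless CV), maximum
iterations (100), signal threshold (1, intensity units — pixels below it
are air and excluded), field distance (25 mm, the spline control-point
spacing, converted to pixels via the pixel spacing), subsampling factor
(4, fitting grid decimation), kernel FWHM (0.15, in log-intensity
units), and Wiener noise constant (0.01). These defaults are the
optimized values used with 1.5 T thigh imaging and are left untouched by
every test in the package.

Two numerical choices are ours and deserve a record:

* **Histogram domain padding.** The bin domain extends six kernel sigmas
  beyond the observed log-intensity range. Without padding, the tissue
  modes sit exactly at the range edges once the field is nearly
  converged; the deconvolution ringing is then truncated asymmetrically,
  which biases the conditional-mean mapping differently for each tissue
  mode. Because tissue composition varies across the slice (the
  subcutaneous ring is pure fat while the fascial interior is mixed),
  those per-mode biases masquerade as a smooth spatial field and the
  iteration stalls near 1% RMS error. With padding, recovery of a known
  polynomial field on a noiseless phantom is exact to ~10⁻⁴ RMS.
* **Mass-split binning.** Each sample splits linearly between its two
  nearest bins, removing sub-bin quantization offsets of near-delta
  histograms.

The smoother solves a ridge-stabilized (10⁻⁶ relative) least-squares
problem in the tensor B-spline basis; the normal equations are factored
once per slice, so a 100-iteration correction of a 320 × 192 slice runs
in about a second.

# Threshold determination

The muscle/fat threshold is "the base of the first peak" of the pooled
bimodal ROI histogram. The estimator makes that landmark precise: on the
histogram smoothed with a Gaussian of σ = 2 bins, take the first
windowed local maximum with at least 5% of the peak mass (stray tail
bumps are not modes), then the first local minimum after it; bins whose
smoothed counts are statistically indistinguishable from that minimum
(within $\sqrt{v_{\min}+1}$, the Poisson counting-noise scale) form a
plateau whose midpoint is the threshold. The plateau rule matters
whenever the modes are well separated: the between-mode density then
underflows to zero counts over a wide run, any point of which separates
the classes, and the run midpoint is the estimator with by far the
smallest variance — for symmetric modes it coincides with the minimum of
the generating mixture density. The bin count defaults to
$\min(256, 2\sqrt{n})$: 256 bins suit the large pooled samples used in
validation, while the ~400-pixel samples of six small ROI disks would
leave most of 256 bins empty.

The analysis is repeated three times with ROI disk centres re-jittered
by up to 2 px (seeded) and the thresholds averaged — the repetition
count and averaging mirror the manual procedure, whose repetitions vary
operator ROI placement. Pooled ROI intensities below a quarter of the
sample median are discarded before histogramming: ROIs are placed in
tissue by construction, so such values can only be air picked up at the
edge of the subcutaneous ring, and a cluster of near-zero values would
fake a low first mode. Ties at the threshold classify as muscle: the
published rule assigns "lower" to muscle and "higher" to adipose and is
silent on equality, so the tie rule is documented and tested rather than
implicit.

Within-fascia sub-threshold pixels outside every muscle polygon belong
to no published tissue class; they are counted and reported as
`unassigned` rather than silently folded into InterMAT, whose definition
is strictly above-threshold. No connectivity rule is applied to
InterMAT. The SAT outer boundary is the supra-background connected
component containing the fascia (background threshold: half the
muscle/fat threshold), so SAT by direct labelling equals the
total-minus-parts subtraction identically — the partition makes the
published subtraction equation an invariant, not an approximation.

# The phantom generator

`generatePhantom()` renders what the study conditions require and
nothing more: a fascia ellipse holding 13 (or fewer) muscles as
non-overlapping annular sectors around a femur disk, a subcutaneous fat
ring out to the skin ellipse, bimodal intensities (muscle 100, fat 200
a.u.), additive Gaussian noise (sd 5 by default, i.e. muscle SNR 20;
Rician optionally for realism checks), a clamped second-order polynomial
bias field (amplitude 0.2, range [0.8, 1.25]) and uniform random
IntraMAT speckle at a per-muscle area fraction (default 0.15, matching
mid-teens IntraMAT contents in adult thighs). Default matrix geometry is
450 × 270 mm interpolated to 320 × 192 px, 12 mm slices with 12 mm
gaps; 15 slices span a 36 cm thigh segment. The fascia and femur
regions are rasterized from the same polygons returned as outlines, so
a noiseless phantom round-trips through classification pixel for pixel.

What the phantom does **not** emulate — and what green tests therefore
do not show about real data: anatomical muscle shapes and their
along-thigh variation, partial-volume pixels at tissue borders, Rician
noise floors at low SNR (unless enabled), chemical-shift artefacts, and
tracing error in the outlines. The phantom validates the computational
pipeline, not the tracing.

`generateCohort()` draws, per subject and structure, a true baseline
volume and a true before/after change from Normal effect models; the
default models come from published group summaries of an 8-week
bed-rest study with a pooled resistance-exercise group (n = 13) and a
non-exercise control group (n = 7), with the change sd recovered from
the printed 95% CI half-width as $\mathrm{sd} = h\sqrt{n}/t_{0.975,n-1}$.
The drawn volumes are the cohort's ground truth (volumes-only mode, the
default, is what the statistical battery consumes). Rendered mode
scales each template muscle polygon so its volume relative to the
template equals the subject's drawn volume relative to the group
baseline mean; this keeps study-scale effect models (thousands of cm³)
compatible with any template anatomy, at the cost that absolute rendered
volumes are meaningful only relative to the template. Two printed rows
of the source summaries are internally inconsistent with their own
session means (the control-group whole-thigh muscle change, which
duplicates the SAT row, and the control-group InterMAT change); they are
carried verbatim in `studyChangeTable()` but excluded from arithmetic
checks.

# Statistics

The two-factor mixed ANOVA (time within subject × group between
subjects) is computed from sums of squares directly, via per-subject
sums and differences, so the F/df/partial-η² triples are transparent and
testable: the between stratum is a one-way ANOVA on subject means, the
within stratum decomposes the difference scores into time, interaction
and error. With unequal group sizes the time main effect uses
unweighted (type III) group means, matching conventional statistical
software; the tests verify equality with `aov()` on balanced designs and
with type-III multivariate repeated-measures output on unbalanced ones.
Degenerate inputs (zero error variance) report F as computed with a
`degenerate` attribute instead of failing.

Correlation power uses the Fisher $z$ approximation with the
conventional small-sample bias correction,
$z_r = \operatorname{atanh} r + r/(2(n-1))$, and the critical $r$ taken
from the t distribution with $n-2$ df. The uncorrected Fisher $z$
underestimates power noticeably at n = 13 (0.642 where the corrected
form gives 0.669 for |r| = 0.626); the corrected form is the package's
convention and is what `pearsonWithPower()` reports. Cohen's *d* for
between-group percentage-change comparisons uses the pooled standard
deviation; the paired post-hoc *d* is the mean change over the sd of
changes. ICC(2,1) is the two-way random absolute-agreement single-measure
form, $(MS_R - MS_E)/(MS_R + (k-1)MS_E + k(MS_C - MS_E)/n)$, with
$\mathrm{SEM} = \mathrm{sd}\sqrt{1-\mathrm{ICC}}$ over all measurements.

# Validation problem sizes

The test suite validates at sizes chosen to exercise every code path
while keeping a full run around a minute: most phantom tests use a
160 × 96 px geometry (same 1.40625 mm pixel spacing) with 1–2 slices;
the segmentation-recovery check runs the full 320 × 192 geometry with 8
slices and four muscles at SNR 20; threshold-estimator accuracy is
checked against brute-force mixture-density minima on a 20-case grid of
two-Gaussian mixtures at 10⁶ samples per repetition — large enough that
the comparison tests estimator bias rather than sampling noise, with the
grid restricted to cases where the empirical minimum is well-posed
(populated valleys, or symmetric modes whose empty-valley midpoint is
the analytic minimum); the design-power property uses 200 simulated
cohorts of 8 + 7 subjects. Statistical formulas are held to 10⁻⁸
against independent oracles.

# Known limitations

Sector-shaped muscles make polygon-containment edge cases (concavities,
self-intersections) untested against realistic tracings, although the
even-odd rule handles them by construction. Bias fields harsher than
the clamped ±20–25% polynomial, or structured noise, are outside the
validated envelope. The ANOVA handles exactly two sessions (before and
after), as the designs it serves require; more repetitions belong to a
mixed-model framework out of scope here. Rendered cohorts quantize
volumes to one pixel-slab (≈ 0.047 cm³ at default geometry), so drawn
and rendered truth agree only to that resolution.
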