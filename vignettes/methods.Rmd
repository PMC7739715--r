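---
title: "Models, phantoms and design choices in adipoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, phantoms and design choices in adipoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoquant)
```

adipoquant reimplements, as one tested chain, the measurements behind a
pre-/post-menopausal exercise-intervention study of adipose tissue: MRI
depot masses, PET glucose uptake, and the group-by-time statistics. Real
participant data are not publicly available, so the package's first-class
citizens are generators — image phantoms, kinetic simulations, cohort
tables — whose ground truth is known exactly. This vignette explains the
models, the defaults and why they were chosen, what the synthetic data do
and do not emulate, and the numerical corners that needed decisions.

## 1. The MRI segmentation model

The chain mirrors a typical in-house MATLAB pipeline for water-suppressed
T1 abdominal imaging: fat is bright, muscle mid-grey, air dark.

**Bias correction.** Each slice's log-intensity is modelled as a smooth
multiplicative field plus per-tissue offsets. We alternate a 2-class
k-means tissue classification with a least-squares fit of a degree-4
two-dimensional polynomial to the class-centred log-intensities, then
divide the field out and restore the original mean foreground intensity.
The class-centring matters: fitting the polynomial to raw log-intensities
would absorb genuine anatomy (the bright subcutaneous ring) into the
"bias" and flatten the contrast the later stages rely on. The phantom's
bias generator uses degree-2 fields, inside what the degree-4 correction
can represent.

**Unrolling and boundary detection.** Slices are resampled along rays from
the body-mask centroid (360 angles; radial step half an in-plane pixel for
sub-pixel localisation). The outer (skin) boundary comes from the body
mask; the inner SAT boundary is the minimum-cost circular path through
$-\partial I/\partial r$ — the strongest muscle-to-fat edge — under the
smoothness constraint $|r_{j+1}-r_j| \le \delta$ ($\delta$ = 2 radial
samples) including wrap-around. The path problem is solved *exactly*: a
dynamic program runs over all start radii simultaneously and the winning
start is traced back. For a single surface this is equivalent to the
minimum-cut formulation of optimal surface detection, and a brute-force
enumeration oracle on small polar grids verifies the equivalence in the
test suite. After the discrete path is found, both curves are refined to
sub-sample precision (mask 0.5-crossing for the skin; tissue mid-level
crossing for the SAT/muscle edge), which brings boundary error below one
radial sample (≈ 0.59 mm) on noiseless annuli — about the rasterisation
limit of the 1.17 mm pixels themselves.

**The k-means threshold.** The study describes the internal-fat cut as
"the median value of a 5-component k-means clustering" of the
muscular/abdominal compartment — a genuinely ambiguous phrase. The literal
reading (middle of the five sorted centres) fails on muscle-dominated
compartments: 1-D k-means allocates clusters to modes roughly by mass, so
with ~8% internal fat the muscle mode receives four of the five clusters
and *any* centre-based "median", and even the boundary between centres 3
and 4, lands inside the muscle distribution (we measured thresholds of
423–449 against a muscle mode at 400 ± 50, which would misclassify a third
of muscle as fat). We therefore define the threshold as the midpoint
across the *widest gap* between consecutive sorted centres. Because
k-means tiles each well-separated intensity mode internally, the widest
inter-centre gap is the muscle/fat divide however the five clusters split,
and the rule remains translation-equivariant. The literal
`method = "median_center"` is retained as an option.

**Masses.** Volumes integrate voxel counts at the slice *pitch* (7.2 mm,
centre-to-centre) rather than the 6 mm slice thickness, treating the stack
as contiguous anatomy, and convert to mass at 0.9 kg/L exactly. Anatomical
slice ranges (Th11/Th12 disc to last slice without iliac crest for the
visceral depot, and so on) are applied to supplied landmark indices; the
resulting slice count feeds the ANCOVA covariate.

## 2. The PET quantification model

Dynamic tissue curves follow the irreversible two-tissue-compartment
model, $k_4 = 0$:

$$C_t(t) = V_b C_p(t) + \frac{K_1}{k_2+k_3}\left[k_3 + k_2
e^{-(k_2+k_3)t}\right] \otimes C_p(t),\qquad
K_i = \frac{K_1 k_3}{k_2+k_3}.$$

The simulator evaluates the convolution on a 0.01-min grid with trapezoid
end-correction (the closed-form constant-input solution is matched to
0.5%), then averages within each frame of the 26-frame schedule, as
reconstructed dynamic data are. The input function is a Feng-type
tri-exponential (sharp sub-minute peak, bi-exponential washout) with an
analytic AUC; its defaults are conventional rather than study-matched,
since the study does not publish its participants' IDIF shapes.

The default dynamic estimator is the Patlak slope past $t^* = 20$ min — a
deterministic "mathematical model fit to the dynamic time-activity curve";
the weighted nonlinear 2TCM fit (Levenberg–Marquardt with box constraints,
duration weights, seeded multi-start) serves as cross-check and agrees
within 3% on noiseless data. One honest caveat established during
development: for very slow trapping ($k_3 \approx 0.01$/min) the Patlak
slope is intrinsically biased low by 3–8% on a 60-min scan — the
equilibration transient has not converged relative to the tiny $K_i$ — and
an ideal-sampling oracle shows the same bias, so this is a property of the
estimator, not of the implementation. The test suite asserts the 2%
recovery property where it mathematically holds ($k_3 \ge 0.06$) and
documents the slow-trapping regime separately.

The static "estimated Ki" is the fractional uptake rate: mean VOI activity
at the static mid-time (70 min = 60 min dynamic + half of the 2 × 10 min
static block) divided by the IDIF AUC extrapolated to that time
(trapezoid over the samples plus a mono-exponential tail fitted to the
last 20 min; a non-decaying tail degrades gracefully to constant
extrapolation with a warning). For an irreversible tracer
$\mathrm{FUR} = K_i + V_0 C_p(T)/\int_0^T C_p$, so it upper-bounds the
Patlak $K_i$ and tightens as $T$ grows — both properties are tested.
Decay correction uses the F-18 half-life 109.77 min referenced to scan
start, with an explicit correction-state flag so it cannot be applied
twice. CT adipose VOIs are the seeded 26-connected component within
−150…−50 HU (inclusive ends) and are eroded per-slice by a 2-pixel disc.

## 3. The synthetic data, and what passing tests show

The abdominal phantom is a disc (radius 95 mm) with a SAT annulus whose
thickness may vary with angle, scattered circular visceral-fat islands, a
liver ellipse, per-slice quadratic bias and additive Gaussian noise; the
default "study conditions" are 6 slices, noise at 5% of the fat signal and
15% bias amplitude. The CT twin assigns fat voxels uniform HU in
\[−150, −50\]. Ground-truth masses satisfy
`count × voxel volume × 0.9 kg/L` identically, so segmentation accuracy is
measured against an exact reference.

What the phantom does *not* emulate: partial-volume mixing at tissue
interfaces, chemical-shift and motion artefacts, bowel contents and
multi-organ anatomy, or inter-subject shape variability. Consequently a
near-zero mass error on the phantom demonstrates the geometry and
decision logic of the chain — boundary localisation to sub-sample
precision, a threshold placed in the muscle/fat gap, correct bookkeeping —
not clinical-grade accuracy on real scans, where the muscle/fat intensity
structure is richer and the k-means clustering sees more than two modes.

The cohort generator produces one row per participant × time × outcome
with multiplicative structure: a log-normal per-participant size factor
(between-subject CV 0.25) shared across visits, log-normal measurement
noise per visit, a time effect applied to both groups (defaults −4% SAT,
−6% VAT) and optional group and group × time multipliers. The analysed
slice count scales with the size factor, so the ANCOVA covariate carries
real information, as in the study. The default within-subject CV of 0.05
reflects MRI volumetry repeatability (test–retest errors of 1–3% plus
biological drift over 3 months); under it a −6% change at n = 20/group is
detected with ≈ 100% power, consistent with a design powered at 80% for a
20% change. `calibrate_within_cv()` inverts that design statement —
solving for the CV under which a given change reaches a target power on
the paired log-scale analysis — and the simulation harness reproduces the
calibrated power, closing the loop.

## 4. Statistical choices

The repeated-measures structure is a random participant intercept
(compound symmetry), fitted by REML with containment denominator df —
deterministic, and exact for the balanced two-period design, where the
time test provably equals the group-adjusted paired analysis of subject
differences (the suite checks the equality to the optimizer's precision,
about 10⁻⁶ relative; iterative REML cannot match a closed form more
tightly than that). Marginal (type-III) tests are computed under
sum-to-zero contrasts, so main effects average over the design. ls-means
within-group contrasts are reported unadjusted, stated in the output
metadata. The ANCOVA is `value ~ group * time + n_slices` with type-III
tests; a constant covariate is dropped with a warning, and an exactly
collinear outcome (zero residual) is reported via sums of squares rather
than undefined F ratios. Analyses run on raw values by default with a log
option, since the study does not state its scale.

## 5. Problem sizes and determinism

Every stochastic step takes an explicit seed, and the pipeline fans a
single global seed out to stages by stable hashing, so stages rerun alone
reproduce their in-pipeline results; two runs with the same configuration
are identical. The shipped analyses use a 6-slice phantom (~2 × 10⁵
voxels), 100 noisy Patlak replicates, 1000 null cohorts for test size and
500 replicates for power — sizes chosen so the whole suite and the
acceptance script complete in a few minutes on one core while leaving
Monte-Carlo error well inside the asserted margins.

## 6. Known limitations

No PET reconstruction, scatter/attenuation or partial-volume modelling; no
reversible ($k_4>0$) kinetics; no automatic vertebral landmarking (slice
delimiters are inputs); liver and bone-marrow masks are supplied, not
detected; the IDIF aorta geometry is idealised. The boundary detector
assumes a star-convex body outline about the centroid — true for
abdominal and thigh cross-sections, not for arbitrary shapes.
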