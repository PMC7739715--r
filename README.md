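# adipoquant

Quantification chain for adipose-tissue imaging studies of the menopausal
transition and exercise training: automated MRI depot segmentation, dynamic
and static [18F]FDG PET glucose-uptake quantification, and the group × time
repeated-measures statistics used to analyse a two-arm (pre- vs
post-menopausal), two-visit (baseline vs 3 months of training) cohort. The
package targets methodologists who need the full measurement chain —
*images → depot masses → Ki → MRglucose → effect estimates* — as tested,
reproducible code. Because participant-level study data are not publicly
deposited, every input is synthetic: phantom and cohort generators with
exact ground truth make each stage verifiable end to end.

## The methods at its core

**MRI depot segmentation.** Axial T1 slices (1.1719 × 1.1719 mm pixels,
6 mm slices at 7.2 mm pitch) are bias-corrected, unrolled into polar
(angle × radius) coordinates about the body centroid, and the subcutaneous
fat annulus is delineated by an exact minimal-cost circular path through a
radial-gradient cost image subject to |Δr| ≤ δ between adjacent angles —
the single-surface form of graph-cut surface detection. Internal
(visceral / inter-muscular) fat is thresholded with a cut derived from a
5-component k-means clustering of the internal compartment; the manually
segmented liver and the bone marrow enter as exclusion masks. Depot volumes
convert to mass at 0.9 kg/L.

**PET quantification.** Dynamic scans use the 26-frame schedule
(12 × 10 s, 4 × 120 s, 10 × 300 s; 60 min). The blood curve is an
image-derived input function (aorta VOI); adipose VOIs come from CT
connected thresholding at −150…−50 HU with a two-pixel erosion against
spillover. The influx rate constant is the Patlak slope

&nbsp;&nbsp;&nbsp;&nbsp;Ct(t)/Cp(t) = Ki · ∫₀ᵗCp(τ)dτ / Cp(t) + V₀,

cross-checked by an irreversible two-tissue-compartment fit (k₄ = 0,
Ki = K₁k₃/(k₂+k₃)). Static scans yield the fractional uptake rate
("estimated Ki"): mean VOI activity divided by the IDIF area-under-curve
extrapolated from 60 min to the static mid-time (70 min). Glucose uptake is

&nbsp;&nbsp;&nbsp;&nbsp;MRglucose = 1000 · Ki · [glucose] / (LC · ρ),
&nbsp;&nbsp;LC = 1.14, ρ = 0.9 g/mL,

in µmol·kg⁻¹·min⁻¹.

**Statistics.** Outcomes are analysed with a linear mixed model
(group, time, group × time; random participant intercept; REML; containment
df) with unadjusted ls-means within-group contrasts, and depot masses with a
two-way type-III ANCOVA using the number of analysed slices as covariate.
Monte-Carlo harnesses estimate test size and power.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate_phantoms.R --seed 1`, then 02–04).
Stage 2 and 3 print, with seed 1:

```
k-means threshold: 740.6 (muscle ~400, fat ~1000)
  abdominal_SAT  recovered 0.3208 kg vs true 0.3208 kg (+0.00%)
  visceral       recovered 0.0626 kg vs true 0.0626 kg (+0.00%)
  Patlak Ki = 0.00920 (R2 0.9889) | 2TCM Ki = 0.00913 | true 0.00968
  estimated Ki = 0.01132 (upper-bounds the dynamic Ki)
  MRglucose: dynamic 44.83, static 55.18 umol/kg/min
```

The threshold sits in the muscle/fat intensity gap, so both depot masses are
recovered essentially exactly on the noisy phantom; the dynamic Ki estimates
come from a 5%-noise TAC (the noiseless error is ~0.9%), and the static
fractional uptake rate exceeds the dynamic Ki, as it must for an
irreversible tracer with non-zero blood volume. Stage 4 fits the mixed
models (the simulated −6% VAT training effect is detected at
p ≈ 2.5 × 10⁻⁶) and estimates interaction test size (~5%) and design power.

In code, a minimal dynamic-PET quantification is:

```r
library(adipoquant)
sched <- build_frame_schedule()                     # 26 frames / 60 min
inp   <- simulate_input_function(times_min = seq(0, 60, 0.05))
tac   <- simulate_tissue_tac(inp, kinetic_params(0.05, 0.25, 0.06), sched)
fit   <- patlak_ki(tac, inp, t_star_min = 20)
mr_glucose(fit$ki, plasma_glucose_mmol_per_L = 5.0)
```

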