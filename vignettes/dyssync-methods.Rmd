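---
title: "Methods: synthetic post-infarct phantoms and the dyssynchrony pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic post-infarct phantoms and the dyssynchrony pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

After a myocardial infarction (MI), the infarcted wall contracts late and
weakly.  On tagged cardiovascular MR this appears as a delayed, shallow
circumferential strain curve; on an electroanatomic map (EAM) as late local
activation and slow conduction.  `dyssync` implements the full measurement
chain used to quantify this in a closed-chest porcine infarct model:

* **HARP strain**: harmonic-phase estimation of circumferential strain
  (eC, % shortening; negative in systole) from SPAMM-tagged short-axis
  series;
* **mechanics**: per-segment peak eC and time-to-peak (TTP, ms from the
  QRS trigger), global strain, and the dyssynchrony index **SD16** — the
  sample SD of TTP over the 16 AHA segments;
* **LGE**: threshold-based quantification of late gadolinium enhancement,
  transmurality, and the segment classification
  *infarct* (enhanced fraction > 25% **and** |peak eC| < 10%),
  *peri-infarct* (3D-adjacent to an infarct segment), *normal* otherwise;
* **EAM**: local conduction velocity (CV) from tangent-plane fits of
  activation time, with voltage-based and ground-truth zone summaries;
* **morphometry**: Simpson volumes, EF, wall thickness, chamber diameters;
* **stats**: paired t, two-way repeated-measures ANOVA, OLS R², and
  inter-observer coefficient of variation, implemented from first
  principles (base-R `t.test`/`aov`/`lm` serve as independent oracles in
  the test suite).

Because the underlying animal recordings are not public, the package ships
a **synthetic phantom generator** whose presets encode the reference study
conditions at three time-points (baseline, ~10 d early post-MI, ~34 d late
post-MI).  Every estimator is validated by parameter recovery against the
phantom's ground truth and by analytic oracles.

## The phantom

### Geometry

Three short-axis slice levels (basal, mid, apical) of an annular LV, with
6 + 6 + 4 angular sectors forming the standard AHA 16-segment model (the
true apex cap is not modelled).  Endocardial radii are sized so Simpson
summation over the three 15 mm slabs reproduces the end-diastolic volume
targets (42 / 56 / 65 mL); normal wall thickness is 9 / 10 / 12 mm across
the time-points and the infarct wall thins to 6 / 5 mm post-MI.  A
consequence of the 3-slice design is that the early LVEDD implied by the
EDV target (~44 mm) overshoots the reference 40 mm; LVEDD is reported but
is not a validation target.

### Motion

Each segment receives an analytic strain time-course: a raised-cosine ramp
from the QRS trigger to its (negative) peak at TTP, then a raised-cosine
relaxation back to zero at end-cycle, shaped with exponent 0.7 so strain
stays high in early diastole (the curve is exactly periodic; "partial
relaxation" of the infarct tracings is mimicked by the shaping, not by a
non-zero end-cycle value).  Infarct segments additionally stretch early
(dyskinesis): a +5% sine lobe over the first 30% of the cycle, before a
shallow descent to the delayed peak.

The per-segment values are smoothed circularly (Gaussian, σ = 5°) into a
stretch field g(θ, t) that is smooth across segment boundaries; at segment
centres it equals the analytic curve to 1e-6.  The in-plane deformation is
an area-preserving annular map: angular positions redistribute as
∂θ/∂θ₀ = g/ḡ and radii follow
r² = (R_m ḡ)² + (r₀² − R_m²) ḡ/g, which preserves local wall area exactly
for any anchor radius R_m(θ₀).  The anchor is the **local** mid-wall
radius (endo + half the local wall thickness): under area preservation the
circumferential stretch varies strongly across the wall, and anchoring at
the normal-wall mid-radius would make the thin infarct wall's actual
mid-wall ~2 mm deeper than the anchor, rendering its strain 3–5 points
deeper than prescribed.  With the local anchor, the prescribed curve is
exactly what an ideal mid-wall ROI measures.

A deliberate consequence of exact in-plane area preservation at eC = −27%
is a baseline phantom EF near 72% rather than the physiological ~52%:
real hearts trade cavity volume against through-plane shortening, which is
out of scope here.  EDV targets are met to ±1 mL; EF is computed and
reported but is not a recovery target.

### Parameter draws

Per region (normal / peri-MI / infarct), peak-eC means and SDs come from
the reference tables (e.g. early post-MI: −24 ± 4 / −18 ± 2 / −6 ± 2 %).
Subjects draw a region-mean offset from the between-animal SD; segments
scatter around it at 40% of that SD.  TTP works differently: between-animal
variation is modelled as a **common timing offset** (SD 46 ms at baseline,
40 ms post-MI), because independent per-region draws would inflate the
within-subject TTP dispersion and hence SD16 far beyond its own target.
The within-subject segment scatter is then calibrated from the SD16 target:
σ_w = sqrt(max(SD16² − var(region means over the 16 segments), 0)),
giving 28 ms at baseline and ~10 / ~23 ms early / late post-MI.  This is
the one place where the "40% of region SD" rule is overridden — with it,
baseline SD16 would come out near 21 ms instead of 28 ms, contradicting
the dyssynchrony targets the presets must encode.

### Tagged images

A 1-1 SPAMM grid: intensity at current position x equals
mask(x, t) · Π_i [1 − c·cos²(k_i·p(x, t)/2)] plus Gaussian noise
(σ = 5% of the pattern amplitude), where p is the reference-position map
(the analytically inverted motion) and |k_i| = 2π / 6 mm.  96 × 96 pixels
of 1.25 mm, 20 frames over a 660 ms cycle, frame 1 = QRS with straight
grid-aligned tags.  Magnitude noise is Gaussian, not Rician — a documented
simplification.

### LGE volumes

Nine 5 mm slices (three per level) on the end-diastolic geometry.  The
enhanced region spans the infarct sectors from the endocardium to 95% of
the local wall thickness (all infarct segments transmural, ≥ 90%).  Its
angular extent is solved as an order statistic of per-voxel angular
margins so the voxelized enhanced fraction hits the preset target (21% /
20% of LV myocardial volume) within 1% absolute; with the thin infarct
wall this requires the wedge to spill a few degrees into the adjacent
border-zone sectors, which is intentional and keeps peri-MI segments
below the 25% classification threshold only jointly with their preserved
strain.  Enhanced and remote intensities are drawn 8 noise-SDs apart.

### Electroanatomic maps

Activation spreads from a basal anterior-septal source over the mid-wall
surface of revolution (arc-length parameterization, apical cap tapered),
solved with a first-order Godunov fast-sweeping eikonal solver written for
this package (no installed R package provides one).  The source is seeded
with closed-form times on a 6-cell disk — first-order point-source errors
otherwise originate at the source and propagate outward; with the disk the
flat-mesh solution matches distance/speed to ~1%.  Zone speeds are 39 /
18.7 / 5.7 cm/s (remote / border / infarct).  The border band extends the
infarct wedge by 30° and 15 mm, matching the study's definition of
peri-infarct regions as whole adjacent segments; 300 points are sampled
area-uniformly with 1.5 ms activation jitter and lognormal voltages whose
medians (3.5 / 0.9 / 0.25 mV) respect the 0.5 / 1.5 mV cutoffs.

## The estimators

### HARP strain

Per tag direction: 2D FFT, Gaussian band-pass at the known wave-vector,
inverse FFT, wrapped phase φ_i = k_i·p(x).  Wrapped finite differences
(each one-pixel difference re-wrapped to (−π, π]) give ∇φ_i without
unwrap-seam artifacts; stacking both directions yields the inverse
deformation gradient K⁻¹Y, the apparent circumferential stretch
λ = 1/|K⁻¹Y ê_c| (ê_c tangent to circles about the frame's myocardial
centroid), and eC = λ − 1.  Ill-conditioned pixels (condition number of Y
above 1e3) are masked.

Numerical choices that matter on this tag geometry (6 mm tags, 6–12 mm
walls), each verified on noise-free oracles:

* **bandwidth 0.35 |k|** (not 0.5 |k|): at 0.5 the DC and cross-harmonic
  leakage biases a uniform −27% phantom by ~4.5 strain points;
* **DC suppression**: the mask-shaped DC component (mask × its mean
  intensity) is subtracted before filtering — where the wall is about one
  tag period thick, the DC term's sinc-like spectral tails reach the
  passband and bias local phase gradients by up to 10%;
* **two-pass interference cancellation**: pass 2 subtracts the complete
  complex predicted interferent (DC, other-direction harmonic, cross
  product, own conjugate — reconstructed from pass-1 phases and the tag
  contrast) and re-centres the window on the actual spectral peak, since
  the harmonic moves away from the nominal wave-vector in proportion to
  strain;
* **ROI**: middle third of the wall between the frame's contours, with a
  6° sector-edge trim so band-pass blur does not leak a neighbour's
  strain; the ROI average is taken on the apparent frequency (1/λ) and
  inverted once — per-pixel inversion carries a Jensen bias toward
  spuriously deep strain wherever pixel noise is high;
* **reference calibration**: tags are applied at the QRS trigger, so each
  segment's apparent stretch is normalized by its frame-1 value (frame-1
  strain is exactly zero);
* **temporal smoothing**: a 1-2-1 filter (frame 1 untouched) before peak
  detection; without it the min-statistic over the infarct's flat trough
  is biased ~0.5 points deep by frame noise.  The filter slightly shifts
  the infarct trough's argmin toward its flatter (earlier) side, so
  early-cohort SD16 estimates scatter within roughly ±5 ms of truth from
  seed to seed.

Peaks are the most negative sample over the full cycle (infarct peaks fall
after aortic valve closure); TTP is the attaining frame's time, quantized
to the 33 ms frame interval with no sub-frame interpolation, ties to the
earliest frame.  SD16 uses the n−1 denominator and requires at least 14
usable segments.  Cohort statistics aggregate subject means, matching
small-cohort mean ± SD reporting.

### LGE quantification and classification

Threshold = mean + 5 SD of a remote-myocardium sample.  The remote sample
is chosen segment-wise: the brightest segment (mean intensity) locates the
infarct, and of the eight segments farthest from it in 3D (angular
distance plus a level penalty) the four dimmest are sampled — pure
distance-based selection can land in border-zone spill-over and inflate
the threshold.  Transmurality per 3° chord uses 1/r-weighted voxel counts,
an unbiased radial-length estimator on polar voxel grids; segments are
transmural at ≥ 0.90.  Classification applies the enhanced-fraction /
strain rule above, with quality-failed segments excluded and reported.
Whether "> 25% delayed enhancement" means volume or thickness fraction is
ambiguous in the source material; volume fraction is implemented.

### Conduction velocity

For each point, neighbours within 10 mm (≥ 5 required) are projected onto
the PCA tangent plane; a first-order polynomial of activation time over
the in-plane coordinates gives CV = 100/|∇LAT| cm/s.  Estimates are
rejected for near-zero gradients, velocities above 200 cm/s, absolute RMS
residuals above 15 ms, or **relative** residuals above 0.2 × the SD of the
fitted values.  The relative criterion is scale-invariant: a fixed
millisecond cutoff rejects curvature-dominated (near-source) fits in slow
tissue but passes the same geometry in fast tissue, which inflates
remote-zone means by ~9%.  Zone summaries default to ground-truth labels
on synthetic maps; voltage labels (0.5 / 1.5 mV) are available for real
data.

### Statistics

`paired_t`, `rm_anova` (classical within-subject decomposition, each
factor tested against its subject-interaction term, no sphericity
correction, incomplete subjects dropped listwise), `linreg_r2`, and
`interobserver_cov` (SD of paired differences over the grand mean; the
source's CoV formula is unstated, so the published 3% is treated as
qualitative).

## What the phantom does and does not show

Passing recovery tests demonstrates that the estimators are unbiased and
appropriately precise **under the phantom's assumptions**: 2D in-plane
motion, smooth annular geometry, Gaussian magnitude noise, no tag fading,
no breathing or arrhythmia artifacts, isotropic conduction, and a
well-circumscribed transmural infarct.  Real tagged CMR adds through-plane
motion, T1 tag fading, Rician noise and receive-coil shading; real EAM
adds catheter contact artifacts and fibre-direction anisotropy.  None of
these are modelled, so recovery here is a necessary, not sufficient,
validation for real data.

## Problem sizes

Default validation runs use 6-subject cohorts at 96 × 96 × 20 frames × 3
slices, 300-point EAM clouds on a 120 × 56 solver grid, and 9-slice LGE
volumes; the repeated-measures ANOVA null calibration uses 1000 simulated
6 × 3 × 3 designs, and the dyssynchrony power check runs 50 seeded
6-subject cohorts through the full tagged-image chain.

## Example

```{r example}
library(dyssync)
preset <- make_preset("early_post_mi")
cohort <- generate_cohort(preset, n_subjects = 6, seed = 1)
analysis <- analyze_cohort(cohort)
analysis$summary          # SD16, global eC, LGE %, zone CVs
analysis$recovery         # bias / RMSE against phantom ground truth
render_tables(list(early_post_mi = analysis))$table2
```
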