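# dyssync

Analysis of post-infarct left-ventricular **mechanical dyssynchrony** from
tagged cardiovascular MR, late-gadolinium-enhancement (LGE) imaging and
electroanatomic maps (EAM) — with a synthetic porcine-infarct phantom
generator so the whole measurement chain can be exercised and validated
without animal data.

## Who this is for

Cardiac imaging methodologists and electrophysiology researchers who need
a tested, reproducible implementation of the classic dyssynchrony
measurement chain: harmonic-phase (HARP) circumferential strain from
SPAMM-tagged short-axis series, segmental time-to-peak statistics, LGE
segment classification on the AHA 16-segment model, and conduction
velocity from catheter point clouds.

## The measurements

* **Circumferential strain eC(t)** per segment, from the phase of the
  band-passed first spectral harmonic of the tagged images: stacking the
  wrapped-phase gradients of two tag directions gives the inverse
  deformation gradient `K⁻¹Y`, and the apparent circumferential stretch is
  `λ = 1 / |K⁻¹Y ê_c|`, `eC = λ − 1`.
* **TTP**: time from the QRS trigger to the most negative eC;
  **SD16** = sample SD of TTP over the 16 AHA segments — the dyssynchrony
  index. Healthy ventricles sit near 28 ms; an anterior infarct roughly
  doubles it within the first week.
* **LGE**: enhanced fraction per segment against a remote-myocardium
  `mean + 5·SD` threshold, transmural extent per radial chord, and the
  segment classification *infarct* (enhancement > 25% **and**
  |peak eC| < 10%), *peri-infarct* (3D-adjacent), *normal*.
* **Conduction velocity**: per mapped point, a first-order fit of local
  activation time on the PCA tangent plane of its 10 mm neighbourhood;
  `CV = 100 / |∇LAT|` cm/s, with residual- and cap-based rejection.
* **Morphometry**: Simpson slice-summation volumes, EF, wall thickness,
  chamber diameters.
* **Statistics**: paired t, two-way repeated-measures ANOVA
  (within-subject error terms), OLS R², inter-observer CoV — implemented
  from first principles and cross-checked against base R in the tests.

The phantom generator (`make_preset`, `generate_cohort`) encodes the
study conditions of a closed-chest porcine LAD-occlusion model at three
time-points (pre-MI, early ~10 d, late ~34 d post-MI): regional peak
strain −27% → −6% in the infarct, TTP 300 → 440 ms, SD16 28 → 50 ms,
21% LGE with ≥ 90% transmurality, and zone conduction speeds
39 / 18.7 / 5.7 cm/s. See `vignettes/dyssync-methods.Rmd` for the model
and every estimator choice.

## Worked example

```r
library(dyssync)
preset   <- make_preset("early_post_mi")
cohort   <- generate_cohort(preset, n_subjects = 2, seed = 1)
analysis <- analyze_cohort(cohort)
round(analysis$summary, 2)
#>   n_subjects sd16_ms global_peak_ec_pct lge_pct ef_pct cv_infarct_cms cv_border_cms cv_remote_cms
#> 1          2   36.81             -17.79      21  49.03           6.04         19.38         37.31
analysis$regional
#>    region n_subjects peak_ec_mean peak_ec_sd ttp_mean    ttp_sd
#> 1  normal          2   -24.545114  0.1249661    374.0  7.778175
#> 2 peri_mi          2   -18.552700  1.3147923    374.0 23.334524
#> 3      mi          2    -6.499288  2.1730020    445.5 11.667262
```

Reading this: the two synthetic early post-MI subjects show the expected
picture — global strain degraded to −17.8%, infarct-labelled segments
barely contracting (−6.5%) and peaking ~70 ms after the normal wall
(445 vs 374 ms), 21% of the LV myocardium enhanced, and conduction in the
infarct at ~6 cm/s versus ~37 cm/s remotely. `analysis$recovery` reports
bias and RMSE of every estimate against the phantom's ground truth, and

```r
ef(42, 20)
#> [1] 52.38095
```

is the baseline ejection fraction from end-diastolic/systolic volumes of
42/20 mL.

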