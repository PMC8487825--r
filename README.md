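# sonovas

Lower-extremity arterial ultrasound image processing and cohort analysis
in R.

Duplex ultrasound is the workhorse non-invasive exam for peripheral
arterial disease: B-mode images give intima-media thickness (IMT), plaque
and lumen geometry; spectral Doppler gives the hemodynamic indices PSV, RI
and PI. The images are degraded by speckle, and the clinical read-out runs
through a fixed set of measurement rules and group statistics. `sonovas`
implements that whole computational chain as a tested, reusable pipeline
for imaging researchers and biostatisticians:

* **Non-local means denoising** with a Gaussian-weighted patch distance,
  exponential kernel and restricted search window:
  `NL(Y)(p) = Σ_q w(p,q) Y(q)` with
  `w(p,q) = exp(−d(p,q)/h²) / Z(p)` and
  `d(p,q) = Σ_o G(o) (Y(p+o) − Y(q+o))²`.
* **Texture features**: block mean/variance and the gray-level
  co-occurrence matrix (GLCM) descriptors contrast, entropy, correlation
  and energy over distances `d` and angles 0°/45°/90°/135°.
* **Vessel metrics**: triplicate and bilateral averaging; IMT ≤ 0.9 mm
  normal vs thickened; plaque call strictly above 1.2 mm wall thickening;
  stenosis rate `(d₂ − d₁)/d₂ × 100 %`; ordinal grades 0 (< 1 %),
  I [1, 20), II [20, 50), III [50, 100), IV (occlusion, no flow); and
  worst-lesion reduction per segment.
* **Cohort statistics**: mean ± SD summaries, one-way ANOVA, Pearson
  chi-square incidence tests, per-segment incidence tables for three
  groups (A healthy, B diabetic foot, C diabetic foot + arteriosclerosis
  obliterans).
* **Synthetic data**: speckle-corrupted vessel phantoms with known ground
  truth, and cohort simulation calibrated so that grade ≥ I prevalence is
  71 % (group C) / 19 % (group B) and grade ≥ II is 30 % / 13.1 % — the
  published group contrasts — making the full pipeline testable without
  any clinical data.

## Worked example

```r
library(sonovas)

## a phantom with one plaque protruding 3 mm into a 6 mm lumen
ph    <- generate_phantom(phantom_spec(plaques = list(
           list(center_x = 6.4, length = 3, protrusion = 3, echo_level = 210))))
noisy <- add_speckle(ph$image, noise_params(speckle_shape = 10,
                                            gaussian_sigma = 4, seed = 2))
den   <- denoise_nlmeans(noisy, nlm_params(h = 30))

ph$geometry$plaques[[1]][c("d1", "d2")]        # true 3 mm / 6 mm
grade_stenosis(stenosis_rate(3, 6))            # III

## a calibrated cohort, annotated by the measurement rules
coh <- generate_cohort(default_cohort_preset(), n_per_group = 30, seed = 1)
ann <- annotate_cohort(coh)
incidence_table(coh, "grade_ge_I")$tests$all
anova_oneway(ann$imt_bilateral_mm[ann$segment == "femoral"],
             ann$group[ann$segment == "femoral"], "femoral IMT")
```

prints (numbers from this exact run):

```
true d1/d2: 3.0 / 6.0 mm -> stenosis 50% (grade III)
residual variance vs clean: noisy 625.0 -> denoised 273.4
group A: grade>=I 2.0%, thickened IMT 0.7%
group B: grade>=I 24.3%, thickened IMT 83.3%
group C: grade>=I 67.3%, thickened IMT 98.0%
grade_ge_I:all: X-squared = 308.1, df = 2, p = 1.247e-67 (significant at 0.05)
femoral IMT: F = 443, df = 2, 177, p = 1.258e-69 (significant at 0.05)
```

i.e. the denoiser halves the residual variance against the clean phantom,
the simulated severity gradient A < B < C is recovered by the grading
rules, and the group contrasts are highly significant at n = 30/group —
the behaviour expected of this clinical protocol.

`run_full_demo("demo/", seed = 7)` chains every stage (phantom → speckle →
denoise → texture CSV → cohort → analysis report) and logs the resolved
configuration and seeds beside the outputs; a thin command-line front end
with the same subcommands ships in `inst/scripts/sonovas`. The methods
vignette (`vignettes/sonovas-methods.Rmd`) documents the model, parameter
meanings, defaults and limitations.

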