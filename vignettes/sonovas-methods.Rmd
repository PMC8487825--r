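---
title: "Methods: speckle denoising, texture features and cohort metrics in sonovas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speckle denoising, texture features and cohort metrics in sonovas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonovas)
```

## Scope

sonovas implements the computational chain used in duplex ultrasound
assessment of lower-extremity peripheral arterial disease: speckle
denoising of B-mode images by non-local means, block/GLCM texture
description, the standard clinical vessel metrics (IMT classification,
plaque calling, percent-diameter stenosis with ordinal grading), and a
three-group comparison layer (healthy controls A, diabetic-foot patients B,
diabetic foot with arteriosclerosis obliterans C). Clinical images and
patient tables of this kind are generally not shareable, so the package
also ships a synthetic-data module — vessel phantoms with known ground
truth and cohort simulation calibrated to published group contrasts — that
makes every stage testable end to end.

## Non-local means denoising

The denoiser replaces each pixel $p$ of the image $Y$ with a convex
combination over a restricted search window $W(p)$ of half-width
$R_\text{search}$:

$$\mathrm{NL}(Y)(p) = \sum_{q \in W(p)} w(p,q)\, Y(q), \qquad
  w(p,q) = \frac{1}{Z(p)} \exp\!\left(-\frac{d(p,q)}{h^2}\right),$$

with $Z(p)$ normalizing the weights to sum to one and

$$d(p,q) = \sum_{o} G(o)\,\bigl(Y(p+o) - Y(q+o)\bigr)^2$$

a Gaussian-weighted squared distance between the patches around $p$ and
$q$ (offsets $o$ range over a $(2r+1)^2$ patch). Weights therefore lie in
$[0,1]$ and sum to 1, the output lies inside the input's range, and a
constant image is an exact fixed point — all of which the test suite
asserts, along with equivalence to a brute-force triple-loop reference on
small images.

Numerical and design choices:

* **Patch Gaussian normalized to sum 1.** This decouples the scale of $h$
  from the patch size: $d(p,q)$ is a weighted *mean* squared difference in
  gray-units², so $h$ is always expressed in gray units.
* **Self-weight.** The centre pixel receives its natural kernel weight
  $\exp(0)$; the common variant that caps it at the maximum of the other
  weights is available (`self_weight = "max_others"`) but off by default,
  the natural reading being the simpler one.
* **Borders.** Patches are completed by symmetric (edge-repeating)
  reflection; search windows are clipped at the image boundary, so border
  weight maps normalize over fewer pixels rather than over padded values.
* **Defaults** (`h` = 10 gray units, patch radius 2, search radius 10,
  patch-Gaussian σ = 1 px) are implementation choices: no reference values
  exist for this acquisition setting, and no cleaned-image quality figure
  is available to tune against. Denoising quality is therefore validated
  by properties (variance reduction on speckled flat phantoms, mean
  preservation, monotone smoothing in $h$), not by a target number.
* **Complexity.** The implementation vectorises over window offsets
  ($O((2R+1)^2\, (2r+1)\, MN)$ with separable patch convolution), which is
  exact — not an approximation — and keeps 128×128 images around a second
  in pure R.

## Texture features

Images are partitioned into non-overlapping $L \times L$ blocks (row-major,
partial tiles dropped). Per block the first-order statistics are the gray
mean $\bar y_k = L^{-2}\sum_{i,j} y_k(i,j)$ and the population variance
$\sigma^2(y_k) = L^{-2}\sum_{i,j}(y_k(i,j)-\bar y_k)^2$ (divisor $L^2$,
asserted against hand-computed cases).

The gray-level co-occurrence matrix $P_{\theta,d}$ counts ordered pixel
pairs at displacement $d$ along $\theta \in \{0°,45°,90°,135°\}$ after
uniform quantization of $[0,255]$ into $N_g$ bins, and is normalized by the
total pair count $R$. From the normalized matrix the package computes the
four classic Haralick descriptors:

* contrast $\mathrm{CON} = \sum (g_1-g_2)^2 P(g_1,g_2)$,
* entropy $\mathrm{ENT} = -\sum P \log_2 P$ (base 2; the base is a
  convention choice, stated here because it rescales ENT),
* correlation $\mathrm{COR} = (\sum g_1 g_2 P - \mu_1\mu_2)/(\sigma_1\sigma_2)$
  with marginal moments of the normalized matrix,
* energy $\mathrm{ENG} = \sum P^2$.

Three printed-equation corrections are deliberate: the block *mean* is the
arithmetic mean (the variance expression cannot define a mean); contrast is
the standard quadratic form in the co-occurrence cells; and energy is
positive (a negative "energy" contradicts its meaning as a uniformity
measure — the literal sign is available via `paper_literal = TRUE` for
auditability). The GLCM is ordered by default, matching the ordered-pair
definition; `symmetric = TRUE` adds the transpose. Correlation is undefined
on constant regions (zero marginal SD); the package raises a classed error
there and feature tables report `NA`. Defaults $N_g = 8$, $d = 1$, $L = 32$
are implementation choices. All features are verified against independent
brute-force pair enumeration across $d \in \{1,2\}$, the four angles and
$N_g \in \{4,8\}$.

## Vessel metrics

The clinical rules are implemented exactly as printed in the source
protocol and asserted at their boundaries:

* each index is measured three times and averaged; IMT is additionally
  averaged over left and right sides per segment;
* IMT ≤ 0.9 mm is normal, strictly above 0.9 mm thickened;
* plaque is called when localized or diffuse wall thickening strictly
  exceeds 1.2 mm (both modes share the threshold; the mode is carried
  through for transparency);
* stenosis rate $= (d_2 - d_1)/d_2 \times 100\%$ with $d_1$ the residual
  and $d_2$ the original lumen diameter;
* grades: 0 below 1%, I in $[1,20)$, II in $[20,50)$, III in $[50,100)$,
  IV at 100% with absent flow. The printed integer ranges (1–19, 20–49,
  50–99) leave non-integer gaps; the half-open bins preserve every printed
  anchor while making the map total over real-valued rates, and the test
  suite audits the partition at 0.01% resolution. A 100% diameter
  reduction with a recorded flow signal is flagged as a data inconsistency
  rather than silently graded.
* when a segment holds several lesions the most severe grade prevails.

## Synthetic data

**Phantom.** A longitudinal straight-vessel scene: background, two wall
bands of thickness IMT, a lumen of diameter $d_2$, and plaques rendered as
protrusions from the near wall; the label map and a JSON sidecar record the
true geometry, including $d_1 = d_2 - \text{protrusion}$ per plaque. Pixel
$(i,j)$ is row-major from the top-left with the pixel centre at
$(i-\tfrac12)\cdot\text{pixel\_size}$ mm. Noise is unit-mean multiplicative
gamma (shape $k$: mean 1, variance $1/k$) times the clean intensity plus
additive Gaussian noise, clipped to $[0,255]$ — a standard surrogate for
fully-developed ultrasound speckle. It does **not** model the physics of
B-mode formation (point-spread function, beamforming, attenuation,
log-compression correlation structure), so passing tests demonstrate
algorithmic correctness and calibrated behaviour on controlled input, not
clinical performance on real scans.

**Cohort.** Thirty subjects per group by default, each with 5 anatomical
segments × 2 sides. The preset's published anchors are the demographics
(ages 65.1 ± 6.8 / 66.2 ± 5.4 / 64.2 ± 5.9 y; 16/18/17 males of 30; smoker
proportions 16/15.1/15.3%; TC ≈ 4.6 mmol/L in all groups) and the
stenosis-prevalence masses: grade ≥ I in 71% (C) and 19% (B), grade ≥ II
in 30% (C) and 13.1% (B). Everything else — per-segment IMT means, plaque
probabilities, lumen diameters, PSV/RI/PI levels, and the split of the
≥ II mass across II/III/IV — is an invented default chosen for clinical
plausibility and flagged as such in the shipped configuration.

Design decisions worth recording:

* **Grade-consistent diameter sampling.** The grade is drawn first, then
  the stenosis rate uniformly inside that grade's interval (with a 10⁻⁶
  inset at open upper edges so floating-point round-trip can never cross a
  boundary; grade IV forces rate 100 and absent flow), then
  $d_1 = d_2(1-\text{rate}/100)$. Re-grading the stored $(d_1, d_2)$
  therefore recovers the drawn grade exactly, which the tests check
  exhaustively.
* **Uniform grade probabilities across segments.** Only group-aggregate
  prevalences are published, so a per-segment severity gradient would not
  be identifiable; the same vector is used for all five segments of a
  group.
* **Independent plaque and grade draws.** Keeps both marginal calibrations
  exact at the cost of ignoring their clinical correlation.
* **Occlusions carry no flow**: grade-IV segments get PSV = RI = PI = 0.
* **Two source discrepancies are documented, not resolved**: the group-C
  triglyceride entry (4.07 ± 1.19) contradicts the accompanying claim of
  no demographic differences, so the preset uses ≈ 2.07 matching A/B; and
  the narrative is internally inconsistent about whether group B or C
  shows the larger PSV/RI/PI decrease, so the preset orders the groups
  severity-consistently (A > B > C).
* The per-group demographic counts are used rather than the conflicting
  whole-sample aggregate (62 ± 6.5 y, 44 M/46 F).

## Cohort statistics

Summaries are mean ± sample SD ($n-1$ divisor, the convention behind
"x̄ ± s" reporting). Continuous measures are compared by classic one-way
ANOVA ($F = MS_\text{between}/MS_\text{within}$, df $(k-1, N-k)$, via
`stats::lm`), incidence counts by Pearson's chi-square without continuity
correction (the Yates-corrected variant is a flag); both are verified
against explicit textbook-formula oracles to 10⁻⁹ and hold their nominal
5% size in null simulations within 3 binomial standard errors at 2000
replicates. No multiplicity adjustment is applied to group contrasts,
matching the source's apparent practice; a Bonferroni flag would be a
one-line extension. Incidence tables keep exact rational counts
(affected/total) per group × segment before any formatting.

## Problem sizes and reproducibility

The shipped defaults keep every computation at desk scale: phantoms of
128×128 px (denoised in ≈ 1 s in pure R), oracle comparisons on images up
to 9×9, calibration checks on 3000 segments per group (300 subjects × 10
segments), and 2000-replicate null simulations — sizes chosen so that the
full suite and the acceptance script each run in well under a minute to a
few minutes while leaving the binomial/Monte-Carlo error comfortably inside
the stated tolerances. One master seed derives per-stage seeds through a
stated splitting rule (`derive_stage_seed`), so stages can be re-run
independently; every pipeline run logs its fully resolved configuration
and seeds beside its outputs, and identical configuration yields
byte-identical artifacts.

## Known limitations

* The speckle surrogate is statistically, not physically, motivated;
  texture features measured on it should not be read as clinical norms.
* IMT and diameters come from ground-truth geometry or simulated tables,
  not from automated image measurement — lesion segmentation on the
  denoised images is out of scope.
* The cohort simulator draws segments independently within subject; real
  atherosclerosis is spatially correlated, so simulated between-subject
  variance is lower than clinical variance at equal $n$.
* The grading of a 100% reduction requires the flow flag; the package has
  no Doppler model and simply treats the flag as data.
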