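---
title: "Methods: radiobiological QC of clinical ion beams with ionbeamqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiobiological QC of clinical ion beams with ionbeamqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionbeamqc)
```

# Scope

`ionbeamqc` implements the analysis chain used to verify, biologically and
biophysically, that a clinical particle beam delivers what it promises:

1. clonogenic survival fitting and relative biological effectiveness (RBE)
   at an isosurvival level;
2. Poisson statistics of intranuclear ion hits from the particle fluence
   and the nuclear cross-sectional area distribution;
3. read-out of a fluorescent nuclear track detector (FNTD) plane: spot
   detection, conversion of spot intensity to an avalanche-photo-diode
   count rate, and primary/fragment classification;
4. nucleus segmentation, gamma-H2AX focus quantification, repair kinetics
   and correlation of focus metrics with survival;
5. registration of the detector plane to the cell layer by a single global
   translation and one-to-one track/focus pairing.

Every stage consumes inputs that the `generate_*` family can simulate with
known ground truth, so the whole chain is testable without microscope or
beam-line data.

# Survival models and RBE

Clonogenic surviving fraction is modelled as
$\mathrm{SF}(D) = \exp(-\alpha D - \beta D^2)$ (linear-quadratic, LQ), with
the pure linear special case $\beta = 0$ (L) that describes ion-beam data
over the clinical dose range. Fits are weighted least squares on
$\ln \mathrm{SF}$, which is linear in $(\alpha, \beta)$.

Two statistical choices deserve explanation because they are not forced by
the model:

* **A free intercept.** All surviving fractions in one dataset are
  normalised by the same 0 Gy control mean. That shared normalisation
  error correlates the residuals; a fit through the origin then understates
  the parameter errors badly (in simulation, nominal 2-SE coverage of
  $\alpha$ dropped to 0.67–0.79). Fitting
  $\ln \mathrm{SF} = c - \alpha D - \beta D^2$ treats the plating
  efficiency as a nuisance parameter, restoring coverage to 0.93–0.94.
  The survival curve itself remains anchored at $\mathrm{SF}(0) = 1$.
* **Per-dose mean-count weights.** Under Poisson counting noise,
  $\mathrm{Var}(\ln \mathrm{SF}) \approx 1/\text{colonies}$. Weighting by
  each well's *observed* count lets the noise choose its own weight and
  biases the fit; the per-dose mean count is used instead when counts are
  available, equal weights otherwise.

$\beta \ge 0$ is enforced by refitting at the boundary with a flag. Model
choice between L and LQ is a nested F-test at $p < 0.05$; a boundary
$\beta$ counts as no improvement. Wells with zero surviving colonies are
replaced by half a colony so the log transform stays finite.

The isosurvival dose solves $\beta D^2 + \alpha D + \ln s = 0$
analytically, and RBE at level $s$ (default 0.30) is the ratio of the
reference (photon) to the test dose, with a first-order delta-method
uncertainty from the full parameter covariances, the two fits treated as
independent. From the published photon fit
($\alpha = 0.173$/Gy, $\beta = 0.032$/Gy²) and ion slopes
0.332/0.521/0.809/1.041 /Gy this chain returns RBE₃₀ of 1.1, 1.7, 2.7 and
3.5:

```{r rbe}
photon <- survival_fit(0.173, 0.032, alpha_se = 0.026, beta_se = 0.004)
sapply(c(0.332, 0.521, 0.809, 1.041),
       function(a) round(rbe_at_survival(photon, survival_fit(a))$rbe, 1))
```

# Intranuclear hit statistics

A nucleus of cross-sectional area $A$ (μm²) under fluence $\Phi$
(particles/cm²) receives on average $\lambda = \Phi A \times 10^{-8}$
primary hits. Over a sample of areas the hit-count law is the equal-weight
Poisson mixture $P(k) = \frac{1}{n}\sum_i \mathrm{Pois}(k;\lambda_i)$,
whose mean is exactly $\Phi\,\overline{A}$ and whose variance is
$\Phi \overline{A} + \Phi^2 \mathrm{Var}(A)$ (law of total variance).
These identities, the normalisation of the truncated pmf (auto tail mass
$< 10^{-9}$), and the convergence of the Monte-Carlo sampler are the
testable surface of this module.

The area generator is log-normal, parameterised by mean and coefficient of
variation. Defaults: mean 89.5 μm², CV 0.3, n = 1239. The mean is a
calibration: at the carbon-beam fluence $3.8\times 10^6$/cm² it gives
$\Phi \overline A = 3.40$ expected hits, the value transport simulations
report for a mid-SOBP clinical carbon field; the measured reference values
(3.2 ± 0.3 carbon, 2.2 ± 0.2 oxygen) are not reproducible on a desk
because the underlying area sample and detector images are unpublished.
The histogram comparison (`compare_hit_histograms`) reports mean ± SEM on
both sides — the model SEM computed for the same nucleus count — and a
chi-square over bins pooled to expected counts ≥ 5.

# FNTD read-out

The detector records one fluorescent spot per ion traversal; spot
intensity encodes energy deposition, so the count-rate histogram is
bimodal: bright primaries (plus indistinguishable heavy projectile-like
fragments) and dim light fragments. The read-out geometry is a
212.55 × 212.55 μm² plane at 1800 × 1800 pixels with 7.2 μs dwell time;
peak photon counts divided by the dwell time give MHz count rates, and the
clinical operating thresholds are 5.3 MHz (carbon) and 4.4 MHz (oxygen).

Detection enhances spots with a white top-hat (disc radius 3 px), then
smooths with a Gaussian of $\sigma$ = 1 px before thresholding. The
smoothing matters: with 0.3 μm spots the 3-px top-hat kernel halves the
spot contrast, and a plain robust 4-SD threshold on the unsmoothed image
loses about half of the fragment class at SNR 10. The working threshold is
`median + 2.5 × MAD`, deliberately permissive; a second, independent
quality cut — a least-squares Gaussian amplitude of at least 3.5 × the raw
noise MAD — controls false positives. One matching-pursuit round
(fit, subtract, re-detect, vetting candidates on the residual image)
recovers the partner of close spot pairs, about 5% of spots at clinical
fluence. On the stated synthetic world this gives recall 0.96–0.97 and
precision 0.98–0.99 with sub-0.5-pixel centroids.

Count rates come from the fitted Gaussian amplitude rather than a single
raw pixel maximum. The raw read carries ±0.9 MHz of pixel noise plus a
positive bias, which smears the class gap and caps classification accuracy
near 95%; the fitted amplitude is unbiased with ≈0.25 MHz error, giving
≈98.5% accuracy at the default 5-SD class separation. The raw maximum is
still reported (`peak`) for users who want the legacy reading.

`histogram_threshold` supplies a data-driven split when no operating value
is given: Otsu's criterion when it falls in a genuine density valley, and
otherwise the midpoint of the two component means of a 1D two-Gaussian EM
fit. The midpoint is insensitive to class weights — important because
clinical mid-SOBP fields are >90% primaries, which drags both Otsu and
kernel-density valleys toward the dominant mode.

# Nuclei and gamma-H2AX foci

Nucleus segmentation follows the standard automated recipe: per-plane
rolling-ball style background subtraction (implemented as a grayscale
opening), maximum-intensity projection, median filter, global Otsu
threshold, and a marker-based watershed on the Euclidean distance
transform to split touching nuclei, followed by an area filter
(default ≥ 25 μm²). Watershed seeds are distance-map maxima merged within
~4 μm so near-circular nuclei stay whole. Measured disc areas are within
5% of $\pi r^2$; nuclei touching the border are flagged.

Focus detection projects the central planes of the damage channel,
smooths lightly ($\sigma$ = 0.8 px), and thresholds **per nucleus** at
`median + 5 × MAD` of the in-nucleus signal. A mean + 3 SD rule fails
here for a structural reason: the foci themselves inflate the mean and SD,
so nuclei with several bright foci raise their own threshold until
detections vanish. The median/MAD rule is robust to that contamination and
still scale-invariant, so focus counts are unchanged under uniform
intensity rescaling. Touching foci are split at local maxima.

Focus *size* is reported as the physical half-maximum area
$2\pi \ln 2\,(\sigma_f^2 - \sigma_{sm}^2)$ from a fitted Gaussian width,
deconvolved for the smoothing kernel. A thresholded pixel count depends on
the threshold rule and inflates small foci under noise; the fitted width
reproduces the expected ×4 area scaling between 0.4 and 0.8 μm foci
(measured ratios 3.9–4.1).

QC before statistics: `pan_stained` when more than 40% of the nucleus
exceeds the global focus-channel background level (such nuclei cannot be
scored focus-by-focus), `apoptotic` when area < 25 μm² or solidity < 0.7,
`border` for edge nuclei. Focus statistics subtract a spontaneous
background of 0.16 foci/nucleus (a low-background cell line), floored at
zero with a flag. Repair kinetics divide background-corrected means by the
0.5 h baseline; the generator's residual-fraction defaults (0.023 photons,
0.153 carbon, 0.176 oxygen) are recovered within ±0.03 at 150 nuclei per
timepoint. The survival correlation stage is ordinary least squares of
surviving fraction on a focus metric with Pearson $R^2$; on generator data
whose focus counts rise with LET while survival falls it reports a
negative slope with $R^2 > 0.9$. The published per-condition values behind
the reference correlation coefficients are not printed anywhere, so only
this direction-and-magnitude property is checkable.

# Registration

The cell layer moves a few μm between detector irradiation and microscope
read-out, offsetting every track/focus pair by one common vector (~3 μm in
clinical data). `estimate_translation` takes the component-wise median of
nearest-neighbour displacements within a search radius, iterates twice,
then polishes with the mean over inliers (within 3 × the median absolute
residual) — the median is robust but statistically inefficient once
outliers are excluded; the polish brings the worst-case axis error under
0.15 μm at jitter $\sigma$ = 0.3 μm with 20% outliers. Noise-free shifts
are recovered exactly. A reliability flag compares the inlier count with
the chance level expected from unrelated point sets; fields where few
tracks produced foci should pass only intranuclear spots. Pairing is
greedy one-to-one nearest-neighbour in ascending separation with a 5 μm
cut-off (the ~3 μm offset plus focus-position uncertainty); rotation and
scaling are deliberately out of scope, and an optimal bipartite assignment
would be a drop-in refinement if ever needed.

# The synthetic world — what it does and does not establish

The generators emulate: LQ/L survival with Poisson colony noise in
triplicate (doses 0, 0.25, 1, 2, 4 Gy; 500 cells/well; plating efficiency
0.5); log-normal nuclear areas (89.5 μm², CV 0.3); uniform spot placement
at clinical fluences with Gaussian spots ($\sigma$ = 0.3 μm) and Gaussian
count-rate mixtures (carbon-like 6.8 ± 0.6 vs 3.8 ± 0.6 MHz, 8% fragments,
so the class-mean midpoint sits at the 5.3 MHz operating threshold;
oxygen-like 5.6/3.2 ± 0.5 MHz); ellipse nuclei (eccentricity uniform in
[0, 0.6], non-overlapping placement by rejection sampling with 1000
retries); foci at translated track positions with 0.2 μm jitter plus
Poisson background at 0.16/nucleus; and first-order repair with a
non-repairable residual component. Where a value had to be chosen without
a stated reference (repair half-life 6 h, focus amplitude/SNR 10, 5-plane
stacks at 0.322 μm/px) it was chosen once as a realistic wide-field
scoring geometry and not revisited.

The generators do **not** simulate track structure (no delta rays, no
radial dose), detector physics (colour-centre response, read-out
saturation), chromatic or stage drift beyond a rigid translation,
focus substructure, or cell-cycle heterogeneity. A green test therefore
establishes that the *analysis* recovers known ground truth under
realistic noise — not that the generators reproduce every property of real
microscope data.

# Numerical choices and limitations

* Images are plain numeric matrices; the I/O layer uses ASCII PGM with a
  JSON metadata sidecar and CSV object tables, because the target
  environment has no TIFF library. All heavy pixel operations (morphology,
  EDT, watershed, labelling, convolution) are compiled.
* Pixel convention: 0-based indices, positions at pixel centres
  ((j + 0.5) × pixel size), x right, y down.
* The mixture pmf is truncated at the smallest K with tail mass < 1e-9;
  ties in Otsu's criterion across an empty histogram gap resolve to the
  gap centre; EM for the rate mixture is quantile-initialised and runs to
  a 1e-8 mean tolerance.
* Spot detection's amplitude grid (0.8–4.5 px) covers the physical spot
  widths; the focus width fit is continuous (golden-section on the profile
  RSS).
* Runtime: a full 1800² read-out chain takes ~30 s on one core; unit tests
  use smaller fields.
* Known limitations: no 3D focus segmentation or multi-plane track
  trajectory fitting (tilted irradiation); per-field (not per-nucleus)
  translation; greedy rather than optimal pairing; survival fits assume
  log-normal-ish residuals after the Poisson-motivated weighting rather
  than fitting a full counting GLM.
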