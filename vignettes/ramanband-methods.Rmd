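---
title: "Raman band image separation and tissue classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Raman band image separation and tissue classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanband)
```

## The measurement model

Under 785 nm excitation, tissue emits broadband near-infrared
autofluorescence (AF) one to two orders of magnitude stronger than Raman
scattering. Wide-field imaging through a narrow passband centered on a
Raman band therefore measures Raman + AF; a second image through a
passband shifted off the Raman band measures AF alone. `ramanband`
models four calibrated filter windows (50% transmittance limits, fixed
constants of the instrument model):

| band | signal window | AF window |
|------|---------------|-----------|
| 1437 cm⁻¹ | '0-R', 1365–1455 cm⁻¹ | 'R-R', 1358–1418 cm⁻¹ |
| 1655 cm⁻¹ | 'R-0', 1625–1715 cm⁻¹ | '0-0', 1651–1716 cm⁻¹ |

The filter-position labels encode which of the two stacked filters is
rotated (R) or not (0). Because the two windows transmit different
amounts of AF, the AF-position image must be rescaled by a multiplicator
constant $k > 0$ before subtraction. $k$ cannot be fixed per tissue type
(it varies strongly between samples), so it is estimated per sample from
a spectral measurement: the separation chooses $k$ so the image-domain
ratio of mean AF to mean Raman intensity equals the spectrally measured
ratio $r$,

$$\frac{\operatorname{mean}(kB)}{\operatorname{mean}(A - kB)} = r
\quad\Longrightarrow\quad
k = \frac{r\,\operatorname{mean}(A)}{\operatorname{mean}(B)\,(1+r)},$$

with $A$ the signal-position and $B$ the AF-position image. The fixed
point is unique and analytic; a bisection solver (the automated analogue
of manually re-applying $k$ until the ratios match) is run as a
cross-check and must agree with the closed form to $10^{-6}$ relative.
The target $r$ is the ratio of the AF and Raman band integrals of the
decomposed spectrum over the band's signal window
(`spectral_target_ratio()`); the point ratio at the band center
(`af_raman_ratio()`) is reported separately for group comparisons.
Whether the spectral ratio should be integral-based or point-based is
genuinely open; the integral is consistent with what the band images
physically measure, which is why separation uses it.

Negative pixels after subtraction are clamped to zero (Raman intensity
is physically nonnegative); the clamped fraction is logged per sample
because it is the key diagnostic of a mis-estimated $k$. The achieved
ratio is recomputed from unclamped means, so
$A = \text{raman}_{\text{unclamped}} + kB$ holds exactly. The mean
ratio is computed over the full frame by default, with an optional mask
argument; a single spatially uniform $k$ is assumed (the phantom
generator enforces it by construction; violations in real data would
appear as structured residuals, which the package quantifies but does
not correct).

## Baseline decomposition

Each single-point spectrum (1200–1800 cm⁻¹) is split into AF continuum
plus Raman component by an iterative peak-suppressing polynomial fit:
fit a polynomial of order $p$, clip the working trace at the fit, refit
until the maximum change falls below $10^{-7}$ of the input maximum
(cap 1000 iterations; non-convergence raises a warning). The tight
tolerance matters: with AF ~100× the peaks, a tolerance of $10^{-4}$ of
the input maximum is of the order of a peak height and leaves ~10%
peak-height bias.

The order is selected from 9–16 as the lowest order whose converged fit
clips off nearly the least total intensity mass (within 5% of the
minimum). A good baseline clips only the peaks; under-fitting orders
also clip continuum regions (large clipped mass), while over-fitting
orders gain only marginal mass by wiggling into peak flanks — the 5%
slack sends those near-ties to the smoother fit. A final peak-masked
refit (passes excluding points more than 3, 2, then 1.5 estimated noise
sigma above the running fit, with a mask-collapse guard) removes the
small downward bias clipping leaves under broad peaks; the noise sigma
is estimated robustly from second differences. The decomposition is
exactly additive, and the AF trace is clamped at zero.

Intensity "at a wavenumber" is the nearest grid sample, matching
discrete spectrograph pixels; at ~1 cm⁻¹ sampling the difference from
interpolation is negligible.

## The phantom generator

No public imaging data exist for this problem, so validation rests on a
synthetic generator whose defaults define the study conditions:

* **Spectra.** Gaussian peaks at 1239, 1301, 1315, 1342, 1437, 1490,
  1552, 1602, 1628, 1655 and 1745 cm⁻¹ (lipid/protein CH modes, amide
  bands, guanine, tryptophan, phenylalanine, formalin, lipids) on a
  1 cm⁻¹ grid. FWHMs of 10–18 cm⁻¹ were chosen so adjacent listed bands
  (1628/1655, 1301/1315) are resolved, as they are in formalin-fixed
  tissue spectra at sub-nm spectral resolution; the 1437 band is the
  broadest and most intense. Class amplitudes make the mast cell tumor
  (MCT) spectrum strongest and soft tissue sarcoma (STS) weakest.
* **AF continuum.** $\text{af}(\nu) = L\,e^{-d(\nu - 1437) + q(\nu)}$
  with level $L$ 16–42 a.u. (10–100× the Raman amplitudes; STS the
  strongest emitter), decay $d$ 0.006–0.012 cm, and $q$ a random
  low-order polynomial (orders 2–5) in the log domain whose slope is
  capped at 60% of $d$, so the continuum is strictly decreasing toward
  higher wavenumbers yet is not a pure exponential — the polynomial
  baseline stage has realistic work to do.
* **Images.** 256 × 256 px for a 1.4 cm field by default. Pixel value =
  illumination × texture × band integral, with a smooth unit-mean
  Gaussian vignette for non-uniform illumination and a Gaussian random
  field texture (class-specific correlation length 6–14 px and
  amplitude 0.12–0.20) shared between the two filter positions of a
  band. The AF-position image carries an instrument gain drawn so the
  true $k$ is uniform on [0.5, 2]. Detector noise is additive Gaussian
  with sigma $2\times10^{-4}$ of the image mean — the regime of a
  cooled, high-gain camera integrating for seconds, where the noise
  floor sits well below the Raman band signal (a prerequisite for
  subtracting two AF-dominated images at all). Spectral noise defaults
  to 0.02 a.u. (peak SNR ≈ 35–50).
* **Ground truth.** Every sample stores its noise-free Raman/AF traces,
  component images, band integrals, gain and true $k$, enabling direct
  recovery tests.

What the phantoms deliberately do not model: detector physics (EMCCD
gain/readout statistics), formalin-fixation chemistry, spatially varying
true $k$, wavelength-dependent filter transmittance shapes (windows are
ideal boxes at the 50% limits), and co-registration error between filter
positions. Passing tests therefore demonstrate the correctness and
calibration of the *algorithms* under the stated statistical structure,
not instrument-level performance on real tissue.

## Texture features and classification protocol

Twenty patches per image are registered by uniform random translation
plus rotations restricted to multiples of 90° (interpolation would alter
texture statistics). The patch side maps the nominal 1 cm² patch area
into pixels (`round(image_px / field_cm)`), so patches from a 1.4 cm
field overlap heavily — accepted, since twenty 1 cm patches cannot
otherwise fit; transforms are shared across the four image types of a
sample so patches are spatially matched across modalities.

GLCM features use 8 gray levels, distance 1, four angles averaged, and a
symmetric normalized matrix — standard texture-analysis defaults, all
config-exposed. Integer patches whose range fits within the level count
keep their own gray levels; others are min–max quantized, which makes
the features invariant to additive offsets. Histogram features use
population-convention moments (skewness $m_3/\sigma^3$, Pearson
kurtosis $m_4/\sigma^4$, both 0 at zero variance), RMS, Michelson
contrast with min/max read at the 1st/99th percentiles for outlier
resistance, and histogram energy over 256 bins spanning the patch range.
Where a published analysis leaves a definition open (contrast, histogram
energy, moment conventions), the configuration records the choice so
alternates can be swapped in.

Classifiers: LDA (pooled covariance), linear SVM (unit cost), Gaussian
naive Bayes, and a Gini decision tree grown without depth restriction —
deliberately default-parameterized; no tuning. Features are standardized
with training-set statistics inside every split and fold to prevent
leakage. Evaluation runs resubstitution (under-fit check), stratified
10-fold CV (over-fit check), and the final protocol of ten stratified
90/10 splits whose per-split confusion matrices are summed into one
cumulated matrix; accuracy, sensitivity, specificity and precision are
computed from the summed counts, with the first-listed class of each
comparison as positive. The full grid covers 3 pairwise comparisons × 9
feature presets (Raman-only rows 1–3, AF-only rows 4–6, single-band
bimodal rows 7–8, full bimodal row 9) × 4 classifiers = 108 cells.

**Split granularity.** Splits are drawn at the patch level by default,
mirroring the apparent published protocol; because the twenty patches of
a sample overlap heavily, this leaks sample identity between training
and test data. A `group_aware` mode splits by sample instead. The
consequence is measurable: with class effects set to zero, patch-level
splitting still yields ~0.83 median accuracy (classifiers memorize
sample signatures, whose training labels match the test labels), whereas
sample-level splitting is correctly at chance. The null-calibration
check therefore uses sample-level splits; the comparative
(bimodal vs single-modality) experiments use the default patch-level
protocol, where most cells saturate near accuracy 1 under the default
class separation — the ordering claim then holds largely through ties,
which is itself informative about how optimistic patch-level evaluation
is.

## Validation problem sizes and numerical choices

The test suite and `scripts/acceptance.R` run at desk scale, chosen to
estimate each quantity stably: k-recovery over 200 noise-free band sets
(k on a grid over [0.5, 2], 32 px images); separation fidelity on 48 px
images, median over 20 noisy samples; baseline recovery on 60 noise-free
and 200 SNR-20 band-center measurements; feature oracles on 100 random
8×8 patches; null calibration over 20 seeds × 36 grid cells at 10
samples/class (smaller cohorts bias leave-group-out accuracy below
chance by roughly $-1/n$); the ordering experiment over 20 seeds at 6
samples/class, 96 px, SVM. Determinism is checked by byte-comparing the
feature and results CSVs of two identical pipeline runs.

Numerical conventions worth stating: band integrals are trapezoidal with
linear interpolation at window edges; k-bisection brackets
$(0, \operatorname{mean}(A)/\operatorname{mean}(B))$ to relative width
$10^{-12}$; population (divisor $n$) standard deviations throughout the
CV and histogram statistics; 2-level k-means lesion segmentation labels
the higher-mean cluster as lesion and is seeded for determinism;
degenerate inputs (constant images, zero-mean regions, single-class
training sets, windows off the axis) raise errors rather than produce
silent values. Per-item seeds are derived from the global seed by a
fixed integer mix, so datasets are bit-reproducible and samples are
independent draws.

## Known limitations

* The spatially uniform-$k$ assumption is built into both the estimator
  and the phantoms; real tissue with spatially varying AF spectra would
  violate it and the residual structure is only diagnosed, not
  corrected.
* Patch-level evaluation numbers should be read as optimistic upper
  bounds; sample-level numbers are the generalizing estimate.
* The AF continuum and noise models are statistical stand-ins, not
  detector physics; absolute intensities are arbitrary units.
* Only binary comparisons are implemented (no 3-way classification, no
  ROC analysis, no feature selection), matching the evaluation design.
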