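# ramanband

Wide-field Raman spectral band imaging of tissue is dominated by
near-infrared autofluorescence (AF), an endogenous emission one to two
orders of magnitude stronger than Raman scattering. `ramanband`
implements the analysis chain that turns paired narrow-band images into
Raman maps and tissue-class decisions:

1. **Baseline decomposition** of single-point spectra: an iterative
   peak-suppressing polynomial fit (orders 9–16) splits each measured
   trace exactly into a smooth AF continuum and a Raman component.
2. **Band image separation.** For each band (1437 cm⁻¹, CH₂/CH₃ modes;
   1655 cm⁻¹, amide I / C=C), two images are acquired through calibrated
   filter positions: a signal-position image *A* (Raman + AF) and a
   shifted AF-only image *B*. A multiplicator constant *k* is applied to
   *B* so that the image-domain ratio of mean AF to mean Raman intensity
   matches the spectrally measured ratio *r*:

       mean(k·B) / mean(A − k·B) = r   ⟹   k = r·mean(A) / (mean(B)·(1+r))

   The Raman image is `clamp(A − k·B, 0)`; an iterative bisection solver
   cross-checks the closed form.
3. **Texture features.** Twenty patches per image (random translation,
   90° rotations) yield 11 features each: GLCM entropy, energy and
   homogeneity plus eight intensity-histogram statistics (mean, histogram
   energy, SD, RMS, Michelson contrast, variance, skewness, kurtosis).
4. **Classification.** LDA, linear SVM, Gaussian naive Bayes and decision
   trees are evaluated for three pairwise tissue comparisons (mast cell
   tumor vs soft tissue sarcoma vs benign) over nine feature presets —
   Raman-only, AF-only and combined bimodal sets — by resubstitution,
   stratified 10-fold CV, and ten 90/10 holdout splits whose confusion
   matrices are cumulated before computing accuracy, sensitivity,
   specificity and precision.

Because no public instrument data exist, the package ships a first-class
synthetic phantom generator (`generate_dataset()`) with complete ground
truth — class-dependent Gaussian Raman peaks, a decaying AF continuum,
Gaussian-random-field texture, non-uniform illumination, detector noise
and a known true *k* per band — so every stage is testable end to end.

## Worked example

```r
library(ramanband)

params <- phantom_class_table()$MCT
sp <- generate_spectrum(params, seed = 3, sample_id = "demo")
d <- subtract_baseline(sp)
d
#> Baseline decomposition: order 11, 259 iterations, residual norm 4.153e-05

af_raman_ratio(d, 1437)          # point AF/Raman ratio at the band center
#> [1] 25.0854

bs <- render_band_image_set(sp, 1437, params, seed = 3, image_px = 128)
res <- separate(bs, spectral_target_ratio(d, 1437))
res
#> Band 1437 cm-1 separation: k = 0.7153, achieved/target ratio = 141.6/141.6, clamped 0.00%
bs$ground_truth$k_true           # generator truth for comparison
#> [1] 0.7152257
```

The point AF/Raman ratio ~25 reflects the phantom's order-of-magnitude
AF dominance at 1437 cm⁻¹, and the estimated k matches the phantom's
true constant to ~0.01% here; the
separated `res$raman_image` is the AF-free Raman map used downstream.
A full run — simulate, separate, extract features, evaluate the
3 × 9 × 4 grid — is one call:

```r
cfg <- validate_config(list(n_per_class = 4L, image_px = 96L,
                            patches = list(n = 8L)))
run_pipeline(cfg, "scratch/demo_run")
head(read.csv("scratch/demo_run/results/results.csv"), 2)
#>   comparison preset classifier tp fp tn fn accuracy sensitivity specificity precision
#> 1 MCT-vs-STS      1        LDA 30  0 30  0        1           1           1         1
#> 2 MCT-vs-STS      1        SVM 30  0 30  0        1           1           1         1
```

(At this phantom scale the default classes are easily separated, so many
grid cells saturate; the null-configuration and noise knobs in
`phantom_class_table()` control task difficulty.)

A command-line front end with `simulate | separate | features | classify
| report | full` subcommands is installed at
`system.file("cli", "ramanband.R", package = "ramanband")`.

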