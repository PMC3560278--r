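# colonyscatter

Label-free scoring of human embryonic stem cell (hESC) colony quality from
laser forward-scatter patterns.

## The problem

hESC colonies are graded by eye under a microscope: *good* colonies grow as
uniform flat sheets with clear edges, while *bad* (differentiating) colonies
pile up into lumpy, irregular-edged mounds. Manual grading is slow,
subjective, and does not scale to production culture. Because a colony acts
as a thin phase object — it delays the light passing through it in
proportion to its local thickness — its morphology is imprinted on the
forward-scatter pattern a laser projects onto a sensor behind the dish.
`colonyscatter` implements the full desk-scale version of that assay for
anyone developing or validating scatter-based colony scoring: synthetic 3-D
colony phantoms, physical-optics simulation of their scatter patterns,
rotation-invariant feature extraction, feature selection, SVM
classification, and the morphometric measurements (colony height,
Oct-4/DAPI expression ratio) used to validate the optical scores.

## The model

1. **Phase object.** A colony of thickness `h(x, y)` (μm) with
   refractive-index contrast Δn against the medium transmits
   `t(x, y) = exp(i 2π Δn h(x, y) / λ)`.
2. **Propagation.** The transmitted field, under Gaussian illumination, is
   propagated a distance `z` to the detector by the band-limited angular
   spectrum method — the exact scalar transfer function
   `exp(i 2π z/λ √(1 − (λ f)²))` applied in the FFT domain with evanescent
   and anti-aliasing cutoffs. Detector intensity is `|U_z|²` with Poisson
   shot noise and 16-bit quantization.
3. **Features.** The log-compressed pattern is mapped onto the unit disk
   and expanded in pseudo-Zernike moments
   `A_nm = (n+1)/π ∬ f(ρ, θ) R_nm(ρ) e^(−imθ) dA`, `0 ≤ m ≤ n ≤ 17`
   (171 magnitudes `|A_nm|`, which are rotation invariants).
4. **Selection and classification.** Each feature is scored by Fisher's
   criterion `F(j) = (μ_good − μ_bad)² / (s²_good + s²_bad)`; the top 161
   features feed a linear SVM (C = 1), trained on standardised features.
5. **Validation morphometry.** Colony height is estimated from
   confocal-style z-stacks as the mean per-pixel axial extent over the
   colony mask (global Otsu threshold), and pluripotency as the
   background-subtracted Oct-4/DAPI integrated-intensity ratio; classes are
   compared with two-sample t-tests.

The synthetic generator is calibrated to the measured class morphology:
good colonies 53 ± 4.2 μm mean thickness with near-circular boundaries, bad
colonies 44 ± 13.9 μm with irregular edges and lumpy surface structures.

## Worked example

```r
library(colonyscatter)

# one lumpy bad-class colony and its scatter pattern
ph  <- generate_phantom(phantom_params("bad"), seed = 7)
ph
#> <colony_phantom> bad, 512x512 px @ 2 um/px, mean thickness 40.4 um, peak 43.2 um
pat <- simulate_pattern(ph, optical_config(), seed = 7)
length(extract_features(pat))
#> [1] 171

# end-to-end benchmark at reduced field size (25 + 25 colonies)
small <- function(cl) phantom_params(cl, grid_size = 128, pixel_pitch = 8)
bm <- run_scatter_benchmark(n_good = 25, n_bad = 25, seed = 42,
                            good_params = small("good"),
                            bad_params  = small("bad"))
bm$report
#> Distinguish rate (%) by human-assigned class
#>                          good     bad
#>   good                 100.0%    0.0%
#>   bad                    0.0%  100.0%
#>   n_test = 16

# morphometric validation on synthetic stacks and fluorescence pairs
run_height_study(n_per_class = 30, seed = 42,
                 good_params = small("good"), bad_params = small("bad"))$summary
#> Colony height: good 52.6 +/- 3.7 um (n=30), bad 46.9 +/- 10.5 um (n=30)
#>   student t = 2.794, df = 58.00, p = 0.00705
run_ratio_study(n_per_class = 18, seed = 43,
                good_params = small("good"), bad_params = small("bad"))$summary
#> Oct-4/DAPI ratio: good 0.952 +/- 0.027 (n=18), bad 0.712 +/- 0.041 (n=18)
#>   student t = 21.020, df = 34.00, p = 4.64e-21
```

The distinguish-rate table reads row-wise: of the held-out colonies a human
would call good, 100% were scored good by the pipeline. The height study
recovers the calibrated class means and their variance ordering; the ratio
study recovers the higher pluripotent fraction of good colonies.

A command-line wrapper covering `simulate`, `extract`, `train`, `classify`,
`evaluate` and `morpho` is installed at
`system.file("cli", "colonyscatter", package = "colonyscatter")`; see
`?cs_cli`.

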