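---
title: "Methods: simulated forward-scatter scoring of stem-cell colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated forward-scatter scoring of stem-cell colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyscatter)
```

`colonyscatter` simulates and analyses a label-free optical assay for
grading human embryonic stem cell (hESC) colonies. This vignette is the
package's own account of the science: the models, the parameters that
matter, what the synthetic data does and does not emulate, and the design
choices made where the design was genuinely open.

## 1. Colony phantoms

### What the generator emulates

Manual colony grading rests on two morphological archetypes. *Good*
colonies are uniform flat sheets with clear edges; *bad* (differentiating)
colonies are irregular-edged with lumpy, non-uniformly stacked surface
structures. Confocal z-stack measurements put the average thickness of good
colonies at 53 ± 4.2 μm and of bad colonies at 44 ± 13.9 μm — the tenfold
variance ratio being the quantitative trace of the bad class's surface
lumps. The generator reproduces exactly these facts:

* The colony boundary is `R(θ) = R0 (1 + e · P(θ))` with `P` a random
  Fourier series over angular orders 2–6 normalised to unit rms, so
  `edge_irregularity` (e) is the rms relative boundary perturbation:
  0.03 for good, 0.25 for bad.
* The height profile is a flat plateau with a raised-cosine rim occupying
  the outer 12% of the radius (`rim_width`). The rim does not taper to
  zero: it ends at 25% of the plateau height (`edge_floor`) in a clean
  cliff, because a colony edge is at least one cell layer thick, never an
  infinitesimal wedge — this is also what makes a "clear colony edge".
* Bad colonies additionally receive a Poisson(6) number of signed Gaussian
  bumps (width 30–80 μm, amplitude sd 12 μm) inside the footprint, clipped
  at zero height.
* Each colony's per-colony height `H` is drawn from a truncated normal
  (inverse-CDF truncation at zero, never resampling) with the class mean
  and sd above, and the whole height map is rescaled so that its **mean
  thickness over the footprint equals `H` exactly**.

The last point is a deliberate semantic choice. A z-stack "average height"
measurement returns the mean axial extent over the colony, so the
generator's `height_mean`/`height_sd` parameterise the distribution of that
measurable quantity, not the apex height. Calibrating the apex instead
would make every downstream height statistic depend on the profile shape,
and no profile shape could then reproduce the reported class means with an
unbiased mean-extent estimator. The apex of a defaults good colony sits
~10% above its mean thickness.

Default geometry: 512 × 512 px at 2 μm/px (a 1.02 mm field), colony radius
400 ± 40 μm. hESC colonies are sub-millimetre; a colony then fills roughly
40% of the field, which samples the diffraction problem adequately without
heavy compute. Grid, pitch and radius are free parameters, and the test
suite uses 64–128 px fields where full resolution adds nothing.

### What it does not emulate

Phantoms are smooth continuum height maps: there is no cellular texture, no
internal refractive-index heterogeneity, no extracellular matrix, and the
fluorescence simulator places idealised Gamma-brightness nuclei rather than
segmentable cell images. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and that the *morphological signal* the
assay relies on survives simulation, detection noise and feature
compression — they do not demonstrate classifier performance on real
detector images, which contain speckle from subcellular structure the
phantoms lack.

## 2. Forward-scatter simulation

The colony is a thin phase object: the transmitted field is
`t(x, y) = exp(i 2π Δn h(x, y)/λ)`. Assumptions: single scattering, no
volumetric propagation inside the colony, scalar theory. For a ~50 μm
colony with Δn ≈ 0.04 this puts ~20 rad of smooth phase across the field —
a weak lens whose self-interference produces the characteristic ring
systems on the detector.

Parameters (`optical_config()`):

| parameter | default | units | rationale |
|---|---|---|---|
| `wavelength` | 633 | nm | HeNe-class diode; 632 nm hardware is equally supported |
| `delta_n` | 0.04 | — | typical cell-vs-medium refractive contrast |
| `z` | 20 | mm | sensor directly behind the dish, no lens |
| `beam_radius` | 600 | μm | Gaussian 1/e² radius comfortably covering one colony |
| `peak_counts` | 5000 | counts | shot-noise scale at the brightest pixel |
| `detector_bits` | 16 | bits | monochrome CMOS quantization |

Propagation uses the band-limited angular spectrum method: the exact
scalar transfer function, evanescent cutoff, and the
`f_lim = 1/(λ √((2z/L)² + 1))` anti-aliasing limit (`L` = field width).
Within the passband the method is unitary, so energy is conserved to
machine precision for band-limited fields — the hard-aperture validation
below conserves energy to 0.02%. Colony phantoms are *not* band-limited:
their rims carry phase gradients that deflect 4–8% of the beam energy
beyond `f_lim` at the default geometry. That light would miss a finite
sensor; discarding it is the physically sensible behaviour, and the package
documents conservation as holding for in-band fields rather than
universally.

Two analytic anchors validate the propagator: (i) a hard circular aperture
of diameter D reproduces the Airy first minimum at `1.22 λz/D` within one
detector pixel; (ii) intensity scales as the square of a field amplitude
scale factor. A circularly symmetric phantom yields a pattern symmetric
under quarter rotations to machine precision, and the annular asymmetry
index (energy-weighted azimuthal coefficient of variation) separates the
lumpy class from the smooth class by more than a pooled standard deviation.

## 3. Pseudo-Zernike features

Patterns are log-compressed (`log(1 + I)`) before moment computation — the
central lobe otherwise dominates every low-order moment; log compression is
monotone, preserves ring geometry, and needs no tuning. The image is mapped
onto the unit disk at the geometric image centre with the inscribed-circle
radius (the optical axis is the pattern centre by construction; an
intensity-centroid option would couple the mapping to noise), then expanded
in pseudo-Zernike moments with midpoint pixel sampling. Pixels whose
centres fall outside the disk are excluded; the pixel area element is
`1/radius²` in unit-disk units, making `|A_00| = 1` for a uniform unit
image up to discretisation.

Numerically, the textbook alternating factorial sum for the radial
polynomial `R_nm(ρ)` cancels catastrophically at high order — around
n = 17 it loses ~12 significant digits. The implementation instead
evaluates the equivalent Jacobi form
`R_nm(ρ) = ρ^m P^(0, 2m+1)_{n−m}(2ρ − 1)` by the stable three-term
recurrence; the factorial sum remains the independent test oracle at low
order, and radial orthogonality `∫ R_nm R_n'm ρ dρ = δ_nn'/(2n+2)` holds
numerically to 10⁻⁸ at n = 17.

Magnitudes are kept for `0 ≤ m ≤ n ≤ 17`: negative repetitions are complex
conjugates and add no information. Order 17 gives 171 magnitudes, the
smallest complete order set of at least 161 — the standard selected
dimension of this pipeline. Fisher's criterion
`F(j) = (μ_g − μ_b)²/(s²_g + s²_b + ε)` with sample (n−1) variances and
`ε = 10⁻¹²` ranks features (ties broken by lower index; `ε` keeps
zero-variance features finite but dominant), and the top 161 are selected —
always from training data only.

## 4. Classification

A linear SVM with C = 1 on training-standardised features is the default:
with 161 features and a few hundred samples, a maximum-margin linear rule
is well-conditioned, reproducible, and empirically saturates the synthetic
benchmark; an RBF kernel is available via `kernel = "radial"`. The model
object stores support vectors, dual coefficients, offset and scaler, and
prediction is computed from those stored numbers directly — so a model
serialised to JSON predicts bit-identically after reload, and the
in-memory path is verified against a direct libsvm refit in the tests.
Evaluation reports the 2 × 2 confusion matrix with row-normalised
percentages to one decimal place ("distinguish rates"), rows being the
human-assigned class. Benchmarks are generated class-balanced, so no class
weighting is applied.

## 5. Morphometry

**Height.** Slice `k` of a synthetic z-stack samples the axial midplane
`(k − ½) · z_step`; a pixel is occupied where the colony is thicker than
the midplane. Bottom-edge sampling (`k · z_step`) was rejected because it
biases every extent upward by half a slice on average. Occupancy in real
(noisy) stacks is decided by a single global Otsu threshold over the
volume — per-slice thresholds hallucinate structure in empty slices above
the colony. For speed the threshold is computed on a deterministic stride
subsample of at most 10⁶ voxels (Otsu depends only on the histogram
shape). Pixels occupied in fewer than 2 slices are treated as noise specks
and excluded from the colony mask; genuine colony pixels are at least one
cell layer (~6 slices at 2 μm) thick. The per-pixel extent is
`(top − bottom + 1) · z_step`; the colony height is its mean over the mask
(the measurable "average height"), with `method = "peak"` for the apex.
The estimator is exact on noiseless slabs whose height is a multiple of
`z_step` and unbiased for the calibrated mean thickness.

**t-tests.** `compare_heights()`/`compare_ratios()` wrap the classical
two-sample t-test; `"student"` (pooled variance) is the default naming
convention of this assay's literature, with `"welch"` available because the
bad class's variance is an order of magnitude larger, which strains the
pooled assumption. One power fact is worth stating plainly: under the
calibrated class statistics (53 ± 4.2 vs 44 ± 13.9 μm) the pooled effect
size is d ≈ 0.88, so a Student test at α = 0.01 with 18 colonies per class
has only ≈ 47% power — a single small-cohort height comparison will fail
to reach p < 0.01 about half the time even though the class difference is
real. Detecting the difference reliably at that significance level needs
on the order of 50+ colonies per class.

**Expression ratio.** Every simulated nucleus contributes its brightness
to the DAPI channel and, with probability `true_positive_fraction`, the
same brightness to the Oct-4 channel; the background-subtracted integrated
ratio therefore estimates the pluripotent fraction, with binomial sampling
error inflated by the nucleus brightness coefficient of variation (0.2).
Background is the median of out-of-colony pixels — robust to the sparse
tails of the PSF. Default study fractions are 0.9 (good) vs 0.5 (bad):
good colonies are predominantly pluripotent, while bad colonies retain
sizeable Oct-4-positive subpopulations, which keeps the class difference
real but modest, as fluorescence validation data show.

## 6. Reproducibility and problem sizes

Every stochastic function takes a `seed` and restores the caller's RNG
state; study wrappers (`run_scatter_benchmark()`, `run_height_study()`,
`run_ratio_study()`) are pure functions of their seed. The shipped
benchmark sizes — 100 + 100 colonies at 512 px for classification and
height recovery, 18 per class for the fluorescence study, 64–128 px fields
for property tests — were chosen as the smallest sizes at which the
quantities of interest are statistically stable; they run in a few minutes
on one CPU.

## 7. Known limitations

* Thin-phase, single-scattering optics: no volumetric or vector effects,
  no multiple scattering inside thick lumps.
* Steep-rim phantoms lose a few percent of energy past the numerical
  aperture; patterns are correct on the detector but total-energy
  bookkeeping must use the in-band statement above.
* Phantoms lack cellular texture; absolute classifier accuracies on
  synthetic data are upper bounds, not forecasts, for real instruments.
* The height estimator assumes the colony rests on the first slice's
  substrate; floating debris or detached folds would violate the
  contiguous-occupancy assumption.
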