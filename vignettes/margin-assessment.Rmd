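---
title: "Models and design choices behind octmargin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind octmargin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`octmargin` computes a surgical-margin call for a breast resection specimen
from three co-registered optical channels: a fluorescence image that flags
enzymatically active (suspicious) surface regions, confocal-guided labelled
regions that train a tissue classifier, and a 3-D OCT volume in which the
classifier assigns tumor, adipose or benign stroma to every voxel. Tumor
voxels within 1 mm of the segmented top surface are projected laterally and
the surviving area decides the specimen call. This vignette records the
models, the tunable parameters, and the choices made where the design was
genuinely open.

## Probe activation kinetics

The contrast agent is an internally quenched protease substrate. Two
measured facts anchor the model: quenching efficiency q = 0.90 (so full
cleavage multiplies fluorescence by 1/(1−q) = 10) and the enzyme-to-substrate
ratios representative of tissue — uPA averages 1 ng/mg protein in benign and
8 ng/mg in malignant tissue, anchored at 1:200 for benign, hence 1:25 for
tumor and 1:50 for infiltrated tissue by exact inverse proportionality
(`es_ratio()`).

Cleavage is modelled as pseudo-first-order in the relative enzyme
concentration, `c(t) = 1 − exp(−k t / N)` for an E:S ratio `1:N`. No
Michaelis–Menten constants are available, so the single rate constant `k`
is calibrated by root finding so that the baseline-subtracted 1:25 vs 1:200
contrast at one minute equals the observed optimum of 4.5
(`calibrate_cleavage_rate()`; the frozen default is k ≈ 38.26 per
relative-enzyme·minute). The calibration is exact for that one condition by
construction; the same k yields ≈ 3.1 for the 1:50 curve, close to but not
asserted against the ≈ 3.5 observed — one rate constant cannot pin three
curves, which is a documented limit of the first-order model. The default
incubation is 2 minutes, the practical compromise between contrast and
agent diffusion depth.

## Source spectrum and axial resolution

The source is modelled as a Gaussian spectral envelope (center wavelength
1310 nm, FWHM bandwidth 100 nm by default, truncated at ±3σ, 2048 samples).
Whether the quoted 3 dB width of the real superluminescent diode is exactly
a Gaussian FWHM is unknowable from the numbers alone; Gaussian FWHM is
assumed. The theoretical axial resolution `(2 ln 2/π) λ₀²/Δλ` evaluates to
7.57 µm in air. The spectral-domain simulator synthesizes fringes
`2√R cos(2kz + φ(k))` under the envelope with optional second-order
dispersion `φ(k) = c₂ (k − k₀)²` and an optionally warped sampling grid;
reconstruction subtracts the envelope, spline-resamples to uniform
wavenumber, forms the analytic signal, applies the conjugate dispersion
phase when asked, and Fourier transforms (8× zero-padding refines the peak
sampling). The tests verify that the simulated point-spread FWHM matches
the closed form within 10% and that compensation is the exact inverse of
simulated dispersion to within 1%. One physical caveat: very strong
dispersion at shallow depths can drive the instantaneous fringe frequency
negative, where the analytic-signal separation (and any real spectrometer)
breaks down; the tests stay in the physical regime.

## Texture features

All filters use symmetric (edge-inclusive) reflection at borders, and the
test suite holds the implementation to brute-force oracles pixel for pixel;
this is why the convolutions are authored in the package rather than
delegated to a library with different border conventions.

* `gaussian_smooth()` — normalized discrete Gaussian, σ_smooth = 2 px
  default, removes speckle-scale noise.
* `roughness_decompose()` — waviness is a second Gaussian pass at
  σ_waviness = 16 px; roughness = smoothed − waviness, exactly.
* `roughness_sd_filter()` — population (divisor n) SD over a 9 px window.
  Population rather than sample SD because the window is the whole
  neighbourhood, not a sample from it; the choice is documented and tested.
* `prewitt_slope()` — 3×3 Prewitt gradient magnitude divided by 6, so a
  ramp of s intensity units per pixel reads s.

The kernel sizes are free parameters (the operators are named in the
underlying method, their sizes are not): 2/16/9 px at the default 10 µm
lateral voxel, rescaled automatically for other voxel sizes
(`texture_params()`). The nine ROI features (mean/SD intensity, mean
waviness, mean/max roughness SD, mean/SD slope, 16-bin intensity entropy,
local contrast) are a declared reconstruction: only roughness SD and slope
are named by the method as the discriminating pair, and the PCA report
(`pca_report()`) exists to show that a handful of components carries the
table's variance. ROI features exclude a border of half the SD window so
every retained pixel has a fully interior neighbourhood.

## Surfaces and depth handling

The top surface is found per A-line as the first local maximum above half
the column maximum — physically sound because the pressed window–tissue
interface reflects specularly, far above any scattering speckle. The bottom
is the deepest voxel of the largest above-threshold run, with the threshold
chosen by between-class-variance (Otsu-style) maximization on 64 histogram
bins of **log** intensity: OCT intensity statistics are multiplicative, so
tissue/background bimodality lives in the log domain (on a noiseless
two-valued slab the split is identical). A lateral-only pre-smoothing
(σ = 2 columns) suppresses speckle outliers without moving axial
boundaries, so noiseless slabs are still recovered exactly. Profiles are
median-smoothed to a median-filter root (idempotent); frames whose
above-threshold runs are uniformly short (75th percentile below nz/6) are
declared signal-free rather than yielding a spurious surface. Per-volume,
the bottom map is additionally median-smoothed across both lateral
dimensions so the foreground mask is a coherent slab.

Three depth-handling steps precede classification, all applied identically
in training and inference:

1. **Surface-echo removal** (`remove_surface_echo()`): the specular surface
   voxel carries no tissue texture and would contaminate windows near the
   surface.
2. **Attenuation gain** (`depth_compensate()`): a linear fit to log mean
   foreground intensity versus depth, gain `exp(rate·z)` normalized to 1 at
   the surface. The shallowest foreground voxel per A-line (the specular
   echo) is excluded from the fit. Applying the gain to intensities rather
   than thresholds is mathematically equivalent for a multiplicative model
   and keeps one code path.
3. **Per-plane normalization**: every en-face plane is scaled to unit
   foreground mean before feature extraction. The fitted exponential cannot
   follow structural axial profiles (fat-cell caps versus equators modulate
   the mean independently of attenuation); normalizing each image directly
   implements "the signal drop is calculated for each image" regardless of
   the drop's cause.

## The classifier

`tissue_classifier()` is the package's fitted-model object (print, summary,
coef, predict methods). For each of the two features a threshold is chosen
by exhaustive search over midpoints of consecutive sorted training values,
minimizing training error; for separable training data this lands in the
middle of the class gap (the documented tie-break takes the first minimal
candidate). The decision list is fixed: adipose if slope exceeds its
threshold — septa membranes dominate gradients — else tumor if roughness SD
exceeds its threshold, else benign. Whether a joint 2-D decision region
would do better is left open deliberately; the decision list is what the
threshold-per-feature training implies. Degenerate training (a feature
identical across classes) is an error naming the feature.

Voxel-level application (`classify_voxels()`) aggregates the feature maps
over a 21 px decision window before thresholding, so the per-voxel
statistics approach the ROI means the thresholds were trained on: the slope
map by window mean (sparse bright septa must be able to pull a window
toward adipose) and the roughness-SD map by window median (an isolated
bright membrane must not read as diffuse tumor texture in its
neighbourhood). Two gates keep the tumor branch physical: a minimum local
signal of half the plane mean (tumor is the strongest scatterer; near-noise
regions such as deep fat lumens are never tumor) and a minimum 70% in-mask
window coverage (a window dominated by out-of-mask fill carries no usable
texture; such voxels stay indeterminate/background). A 3×3×3 majority vote
then smooths the labels; only voxels already carrying a tissue label and
with at least one tissue vote are relabelled.

Training in the pipeline mirrors the study's workflow of dedicated training
image sets: one shared model is fitted from three seeded reference phantoms
(uniform tumor, adipose, and an infiltrating specimen supplying clean
benign stroma), five 28 px ROIs per class by default. 280 µm ROIs are
chosen so an adipose ROI always spans at least one cell septum; per-specimen
training is impossible for single-class specimens anyway.

## Margin projection and evaluation

A lateral pixel is margin-positive when any tumor voxel lies within 1 mm
below the local top surface (the clinical band); connected components below
0.01 mm² are discarded, and the specimen is positive if any area survives.
Enlarging the projection depth can only grow the mask (tested
monotonicity). `evaluate_margins()` reports both metric conventions by
name: the headline `PPV = TP/(TP+FN)` and `NPV = TN/(TN+FP)` — which are
algebraically sensitivity and specificity — alongside the standard
epidemiological definitions, because the headline values of the modelled
study match the former, not the latter, and silent ambiguity would be worse
than redundancy.

## What the phantom generator emulates — and what it does not

`specimen_phantom()` produces seeded, bit-reproducible specimens:
multiplicative gamma speckle (shape 4, the standard OCT intensity
statistic), exponential depth attenuation per class, class-distinct
textures, enzyme-dependent fluorescence, a flat-shaded photo and a
high-resolution en-face confocal-style image. Five layout templates mirror
the representative intraoperative cases: tumor all around, infiltrating
boundary (40% area target), fat-only surface, a benign specimen with a
lobule whose scattering mimics tumor (the known false-positive mode), and a
small tumor focus buried 0.5 mm deep.

No quantitative per-class optics were available, so the scattering
parameters are the package's own, chosen from OCT physics and frozen:

| class  | mean | contrast | µ (1/mm) | scale (µm) |
|--------|------|----------|----------|------------|
| tumor  | 1.0  | 0.45     | 1.2      | 30         |
| adipose| 0.7  | 1.0      | 0.5      | 220 (cell) |
| benign | 0.9  | 0.10     | 0.9      | 60         |

Tumor is a homogeneously grainy clipped-linear random field (a lognormal
field was rejected: its heavy-tailed patch brightness makes ROI statistics
unstable in a way real tumor texture is not). Adipose is a 3-D staggered
Voronoi honeycomb in physical coordinates — closed cells whose A-lines
cross bright septa caps, dark lipid lumens, narrow septa (8% of the cell),
and a bright collagenous membrane along lateral fat/tissue interfaces;
staggering alternate layers avoids unphysical horizontal septa sheets.
Benign stroma is smooth and mildly anisotropic. Attenuation coefficients
are in the low single digits per millimetre so that, as for the real
1310 nm system, the first millimetre below the surface remains assessable;
the default volume is 64×64×220 voxels (0.64×0.64×1.1 mm at 10/5 µm
voxels) with an 0.88 mm-thick slab, a smooth top-surface height variation
of ±2 voxels and a constant-amplitude specular reflection (value 8) at the
window interface, which is coherent and not speckle-modulated.

What passing tests on these phantoms show is that the pipeline recovers
exactly the structure the generator puts in: textures with the assumed
statistics, surfaces with the assumed geometry, monotone margins. They do
not show robustness to anything the generator omits: tissue deformation and
fixation artifacts, refraction, shadowing, motion, probe diffusion limits,
heterogeneous sub-resolution tissue mixtures, or RCM-to-OCT registration
error. The bottom surface deserves a specific caveat: it is a
maximum-*signal* depth, so under strong tumor attenuation it sits a couple
of voxels above the geometric slab end, and under deep fat lumens it is
genuinely undefined; tests assert exact recovery on noiseless slabs,
sub-voxel top-surface accuracy on every template, and sub-voxel bottom
accuracy on the benign-dominated template.

## Numerical choices and problem sizes

Kernels truncate at 3σ; reflection is edge-inclusive; ROI interiors exclude
half the SD window; thresholds break ties toward the first minimal
candidate; Otsu uses 64 bins; median smoothing iterates to a root (cap 25);
registration searches integer offsets only (no sub-pixel model) and breaks
correlation ties toward the nominal placement; stitching feathers linearly
over the realized overlap and normalizes, so constants are preserved
exactly. Degenerate inputs error early and descriptively: empty reflector
lists, flat A-lines, constant overlap bands, all-invalid B-scans,
single-class training sets.

The tests run the full study geometry (64×64×220-voxel phantoms; a
20-specimen cohort of 8 positive and 12 negative layouts; 50 held-out ROIs
per class; 100 seeded registration trials), sizes chosen so the whole suite
completes in a few minutes on one core while every statistic is computed at
the scale its claim is stated for. The separability sweep inside the unit
tests uses 8 phantom pairs as a reduced rendition of the 50-phantom
condition; the cohort and classifier criteria run at full size in the
acceptance tests.
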