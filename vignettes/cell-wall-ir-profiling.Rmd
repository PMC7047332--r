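---
title: "Cell-wall profiling from ATR-FTIR hyperspectral images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-wall profiling from ATR-FTIR hyperspectral images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irwall)
```

## The measurement and the data model

Attenuated-total-reflectance Fourier-transform infrared (ATR-FTIR)
microspectroscopy images a tissue section through a germanium crystal pressed
onto the sample: every pixel of the field of view carries a full mid-infrared
absorbance spectrum. `irwall` models such an acquisition as a cube indexed
(row, col, wavenumber). The default configuration is a (100 × 100) µm² field
at (1.56 × 1.56) µm² pixels — a 64 × 64 grid of 4,096 pixels — over the
fingerprint region 1,800–850 cm⁻¹.

The spectral axis is stored descending (1,800 → 850 cm⁻¹), following
spectroscopy plotting convention; all operations are order-agnostic. The
default grid step is 2 cm⁻¹. An instrument's *optical* resolution (typically
4 cm⁻¹ for this kind of acquisition) is a property of the interferometer, not
of the digital grid; the local-maximum rule below compares σ against σ ± 2
cm⁻¹, which addresses adjacent grid points at a 2 cm⁻¹ step, so that is the
sampling interval we adopt. At 2 cm⁻¹ the default axis has 476 points.

Vendor-side corrections (background subtraction, atmospheric correction) are
out of scope: input cubes are assumed to be corrected absorbance. An optional
Savitzky–Golay smoother (`smooth_spectrum()`) is available for additional
noise reduction; no ATR penetration-depth correction is applied.

## Preprocessing: SNV and detrending

Correlation-based classification must see spectral *shape*, not offsets or
multiplicative scatter. Both reference and pixel spectra therefore pass
through `detrend()`:

1. **SNV** (standard normal variate): standardize each spectrum to mean 0,
   unit sample standard deviation.
2. **Polynomial baseline removal**: subtract the least-squares polynomial of
   degree 2 (configurable) fitted against wavenumber.

The fit uses a wavenumber basis centered and rescaled to [−1, 1] for
conditioning; in exact arithmetic the result is identical to fitting raw
wavenumber powers, and the tests verify agreement with a raw normal-equations
solve to 1e−8. Two consequences worth noting:

* `detrend()` is invariant to positive affine transforms of its input (SNV
  absorbs them), so absorbance scale and offset never influence downstream
  scores.
* A zero-variance (flat) spectrum has no defined SNV. Such degenerate pixels
  are flagged rather than dropped; the assignment stage labels them lumen,
  which is what a truly empty pixel is.

## Pixel assignment by correlation score

The classifier is deliberately simple and transparent:

1. Build a **mean representative spectrum (MRS)** per cell-wall class:
   average the *raw* spectra of manually selected pixels (the reference
   protocol selects 90 per class), then detrend (`build_mrs()`).
2. Detrend every pixel spectrum and compute its **Spearman rank
   correlation** against every MRS (`assign_pixels()`). Spearman is
   implemented as Pearson correlation of mid-ranks (average ranks on ties),
   so any strictly increasing distortion of a detrended spectrum leaves its
   score unchanged.
3. Decide per pixel:
   * all scores < 0.90 → **lumen** (no MRS explains the pixel);
   * best and second-best scores within 1% of the best → **not assigned**
     ("NA"; the pixel is ambiguous, typically at a class interface);
   * otherwise → the argmax class.

The 1% tie rule is interpreted as a *relative* difference,
(best − second)/|best| < 0.01; an absolute reading (0.01 correlation units)
is nearly indistinguishable at scores near 1 but diverges for weak scores.
Both thresholds are arguments (`lumen_threshold`, `tie_fraction`), and exact
score ties are treated as unassignable at any `tie_fraction`. Negative
scores participate in the argmax without special-casing; in practice they
fall under the lumen rule.

Note that full invariance of the *assignment* to monotone transforms of the
raw pixel spectrum holds for affine maps (through detrend invariance);
non-affine monotone maps alter what the polynomial fit removes and may
change detrended ranks. The Spearman score itself is invariant to monotone
maps of its (detrended) inputs, and the tests pin down both statements
separately.

`evaluate_assignment()` scores a prediction against ground truth with a full
confusion matrix including the lumen and NA categories.

## PCA exploration

`run_pca()` performs mean-centered PCA without variable scaling (the analysis
operates on raw spectra), via singular-value decomposition. `false_rgb()`
renders pixel scores on the first three components as an RGB composite
(PC1 → red, PC2 → green, PC3 → blue, each channel min–max rescaled), a quick
visual for choosing training pixels. `pca_loadings()` returns
eigenvector × eigenvalue per component — the product with the variance, kept
as-is because it is the convention this pipeline standardizes on — with the
conventional √eigenvalue scaling behind a flag. Sign convention: the
largest-magnitude coefficient of each component is made positive.

## Differentially absorbed wavenumbers (DAWNs)

To compare two cell-wall classes, every wavenumber is tested with a
two-sided Wilcoxon rank-sum test on the per-pixel absorbances of the two
classes (`pairwise_dawn_scan()` over all unordered class pairs). P-values
are Bonferroni-adjusted and thresholded at α = 0.001.

* **Adjustment family.** The default family is the set of class pairs at
  each wavenumber, mirroring a per-wavenumber pairwise test call; a
  `"global"` option multiplies by pairs × wavenumbers instead. Both are
  offered because either reading is defensible; the default is the milder
  one and the tests exercise both.
* **Exactness.** The test is exact (via the null distribution of the
  Mann–Whitney U statistic) when both samples have ≤ 8 observations and no
  ties, and uses the tie-corrected, continuity-corrected normal
  approximation otherwise. Pixel populations are in the hundreds, so the
  approximation is the operative branch; the exact branch exists so small
  cases are testable against full enumeration.

A statistically significant wavenumber is only biologically interpretable if
it sits on an absorption band, so DAWNs are gated on spectral geometry: σ
must lie within 3 cm⁻¹ of a **local maximum** of a class-mean spectrum,
where σ is a local maximum when its absorbance exceeds that at σ − 2 and
σ + 2 cm⁻¹ (`local_maxima()`, endpoints excluded; distances are physical
cm⁻¹ so non-default axis steps behave). The gate accepts maxima of *either*
class in the pair by default — a band present in only one class is exactly
the interesting case — with a `"both"` option. Passing DAWNs are annotated
with every overlapping entry of a band-assignment table mapping wavenumber
ranges to cell-wall compound classes (cellulose, crystalline cellulose,
hemicelluloses/acetylated xylans, lignins, pectins, proteins); wavenumbers
covered by no entry are reported as "unassigned". A compact built-in table
compiled from the plant cell-wall literature ships with the package and can
be replaced by a user CSV.

One property to keep in mind when reading DAWN output: with ~476 wavenumbers
per pair, a per-wavenumber family at α = 0.001 admits on the order of half a
false positive per scan, and a null false positive can coincide with a
noise-induced local maximum of a class-mean spectrum. Occasional isolated
passing wavenumbers far from any real band are therefore expected behaviour
of the procedure, not a defect; the null-control simulation quantifies the
rate (< 0.5% of wavenumbers).

## Reporting

* `class_average_spectra()` — mean spectrum over each class's pixels (lumen
  and NA excluded).
* `heatmap_matrix()` — rows are (image × class) units, columns the passing
  DAWN wavenumbers, values the class-mean absorbance per image; the display
  matrix is z-scaled per column. Dendrograms use 1 − Pearson correlation as
  the distance, computed on the *unscaled* values (scaling is a display
  device), with average linkage — a common default for correlation
  distances; both the linkage and the scaling choice are configurable.
  Constant units get distance 1 (uncorrelated) with a warning.
* `absorbance_image()` — single-wavenumber rendering: selected classes in
  their class hue with intensity proportional to min–max scaled absorbance,
  lumen black, NA white. The nearest grid point to the requested wavenumber
  is used and reported.
* `score_plot_data()` — per-class (PC1, PC2) means, covariances, and
  covariance ellipses at the χ²(2 df) quantile of the requested level (95%
  coverage of a bivariate normal by default); degenerate covariances are
  flagged rather than inverted.

## The synthetic scene generator

No public instrument data accompany this kind of acquisition, so the package
ships a generator (`generate_scene()`) producing hyperspectral scenes with
known per-pixel labels and known spectral structure. It is first-class,
tested code: every pipeline stage is validated against it.

**Spectra.** Each class is a `class_spectrum_model()`: Gaussian absorption
bands over a quadratic baseline. Gaussian shapes (not Lorentzian/Voigt) keep
peak positions analytic, so local-maximum tests have exact expected answers.
A pixel spectrum is the class model with per-pixel, per-band amplitude
jitter (relative sd 0.05 by default — mimicking real within-class
compositional variation), plus i.i.d. Gaussian absorbance noise (sd 0.01 AU
by default, a realistic post-correction noise floor for 16-scan pixels);
lumen pixels are baseline plus noise only.

**Band inventories** (`default_models()`) encode the qualitative contrasts
of poplar wood cell walls: the tension-wood fiber G-layer lacks the lignin
aromatic bands (1,594 / 1,506 cm⁻¹), carries a strong crystalline-cellulose
double band (1,336 / 1,316 cm⁻¹) plus 1,200 and 1,052 cm⁻¹ bands, and is
weak at the acetylated-xylan bands (1,736 / 1,236 cm⁻¹) where S-layers
absorb strongly; vessel and ray S-layer models vary the same vocabulary.
Amplitudes are simulator choices, fixed once so that detrended clean class
spectra have pairwise Spearman correlations between 0.5 and 0.85 — distinct
enough to classify, similar enough that the 0.90 lumen threshold and the 1%
tie rule are meaningfully exercised. The tension-wood fiber G and S models
share one baseline so that a G-vs-S scan probes band differences only.

**Layout.** Preset rasters tile the default 64 × 64 grid with 16 × 16-pixel
fiber cells (an S-layer ring around a lumen; tension wood adds a
three-pixel-thick G-layer ring), one four-row ray band and three
vessels (ring walls with lumens) stamped on top; class fractions roughly
track real tension-wood composition (G-layer largest, vessels sparse).
Explicit label rasters are accepted for custom layouts. Boundary pixels are
defined by 4-connectivity (a pixel is interior when every in-grid 4-neighbour
shares its label); recovery metrics exclude boundaries because interface
pixels carry genuinely mixed signal — in real data those are exactly the
pixels that end up "not assigned". `generate_selections()` samples training
pixels only from class interiors, emulating careful manual selection.

**Determinism.** Each scene uses one private RNG stream seeded from its
spec; the global RNG state is saved and restored, and identical (spec,
models) reproduce bit-identical cubes.

**What passing tests do and do not show.** The generator produces additive
Gaussian noise, uncorrelated across wavenumbers, ideal Gaussian bands, flat
class composition within a scene, and geometrically clean interfaces. Real
acquisitions add correlated baseline drift, atmospheric residuals, contact
artifacts, partial-volume mixing at every interface and instrument drift
between images. High recovery rates on synthetic scenes validate the
*implementation* of the method, and the method's behaviour under its own
assumptions — not its field accuracy on instrument data.

## Numerical choices and degenerate inputs

* Polynomial detrend basis scaled to [−1, 1]; agreement with a raw
  normal-equations solve is tested to 1e−8.
* Spearman returns an undefined-score signal (NA, treated as −∞ by the
  decision rule) when an input has zero rank variance.
* Exact ties in the decision rule are always "not assigned".
* The Wilcoxon normal approximation applies the tie correction and a 0.5
  continuity correction; degenerate all-identical samples give p = 1.
* Column scaling of a constant heatmap column yields zeros; correlation
  distance to a constant unit is pinned at 1 with a warning.
* The exact/approximate Wilcoxon switchover sits at n ≤ 8 per sample
  (no ties): enumeration there is cheap and testable, while every realistic
  pixel population is far beyond it.

## Problem sizes used in the validation suite

The test and acceptance harnesses run the full default scene (64 × 64 × 476,
one image), class populations of 200 spectra for the null and seeded-effect
DAWN simulations, exhaustive Wilcoxon enumeration up to n = m = 6, and 1,000
random vector pairs for the Spearman oracle — sizes chosen to exercise every
code path at full fidelity while keeping the whole suite in the tens of
seconds on a laptop.

## Known limitations

* The classifier is a nearest-reference rule; it cannot represent within-class
  multimodality beyond what the MRS averages away. Methods that failed for
  this problem in practice (k-means, hierarchical clustering on principal
  components, k-NN) are deliberately not implemented.
* MRS selection quality is the user's responsibility; the package emulates
  it only synthetically.
* Band annotation is a range lookup: overlapping assignments are reported,
  not disambiguated, and spectral deconvolution is out of scope.
* Proprietary instrument file formats are not parsed; convert to ENVI or the
  long-table CSV first.
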