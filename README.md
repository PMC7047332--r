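# irwall — cell-wall profiling from ATR-FTIR hyperspectral images

`irwall` is an R toolkit for analysing attenuated-total-reflectance
Fourier-transform infrared (ATR-FTIR) hyperspectral images of plant tissue
cross-sections, built for wood-anatomy and cell-wall researchers who want
per-cell-type infrared profiles without dissecting the tissue. Given an
absorbance cube A(x, y, σ) over the mid-IR fingerprint region
(1,800–850 cm⁻¹), it:

1. **classifies every pixel** into cell-wall classes (fiber S-layer,
   tension-wood fiber G-layer, vessel S-layer, ray S-layer) or lumen, by
   Spearman correlation of the detrended pixel spectrum against detrended
   **mean representative spectra** (MRS) built from user-selected training
   pixels;
2. **detects differentially absorbed wavenumbers (DAWNs)** between classes
   with per-wavenumber pairwise Wilcoxon rank-sum tests, Bonferroni
   correction, and a spectral local-maximum gate;
3. **annotates** DAWNs with cell-wall compound classes (cellulose,
   crystalline cellulose, acetylated xylans, lignins, pectins, proteins);
4. **reports**: class-average spectra, PCA score plots with 95% normal
   ellipses, loadings, column-scaled heatmaps with correlation-distance
   dendrograms, and single-wavenumber absorbance images;
5. **simulates** hyperspectral scenes with known ground truth, so the whole
   pipeline is testable without instrument data.

## The method in brief

For a pixel spectrum **a** and class references **m**₁…**m**ₖ (all
detrended: SNV followed by removal of a degree-2 polynomial in σ), let
ρᵢ = Spearman(**a**, **m**ᵢ). The pixel is

* **lumen** if max ρᵢ < 0.90,
* **not assigned** if (ρ₍₁₎ − ρ₍₂₎)/ρ₍₁₎ < 0.01 (top two scores within 1%),
* otherwise the **argmax class**.

For classes u, v and wavenumber σ, the DAWN scan tests
H₀: Aᵤ(σ) ~ Aᵥ(σ) with the two-sided Wilcoxon rank-sum statistic over the
per-pixel absorbances, adjusts p over the class pairs (Bonferroni), and
keeps σ when the adjusted p < 0.001 **and** σ lies within 3 cm⁻¹ of a local
maximum of a class-mean spectrum, where σ is a local maximum when
A(σ) > A(σ−2) and A(σ) > A(σ+2) cm⁻¹.

## Worked example

A synthetic tension-wood scene end to end (numbers are what the code
prints):

```r
library(irwall)

scene <- generate_scene(scene_spec(wood_type = "TW", noise_sd = 0.01, seed = 42))
scene$image
#> <hsi_image> 64 x 64 pixels x 476 bands (1800-850 cm^-1)

sel <- generate_selections(scene$truth, n_per_class = 90, seed = 42)
mrs <- build_mrs(list(image1 = scene$image), sel)
mrs
#> <mrs_library> 4 classes (fiber_G, fiber_S, ray_S, vessel_S); 90/90/90/90 pixels

res <- assign_pixels(scene$image, mrs, lumen_threshold = 0.90, tie_fraction = 0.01)
res
#> <label_map> 64 x 64 pixels; fiber_G=1346, fiber_S=1351, LUMEN=615, ray_S=256, vessel_S=528

round(evaluate_assignment(res$label_map, scene$truth)$per_class, 3)
#>  fiber_G  fiber_S    LUMEN    ray_S vessel_S
#>        1        1        1        1        1
```

Every class is recovered (boundary pixels included here; at higher noise the
interface pixels are the first to drop to "NA", as in real images). Now the
G-layer vs S-layer DAWN scan:

```r
m    <- pixel_matrix(scene$image)
labs <- as.vector(t(res$label_map$labels))
sets <- lapply(c("fiber_G", "fiber_S"), function(cl)
  class_spectra_set(cl, m[labs == cl, , drop = FALSE], scene$image$axis))
dawns   <- find_dawns(sets, alpha = 0.001, window_cm = 3)
passing <- subset(as.data.frame(dawns), passes & annotations != "unassigned")
passing[passing$sigma_cm %in% c(1736, 1506, 1336, 1316, 1236, 1200),
        c("sigma_cm", "p_adj", "annotations")]
#>  sigma_cm p_adj                                                annotations
#>      1736     0 hemicellulose/acetylated xylan (C=O stretch of acetyl ...)
#>      1506     0                       lignin (aromatic skeletal vibration)
#>      1336     0               crystalline cellulose (O-H in-plane bending)
#>      1316     0              crystalline cellulose (CH2 rocking vibration)
#>      1236     0 hemicellulose/acetylated xylan (acetyl and carboxyl ...)
#>      1200     0                        cellulose (OH in-plane deformation)
```

The scan recovers exactly the chemistry the generator seeded: the G-layer's
crystalline-cellulose double band (1,336/1,316 cm⁻¹) and 1,200 cm⁻¹ band,
the lignin band (1,506 cm⁻¹) it lacks, and the acetylated-xylan bands
(1,736/1,236 cm⁻¹) where S-layers absorb more.

A command-line wrapper over the same functions ships at
`inst/cli/irwall.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "irwall.R", package = "irwall"))')" \
  simulate --wood_type TW --seed 42 --out_dir scene/
```

with subcommands `simulate`, `assign`, `dawn`, `report`.

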