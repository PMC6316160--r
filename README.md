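# sersuptake

Quantifying nanoparticle uptake in single cells with SERS imaging — and
everything needed to characterize the probes that make it possible.

Thiophenol-functionalized gold nanospheres are strong, stable SERS
(surface-enhanced Raman spectroscopy) reporters: the phenylthiolate
monolayer chemisorbed on ~24 nm gold spheres emits a narrow analytical band
at 1078 cm⁻¹ (C–C anti-symmetric stretching). Raman-mapping a cell after
incubation with such probes turns internalized particle count into an
optical statistic, **I₁₀₇₈** — the 1078 cm⁻¹ band intensity of the
*sum-spectrum* over the cell body — which separates prostate tumor cells
(PC3, high and growing uptake) from normal prostate epithelium (PNT2,
uptake saturating by 2 h).

The package is tidyverse-native (tibbles in and out, pipe-friendly,
`tidy()`/`glance()`/`autoplot()` methods) and covers four analysis stages
plus their synthetic-data generators:

* **Particle morphometry** (`binarize()`, `label_regions()`,
  `region_properties()`, `classify_shape()`, `population_stats()`,
  `histogram_fwhm()`): Otsu thresholding, 8-connected labeling, and
  per-particle descriptors including the roundness
  `R = 4A / (π·d_max²)` (1 for a circle; spheres `R ≥ 0.85`, rods
  `R ≤ 0.6`), Feret diameters, solidity and the size-distribution FWHM.
* **UV-Vis quantification** (`find_lspr_peak()`, `fit_beer_lambert()`,
  `estimate_concentration()`, `stability_series()`,
  `aggregation_index()`): LSPR peak location (526 nm for these colloids),
  through-origin Beer–Lambert calibration, ageing stability, aggregation
  screening.
* **Enhancement-factor model** (`particle_geometry()`, `particle_mass()`,
  `surface_budget()`, `reference_number_density()`,
  `enhancement_factor()`, `ef_chain()`): the geometric chain
  `EF = (I_SERS/I_REF)·(N_REF/N_SERS)` counting SERS-active molecules from
  the gold surface per litre and the thiophenol monolayer footprint
  (ρ = 5.7×10⁻¹⁵ cm²).
* **Hyperspectral maps** (`read_map()`, `band_intensity()`,
  `reconstruct_image()`, `sum_spectrum()`, `compute_i1078()`,
  `summarize_uptake()`, `band_shift_table()`): band extraction with local
  linear baseline, SERS image reconstruction, the I₁₀₇₈ statistic and
  cell-line/time contrasts.
* **Generators** (`simulate_particle_image()`, `simulate_uvvis_spectrum()`,
  `simulate_tp_spectrum()`, `simulate_cell_map()`, `uptake_profile()`,
  `tp_band_table()`): every raw input with known ground truth and
  calibrated defaults (24 nm / FWHM 10.1 nm diameters, 3% rods, 526 nm
  LSPR, the thiophenol Raman/SERS band table with the 920 cm⁻¹ S–H band
  absent in SERS, and PNT2/PC3 uptake kinetics).

See the methods vignette (`vignettes/sers-uptake-methods.Rmd`) for the
models, assumptions and design decisions.

## Worked example

```r
library(sersuptake)
library(dplyr)

# --- particle population from a synthetic micrograph --------------------
spec <- particle_image_spec()                 # 512 px, 100 particles, 24 nm
g <- simulate_particle_image(spec, seed = 42)
recs <- g$image |> binarize() |> label_regions() |> region_properties()
population_stats(recs)
#> Particle population: n = 100
#>   mean equivalent diameter: 24.16 nm (histogram FWHM 8.98 nm)
#>   spherical (R >= 0.85): 97.0%   rods (R <= 0.6): 3.0%

# --- enhancement factor from a synthetic SERS/Raman pair ----------------
ef_chain(colloid_model(),
  i_sers = band_intensity(simulate_tp_spectrum("sers", default_sers_scale(),
                                               noise_sd = 0),
                          center = 1576, half_window = 20, mode = "area"),
  i_ref  = band_intensity(simulate_tp_spectrum("raman", 1, noise_sd = 0),
                          center = 1587, half_window = 20, mode = "area"))
#> SERS enhancement-factor chain
#>   V_NP = 7.24e-18 cm^3   m_NP = 1.4e-16 g   S_NP = 1.81e-11 cm^2
#>   N_NP = 2.1e+15 /L   S_T = 3.8e+04 cm^2/L
#>   molecules per NP = 3175   N_SERS = 6.67e+18 /L   N_REF = 4.43e+23 /L
#>   I_SERS/I_REF = 22.8   EF = 1.52e+06

# --- single-cell uptake contrast at 2 h (10 cells per line) -------------
res <- bind_rows(lapply(1:10, function(i) bind_rows(
  { c1 <- simulate_cell_map("PNT2", 2, seed = i)
    compute_i1078(c1$map, c1$mask, cell_id = i, cell_line = "PNT2", time_h = 2) },
  { c2 <- simulate_cell_map("PC3", 2, seed = 100 + i)
    compute_i1078(c2$map, c2$mask, cell_id = i, cell_line = "PC3", time_h = 2) })))
summarize_uptake(res)
#> Uptake summary (I1078, counts/s)
#> # A tibble: 2 × 6
#>   cell_line time_h  mean    sd   sem n_cells
#>   <chr>      <dbl> <dbl> <dbl> <dbl>   <int>
#> 1 PC3            2 1058. 125.   39.5      10
#> 2 PNT2           2  279.  34.5  10.9      10
#>
#> PC3 vs PNT2 percent excess
#> # A tibble: 1 × 4
#>   time_h mean_pc3 mean_pnt2 percent_excess
#>    <dbl>    <dbl>     <dbl>          <dbl>
#> 1      2    1058.      279.           279.
```

The particle block recovers the injected population (mean 24 nm, 97%
spherical); the EF chain reproduces the geometric quantities
(V ≈ 7.24×10⁻¹⁸ cm³, 3175 molecules per particle, EF ≈ 1.5×10⁶); and the
2 h uptake contrast lands near the calibrated 260% excess (279% here with
only 10 cells per line — the Monte-Carlo scatter shrinks at the standard
30 cells).

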