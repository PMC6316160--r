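---
title: "Methods: SERS nanoprobe characterization and single-cell uptake quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SERS nanoprobe characterization and single-cell uptake quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersuptake)
library(dplyr)
```

# The scientific problem

Thiophenol-functionalized gold nanospheres are bright, stable SERS
(surface-enhanced Raman spectroscopy) probes: a phenylthiolate self-assembled
monolayer chemisorbed on ~24 nm gold spheres reports its presence through a
narrow, strong band at 1078 cm⁻¹ (C–C anti-symmetric stretching). Mapping a
cell with a confocal Raman microscope after incubating it with such probes
turns nanoparticle uptake into a quantitative optical measurement: the more
particles a cell internalizes, the stronger the 1078 cm⁻¹ signal summed over
its body. Prostate tumor cells (PC3) internalize far more of these probes
than normal prostate epithelium (PNT2), and with different kinetics, so the
uptake statistic separates the two lines.

This package implements the complete computational side of such a study —
particle morphometry from micrographs, UV-Vis colloid quantification, the
geometric enhancement-factor model, and hyperspectral map processing — plus
synthetic-data generators that emulate each raw input with known ground
truth, so every stage is testable end-to-end without instrument data.

# Particle morphometry

Micrographs show particles as dark objects on a bright support. The analysis
chain is: Otsu auto-thresholding (`binarize()`), 8-connected component
labeling with small-region and border filtering (`label_regions()`), and
per-region descriptors (`region_properties()`). The central shape statistic
is the roundness

$$R = \frac{4A}{\pi d_{\max}^2},$$

where $A$ is the particle area and $d_{\max}$ its major axis. $R = 1$ for a
circle and falls as $b/a$ for an ellipse with semi-axes $a > b$. Particles
with $R \ge 0.85$ are classified spherical, $R \le 0.6$ as rods, the rest
intermediate (`classify_shape()`).

Estimator choices where the field leaves latitude:

* **$d_{\max}$** is the maximum Feret (caliper) diameter, measured as the
  maximum pairwise distance over the convex hull of pixel centers. Centers
  rather than pixel corners keep $R$ of a rasterized disk at 1 within
  discretization error instead of biasing it low; a moment-matched-ellipse
  major axis is available via `major_axis = "ellipse"`.
* **Perimeter and solidity** use the convex hull of the pixel *corner*
  points (the Minkowski sum of the center hull with the unit pixel square),
  which guarantees solidity ≤ 1. Note that the pixel union of a rasterized
  disk genuinely fills only ~97% of its convex hull at radius 30 px.
* **Roundness allowance**: rasterization can push $R$ slightly above 1; an
  allowance of 0.05 is tolerated before anything is flagged.
* **Labeling** is 8-connected (run-based union-find); `min_area` defaults to
  9 px and border-touching regions are excluded, since partial particles
  bias population statistics.
* Single-pixel or collinear regions get `degenerate = TRUE` with finite
  fields rather than an error.

`population_stats()` reports per-descriptor mean/median/min/max/sd, the
equivalent-diameter histogram (2 nm bins by default), its FWHM, and the
shape fractions. The histogram FWHM is measured between the two half-maximum
crossings obtained by linear interpolation between adjacent bin centers; a
single occupied bin returns one bin width by convention, and a side that
never crosses half maximum is an error rather than a guess. Whether a
population's "mean diameter" means equivalent or Feret diameter is
ambiguous in common usage; both are reported (`mean_diameter`,
`mean_feret_max`) and the equivalent diameter is primary.

The synthetic micrograph generator (`simulate_particle_image()`) draws
anti-aliased disks — Gaussian diameters, mean 24 nm, FWHM 10.1 nm, i.e.
sd = 10.1/2.3548 nm — with a deterministic 3% rod fraction (equal-area
ellipses, aspect 3) placed without overlap and fully interior, so recovered
counts can be compared to truth exactly. A reported bimodal shoulder in real
size distributions is not emulated by default. Defaults (512×512 px at
1 nm/px, 100 particles, foreground 50 / background 200, read-noise sd 8)
give the sharp contrast regime in which Otsu thresholding is essentially
unbiased; the population-recovery checks pool 20 frames (2000 particles).

# UV-Vis quantification

The LSPR band of well-dispersed ~24 nm gold spheres sits at 526 nm.
`find_lspr_peak()` returns the in-window absorbance maximum refined by a
three-point parabola (spectra are sampled on an integer-nm grid); a maximum
on the window edge raises a truncation warning instead of silently
reporting it. `fit_beer_lambert()` fits absorbance against concentration
constrained through the origin — zero gold, zero plasmon — and reports
$R^2 = 1 - SS_{res}/\sum y^2$ against that through-origin model;
`estimate_concentration()` inverts the slope. `stability_series()` tracks
concentration-normalized LSPR height over ageing time and flags a colloid
stable when no point drops more than 10% below the first measurement (a
design choice; ageing data are usually judged by eye). `aggregation_index()`
is the ratio A(650 nm)/A(λ_LSPR): aggregation red-shifts plasmon strength
into a shoulder well above the monomer band, and 650 nm sits between the
526 nm monomer position and typical aggregate bands. The index is ~0.03 for
the default synthetic spectrum, 1 for a flat spectrum, and grows
monotonically with the generator's shoulder amplitude.

The synthetic UV-Vis model is a pseudo-Voigt LSPR band (FWHM 60 nm) plus a
weak interband tail rising toward the UV and an optional aggregation
shoulder, all scaled linearly by concentration — Beer–Lambert by
construction, so calibration tests have an exact truth.

# The geometric enhancement-factor model

The SERS enhancement factor compares per-molecule signal on the metal
against bulk solution:

$$EF = \frac{I_{SERS}}{I_{REF}} \cdot \frac{N_{REF}}{N_{SERS}},$$

with integrated band areas taken at 1576 cm⁻¹ (SERS) and 1587 cm⁻¹ (Raman
reference), both exposure-normalized. $N_{SERS}$ is counted geometrically:
for spheres of radius $r$, $V = \tfrac43\pi r^3$, $m = V D_{Au}$
($D_{Au} = 19.32$ g/cm³), $S = 4\pi r^2$; the gold mass per litre divided by
$m$ gives the particle number density, times $S$ the total gold surface
$S_T$ per litre; dividing surfaces by the thiophenol equatorial cross
section $\rho = 5.7\times10^{-15}$ cm² (a fixed constant from quantum-
chemical structure inspection, not computed here) yields molecules per
particle ($\approx 3175$ for $r = 12$ nm) and $N_{SERS} = S_T/\rho$.
$N_{REF}$ comes from the molarity of the 10 wt% thiophenol/ethanol
reference; since the solution density is not tabulated, ideal mixing of the
component densities (1.0766 and 0.789 g/mL) is assumed, giving
$4.43\times10^{23}$ molecules/L.

Two deliberate conventions: the monolayer count per particle is *reported*
rounded to the nearest integer but all downstream math uses the unrounded
value; and the colloid gold mass concentration is an explicit input —
batches differ — with the default (0.294 g/L) chosen as the value at which
the default geometry yields $S_T = 3.8\times10^4$ cm²/L. Internally the
chain works exclusively in cm, g, L and counts/s; units convert only at I/O
boundaries.

The synthetic Raman/SERS pair is calibrated by inverting the EF definition:
the default SERS-to-Raman amplitude ratio (`default_sers_scale()`, ≈ 22.6)
is the one that makes the default model reproduce the enhancement factor of
$1.5\times10^6$ measured for this probe chemistry. The end-to-end check then
regenerates both traces, measures the two band areas with the package's own
band-intensity extractor and runs the chain — so window/baseline handling,
not just algebra, is exercised.

# Hyperspectral maps and the uptake statistic

Maps are long-format tibbles (`x_um`, `y_um`, `wavenumber_cm1`,
`intensity`) sharing one axis and one exposure (default 2.0 µm step, 3 s
exposure, 600–1800 cm⁻¹ at 2 cm⁻¹). `band_intensity()` draws a straight
baseline between the intensities at the ends of a ±20 cm⁻¹ window around
the band, subtracts it, and returns the maximum (height mode, default) or
trapezoidal integral (area mode), divided by exposure. With a 10 cm⁻¹-wide
band, the endpoint baseline sitting on Lorentzian tails costs ~3% of the
height — accepted as the price of robustness against fluorescence
backgrounds; no global baseline model is attempted for a single analytical
band.

The uptake statistic $I_{1078}$ of a cell is the band intensity of its
**sum-spectrum**: the pointwise sum of all spectra inside the cell-body
mask (`sum_spectrum()`, `compute_i1078()`). Height was chosen as the default
mode because the statistic is described as a peak intensity; area is
available, and for area mode the statistic commutes exactly with summation
(the trapezoid and endpoint-baseline operators are linear), which the tests
assert. For height mode that equivalence deliberately is *not* asserted —
the height of a sum is not the sum of heights. Negative baseline-corrected
values are floored at zero and flagged, keeping the statistic a valid
abundance proxy. Masks are user-supplied 0/1 grids (in practice drawn from
a co-registered visible image, which is out of scope); the full map is the
default mask.

`summarize_uptake()` aggregates per-cell results into group mean/sd/sem and
computes the tumor-vs-normal contrast as percent excess,
$(\bar I_{PC3} - \bar I_{PNT2})/\bar I_{PNT2} \times 100$ — the standard
reading of "X% higher"; the alternative ratio reading ($A/B \times 100$)
is rejected, and the generator uses the same convention, so recovery tests
are internally consistent either way.

# The synthetic cell-map generator

`simulate_cell_map()` emulates the measured object, not the microscope: an
elliptical cell mask (semi-axes ~30–36% of the 30×30 grid, jittered ±10%
per cell), a per-cell expected total load proportional to the uptake
profile multiplier and the mask area, lognormal per-cell load jitter with
coefficient of variation 0.15 (a modest biological variability consistent
with n = 30 averaging), pseudo-Voigt thiophenol SERS bands scaled per
pixel, a gently sloping baseline, and additive Gaussian noise calibrated so
the per-pixel SNR at 1078 cm⁻¹ is ≈ 20 at unit load (Poisson-like shot
noise is available behind a flag). The spatial phenotypes follow the two
observed uptake patterns: normal cells concentrate their small load in one
or two compact spots (≥ 90% of mask pixels carry no particle signal) while
tumor cells disperse it homogeneously (≥ 90% carry signal).

`uptake_profile()` holds the calibrated kinetics: PNT2 saturates by 2 h
(multiplier 1 at 2, 4 and 6 h); PC3 multipliers 3.6 at 2 h and 10.5 at 6 h
are the inversions of the 260% and 950% percent-excess contrasts, and the
4 h value (7.05) is their linear interpolation because no 4 h contrast is
tabulated. Ground truth ($I_{1078}$ = noise-free sum of per-pixel 1078-band
heights over the mask) is returned with every cube, so the pipeline's
estimate can be compared against the injected value (it recovers it to
within ~3%, the window-baseline bias above).

What the generator does *not* emulate: cosmic-ray spikes, detector etaloning,
focus drift, cell autofluorescence structure, particle aggregation into
hot-spots, or registration error between visible and Raman images. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated noise model, not robustness to every instrumental artifact.

Raman-vs-SERS band comparison (`band_shift_table()`) detects each band pair
inside a common window centered midway between the two nominal positions
(half-width 15 cm⁻¹; a common window makes identical traces give exactly
zero shift). A band is called present only if its baseline-corrected height
exceeds 3× the local noise *and* 1% of the spectrum's strongest band — the
relative floor keeps absence calls stable on noise-free synthetic traces
whose neighbouring-band tails are tiny but nonzero. On default synthetic
pairs the S–H bend at 920 cm⁻¹ is reported absent in SERS (the S–H bond is
cleaved on chemisorption) and the C–C anti-symmetric shift is detected at
−18 cm⁻¹, the value implied by the band table's printed positions; reported
textual shifts of −12/−6 cm⁻¹ conflict with those positions and this
package follows the table without arbitrating.

# Reproducibility and problem sizes

Every generator is a pure function of its specification plus an integer
seed. The recovery studies use 20 frames × 100 particles (2000 particles)
for morphometry and 30 cells per line and time for uptake — the stated
replication of the underlying experiments — which keeps the full test suite
and the acceptance script in the minutes range on a single core. At 30
cells per group the Monte-Carlo standard error of a percent-excess contrast
is ~5%, so recovered contrasts scatter by a few percent around the injected
260%/950% values; tests allow 10% relative.

# Known limitations

* Watershed splitting of touching particles is not implemented; the
  generator guarantees non-overlap, and real agglomerated samples would
  need it.
* The enhancement-factor chain assumes monodisperse spheres at the mean
  radius; polydispersity corrections (surface-weighted radii) are not
  applied.
* Absolute uptake values are instrument-relative; only within-study
  contrasts are meaningful, which is why the acceptance checks target the
  percent-excess statistics rather than absolute $I_{1078}$.
* Multivariate decomposition (PCA/MCR) of cubes, visible/Raman image
  registration and cytotoxicity statistics are out of scope.
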