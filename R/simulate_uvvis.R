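#' Simulate a gold-colloid UV-Vis extinction spectrum
#'
#' Models the absorbance of a thiophenol-functionalized gold nanosphere
#' colloid as Beer-Lambert scaling of a fixed spectral shape: a pseudo-Voigt
#' localized surface plasmon resonance (LSPR) band centered at 526 nm (the
#' position characteristic of ~20-25 nm spheres), a weak interband absorption
#' tail rising toward the UV, and an optional aggregation shoulder at longer
#' wavelengths. Absorbance is strictly proportional to concentration through
#' the origin when noise is zero.
#'
#' @param concentration Gold molar concentration, mol/L (>= 0).
#' @param wavelength Wavelength axis, nm (default 300-800 at 1 nm).
#' @param lspr_center LSPR band center, nm.
#' @param lspr_fwhm LSPR band full width at half maximum, nm.
#' @param extinction_coeff Peak decadic extinction per (mol/L) of Au at the
#'   LSPR maximum, AU L/mol.
#' @param interband Relative amplitude of the UV interband tail (fraction of
#'   the LSPR peak height; decays with a 90 nm constant from 300 nm).
#' @param shoulder Relative amplitude of an aggregation shoulder (Gaussian at
#'   `shoulder_center`); 0 for a well-dispersed colloid.
#' @param shoulder_center,shoulder_fwhm Aggregate band position and width, nm.
#' @param noise_sd Additive Gaussian noise on absorbance, AU.
#' @param seed Optional integer seed.
#' @return A tibble with columns `wavelength` (nm) and `absorbance` (AU).
#' @export
#' @examples
#' sp <- simulate_uvvis_spectrum(2e-4)
#' sp$wavelength[which.max(sp$absorbance)]  # 526
simulate_uvvis_spectrum <- function(concentration,
                                    wavelength = seq(300, 800, by = 1),
                                    lspr_center = 526,
                                    lspr_fwhm = 60,
                                    extinction_coeff = 4000,
                                    interband = 0.3,
                                    shoulder = 0,
                                    shoulder_center = 650,
                                    shoulder_fwhm = 120,
                                    noise_sd = 0,
                                    seed = NULL) {
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration < 0) {
    abort("`concentration` must be a single non-negative mol/L value.",
          class = "sersuptake_concentration_error")
  }
  check_axis(wavelength, "wavelength")
  shape <- pseudo_voigt(wavelength, lspr_center, lspr_fwhm, eta = 0.5) +
    interband * exp(-(wavelength - min(wavelength)) / 90) +
    shoulder * exp(-4 * log(2) * ((wavelength - shoulder_center) / shoulder_fwhm)^2)
  a <- concentration * extinction_coeff * shape
  if (noise_sd > 0) {
    a <- a + with_seed_or_not(seed, rnorm(length(wavelength), 0, noise_sd))
  }
  tibble(wavelength = as.numeric(wavelength), absorbance = a)
}
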