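#' Default wavenumber axis for synthetic Raman/SERS spectra
#'
#' 600-1800 cm^-1 at 2 cm^-1 spacing, covering every thiophenol band in
#' [tp_band_table()] with generous margins for local baseline windows.
#'
#' @return Numeric vector of wavenumbers, cm^-1.
#' @export
default_wavenumber_axis <- function() seq(600, 1800, by = 2)

#' Simulate a thiophenol Raman or SERS spectrum
#'
#' Builds the synthetic point spectrum as a sum of pseudo-Voigt bands at the
#' positions of [tp_band_table()] (Raman column for `mode = "raman"`, SERS
#' column for `mode = "sers"`; the 920 cm^-1 S-H bend is dropped in SERS mode
#' because its column is empty), plus a polynomial baseline and optional
#' additive Gaussian noise. Intensities are counts: the band-plus-baseline
#' rate is multiplied by the exposure time, and noise is applied on counts.
#'
#' @param mode `"raman"` or `"sers"`.
#' @param scale Overall band amplitude scale in counts/s (>= 0). The height of
#'   the strongest band (relative amplitude 1) equals `scale` counts/s.
#' @param axis Strictly increasing wavenumber axis (cm^-1).
#' @param band_table Band table as returned by [tp_band_table()].
#' @param baseline Polynomial baseline coefficients in counts/s, lowest order
#'   first, evaluated in `(wavenumber - 1200)/600` to keep coefficients O(1).
#' @param noise_sd Additive Gaussian noise standard deviation on counts.
#' @param exposure Exposure time, s.
#' @param eta Pseudo-Voigt Lorentzian fraction shared by all bands.
#' @param seed Optional integer seed; identical seeds give identical spectra.
#' @return A spectrum tibble (see [new_spectrum()]).
#' @export
#' @examples
#' sp <- simulate_tp_spectrum("sers", scale = 100, noise_sd = 0, seed = 1)
simulate_tp_spectrum <- function(mode = c("raman", "sers"),
                                 scale = 1,
                                 axis = default_wavenumber_axis(),
                                 band_table = tp_band_table(),
                                 baseline = 0,
                                 noise_sd = 0,
                                 exposure = 3,
                                 eta = 0.5,
                                 seed = NULL) {
  if (!is.character(mode) || !all(mode %in% c("raman", "sers"))) {
    abort("`mode` must be \"raman\" or \"sers\".",
          class = "sersuptake_mode_error")
  }
  mode <- match.arg(mode)
  check_axis(axis, "axis")
  stopifnot(scale >= 0, noise_sd >= 0)

  rate <- tp_band_sum(axis, mode, band_table, eta) * scale +
    eval_baseline(axis, baseline)
  counts <- rate * exposure
  if (noise_sd > 0) {
    counts <- counts + with_seed_or_not(seed, rnorm(length(axis), 0, noise_sd))
  }
  new_spectrum(axis, counts, exposure = exposure)
}

# Noise-free unit band sum (counts/s for scale 1) for a mode.
tp_band_sum <- function(axis, mode, band_table = tp_band_table(), eta = 0.5) {
  pos <- if (mode == "raman") band_table$raman_cm1 else band_table$sers_cm1
  keep <- !is.na(pos)
  rowsum <- numeric(length(axis))
  for (i in which(keep)) {
    rowsum <- rowsum + band_table$relative_amplitude[i] *
      pseudo_voigt(axis, pos[i], band_table$width_fwhm[i], eta)
  }
  rowsum
}

eval_baseline <- function(axis, coefs) {
  z <- (axis - 1200) / 600
  out <- numeric(length(axis))
  for (k in seq_along(coefs)) out <- out + coefs[k] * z^(k - 1)
  out
}
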