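# Shared numerical helpers and the spectrum container.

#' Construct a spectrum tibble
#'
#' Spectra are plain tibbles with a strictly increasing abscissa column and an
#' `intensity` column; the acquisition exposure (seconds) travels along as the
#' `exposure_s` attribute so that downstream band intensities can be
#' exposure-normalized without extra bookkeeping.
#'
#' @param wavenumber Strictly increasing Raman shift axis, cm^-1.
#' @param intensity Detector counts, same length as `wavenumber`.
#' @param exposure Acquisition time in seconds (> 0).
#' @return A tibble with columns `wavenumber`, `intensity` and attribute
#'   `exposure_s`.
#' @export
new_spectrum <- function(wavenumber, intensity, exposure = 3) {
  check_axis(wavenumber, "wavenumber")
  if (length(intensity) != length(wavenumber)) {
    abort("`intensity` and `wavenumber` must have the same length.",
          class = "sersuptake_length_error")
  }
  if (!is.numeric(exposure) || length(exposure) != 1L || exposure <= 0) {
    abort("`exposure` must be a single positive number of seconds.",
          class = "sersuptake_exposure_error")
  }
  out <- tibble(wavenumber = as.numeric(wavenumber),
                intensity = as.numeric(intensity))
  attr(out, "exposure_s") <- as.numeric(exposure)
  out
}

#' Exposure metadata of a spectrum or map
#'
#' @param x A spectrum or hyperspectral map tibble.
#' @return Exposure time in seconds.
#' @export
exposure_of <- function(x) {
  e <- attr(x, "exposure_s", exact = TRUE)
  if (is.null(e)) {
    abort("Object carries no `exposure_s` attribute.",
          class = "sersuptake_exposure_error")
  }
  e
}

check_axis <- function(x, name = "axis") {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x) || any(diff(x) <= 0)) {
    abort(paste0("`", name, "` must be a strictly increasing numeric vector."),
          class = "sersuptake_axis_error")
  }
  invisible(x)
}

# Pseudo-Voigt profile, unit height at the center. `eta` mixes Lorentzian and
# Gaussian components that share one FWHM, the common phenomenological line
# shape for Raman bands.
pseudo_voigt <- function(x, center, fwhm, eta = 0.5) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1)
  hwhm <- fwhm / 2
  lor <- hwhm^2 / ((x - center)^2 + hwhm^2)
  gau <- exp(-4 * log(2) * ((x - center) / fwhm)^2)
  eta * lor + (1 - eta) * gau
}

# Trapezoidal integral on an irregular grid.
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Run `expr` under a fixed RNG state when `seed` is given, without disturbing
# the caller's stream otherwise.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(as.integer(seed), expr)
}

# Linear interpolation of y(x) at x0 (x strictly increasing).
interp1 <- function(x, y, x0) {
  stats::approx(x, y, xout = x0, rule = 1)$y
}
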