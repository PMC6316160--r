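# UV-Vis quantification of gold colloids: LSPR peak detection, through-origin
# Beer-Lambert calibration, ageing stability and an aggregation index.

#' Locate the LSPR band maximum
#'
#' Finds the wavelength of maximum absorbance inside a search window, refined
#' by parabolic interpolation through the three samples around the discrete
#' maximum (absorbance positions are acquired on an integer-nm grid; the
#' parabola recovers sub-sample peak positions for smooth bands).
#'
#' @param spectrum Tibble with `wavelength` (nm, increasing) and `absorbance`.
#' @param search_window Length-2 numeric window in nm, default `c(400, 700)`.
#' @return One-row tibble: `lambda_max` (nm), `a_max` (AU), `edge` (`TRUE`
#'   when the maximum sits on the window boundary, where the band may be
#'   truncated; a warning of class `sersuptake_edge_warning` is also raised).
#' @export
find_lspr_peak <- function(spectrum, search_window = c(400, 700)) {
  stopifnot(is.data.frame(spectrum),
            all(c("wavelength", "absorbance") %in% names(spectrum)))
  wl <- spectrum$wavelength; a <- spectrum$absorbance
  check_axis(wl, "wavelength")
  if (search_window[1] < min(wl) || search_window[2] > max(wl)) {
    abort("`search_window` must lie within the wavelength axis.",
          class = "sersuptake_window_error")
  }
  inw <- which(wl >= search_window[1] & wl <= search_window[2])
  i <- inw[which.max(a[inw])]
  edge <- i == inw[1] || i == inw[length(inw)]
  if (edge) {
    warn("LSPR maximum lies on the search-window edge; the band may be truncated.",
         class = "sersuptake_edge_warning")
    lam <- wl[i]; amax <- a[i]
  } else {
    # parabolic refinement through (i-1, i, i+1)
    y1 <- a[i - 1]; y2 <- a[i]; y3 <- a[i + 1]
    x1 <- wl[i - 1]; x2 <- wl[i]; x3 <- wl[i + 1]
    denom <- (x1 - x2) * (x1 - x3) * (x2 - x3)
    A <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / denom
    B <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / denom
    if (A < 0) {
      lam <- -B / (2 * A)
      amax <- A * lam^2 + B * lam + (y2 - A * x2^2 - B * x2)
    } else {
      lam <- x2; amax <- y2
    }
  }
  tibble(lambda_max = lam, a_max = amax, edge = edge)
}

#' Through-origin Beer-Lambert calibration
#'
#' Least-squares slope of peak absorbance against concentration constrained
#' through the origin (zero gold gives zero plasmon absorbance), with the
#' coefficient of determination computed against the through-origin model
#' (`R^2 = 1 - SS_res / sum(y^2)`).
#'
#' @param concentrations Standard concentrations, mol/L (non-negative, not
#'   all zero, at least two distinct values recommended).
#' @param peak_absorbances LSPR peak absorbances of the standards, AU.
#' @return An object of class `"beer_lambert_fit"` with elements `slope`
#'   (AU per mol/L), `r_squared` and `n_points`.
#' @export
fit_beer_lambert <- function(concentrations, peak_absorbances) {
  c0 <- as.numeric(concentrations); a0 <- as.numeric(peak_absorbances)
  if (length(c0) < 2 || length(c0) != length(a0)) {
    abort("Need >= 2 matched (concentration, absorbance) points.",
          class = "sersuptake_fit_error")
  }
  if (any(c0 < 0) || all(c0 == 0)) {
    abort("Concentrations must be non-negative and not all zero.",
          class = "sersuptake_fit_error")
  }
  if (length(unique(c0)) < 2) {
    abort("Calibration is rank-deficient: all standards share one concentration.",
          class = "sersuptake_fit_error")
  }
  slope <- sum(c0 * a0) / sum(c0^2)
  ss_res <- sum((a0 - slope * c0)^2)
  ss_tot <- sum(a0^2)
  structure(list(slope = slope,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_points = length(c0)),
            class = "beer_lambert_fit")
}

#' @export
print.beer_lambert_fit <- function(x, ...) {
  cat(sprintf("Beer-Lambert fit through the origin: slope = %.4g AU/(mol/L), R^2 = %.5f, n = %d\n",
              x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' @rdname fit_beer_lambert
#' @param x A `beer_lambert_fit`.
#' @param ... Unused.
#' @export
tidy.beer_lambert_fit <- function(x, ...) {
  tibble(term = "slope", estimate = x$slope)
}

#' @rdname fit_beer_lambert
#' @export
glance.beer_lambert_fit <- function(x, ...) {
  tibble(slope = x$slope, r_squared = x$r_squared, n_points = x$n_points)
}

#' Estimate gold concentration from a peak absorbance
#'
#' Inverts the Beer-Lambert calibration: `concentration = a_max / slope`.
#'
#' @param a_max Peak absorbance, AU.
#' @param fit A [fit_beer_lambert()] object.
#' @return Concentration in mol/L.
#' @export
estimate_concentration <- function(a_max, fit) {
  stopifnot(inherits(fit, "beer_lambert_fit"))
  if (!is.finite(fit$slope) || fit$slope <= 0) {
    abort("Calibration slope must be positive to invert.",
          class = "sersuptake_fit_error")
  }
  a_max / fit$slope
}

#' Colloid ageing-stability series
#'
#' Concentration-normalized LSPR peak height as a function of ageing time. A
#' colloid is flagged stable when the relative drop from the first point
#' never exceeds `drop_threshold` at any later time.
#'
#' @param spectra List of UV-Vis spectrum tibbles (see
#'   [simulate_uvvis_spectrum()] for the format).
#' @param days Numeric acquisition times in days, one per spectrum.
#' @param reference_concentration Concentration used to normalize heights,
#'   mol/L.
#' @param drop_threshold Maximum tolerated relative drop (default 0.10).
#' @param search_window Passed to [find_lspr_peak()].
#' @return A tibble `(day, a_max, normalized_absorbance)` ordered by day,
#'   with attribute `stable` (logical verdict).
#' @export
stability_series <- function(spectra, days, reference_concentration,
                             drop_threshold = 0.10,
                             search_window = c(400, 700)) {
  stopifnot(length(spectra) >= 1, length(spectra) == length(days),
            reference_concentration > 0)
  pk <- purrr::map_dbl(spectra, ~ find_lspr_peak(.x, search_window)$a_max)
  out <- tibble(day = as.numeric(days), a_max = pk,
                normalized_absorbance = pk / reference_concentration)
  out <- arrange(out, .data$day)
  drops <- 1 - out$normalized_absorbance / out$normalized_absorbance[1]
  attr(out, "stable") <- all(drops <= drop_threshold)
  out
}

#' Is an ageing series stable?
#'
#' @param series Result of [stability_series()].
#' @return Logical verdict.
#' @export
is_stable <- function(series) {
  isTRUE(attr(series, "stable", exact = TRUE))
}

#' Aggregation index of a colloid spectrum
#'
#' Ratio of the absorbance at an aggregate-sensitive wavelength (default
#' 650 nm, between the ~526 nm monomer LSPR and typical aggregate bands) to
#' the LSPR peak absorbance. Near 0 for a well-dispersed colloid; grows
#' monotonically as a red-shifted aggregation shoulder develops; 1 for a flat
#' spectrum.
#'
#' @param spectrum UV-Vis spectrum tibble.
#' @param aggregate_wavelength Probe wavelength, nm.
#' @param search_window LSPR search window, nm.
#' @return Dimensionless index.
#' @export
aggregation_index <- function(spectrum, aggregate_wavelength = 650,
                              search_window = c(400, 700)) {
  wl <- spectrum$wavelength
  if (aggregate_wavelength < min(wl) || aggregate_wavelength > max(wl)) {
    abort("Spectrum does not cover the aggregate probe wavelength.",
          class = "sersuptake_window_error")
  }
  pk <- find_lspr_peak(spectrum, search_window)
  a650 <- interp1(wl, spectrum$absorbance, aggregate_wavelength)
  a650 / pk$a_max
}
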