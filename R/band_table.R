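#' Thiophenol Raman/SERS band table
#'
#' Reference table of the principal thiophenol normal modes in the
#' 900-1600 cm^-1 range, with the liquid-phase Raman position and the
#' position of the corresponding band of the chemisorbed phenylthiolate
#' monolayer (SERS). The S-H in-plane bend at 920 cm^-1 has no SERS
#' counterpart: chemisorption on gold cleaves the S-H bond, so the mode
#' vanishes from the monolayer spectrum.
#'
#' Relative amplitudes are phenomenological defaults for the synthetic
#' generators: the b1 C-C stretching modes at 1078 and 1576 cm^-1 dominate
#' the SERS trace (surface selection rules favour modes polarized along the
#' molecular axis standing normal to the metal), with 1078 >= 1576 > all
#' others.
#'
#' @param width_fwhm Band full width at half maximum in cm^-1 applied to all
#'   rows (default 10; the plasmon-narrowed bands are only a few cm^-1 to
#'   ~10 cm^-1 wide).
#' @return A tibble with columns `raman_cm1`, `sers_cm1` (NA where the band
#'   is absent), `relative_amplitude`, `width_fwhm`, `symmetry`, `label`.
#' @export
#' @examples
#' tp_band_table()
tp_band_table <- function(width_fwhm = 10) {
  stopifnot(width_fwhm > 0)
  tibble(
    raman_cm1 = c(920, 1003, 1028, 1096, 1122, 1161, 1184, 1587),
    sers_cm1  = c(NA, 1002, 1027, 1078, 1117, 1159, 1182, 1576),
    relative_amplitude = c(0.30, 0.55, 0.35, 1.00, 0.20, 0.25, 0.25, 0.90),
    width_fwhm = width_fwhm,
    symmetry = c(NA, "a1", "a1", "b1", NA, "b1", "a1", "b1"),
    label = c(
      "S-H in-plane bending",
      "ring out-of-plane deformation / C-H out-of-plane bending",
      "ring in-plane deformation / C-C symmetric stretching",
      "C-C anti-symmetric stretching",
      "unassigned",
      "C-H in-plane bending",
      "C-H in-plane bending",
      "C-C symmetric stretching"
    )
  )
}
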