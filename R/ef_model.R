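# Geometric surface-packing model of the SERS enhancement factor:
#   EF = (I_SERS / I_REF) * (N_REF / N_SERS)
# with N_SERS counted from the gold surface available per litre of colloid and
# the monolayer footprint of thiophenol, and N_REF from the molarity of the
# neat reference solution. Internal unit system: cm, g, L, counts/s.

AVOGADRO <- 6.02214076e23

#' Colloid model parameters
#'
#' Physical constants and defaults of the functionalized-gold-nanosphere
#' colloid used throughout the enhancement-factor chain. The thiophenol
#' equatorial Van der Waals cross-section `rho` is a fixed input constant
#' (5.7e-15 cm^2). The default colloid mass concentration (0.294 g Au / L)
#' is the value at which the default geometry yields a total gold surface of
#' 3.8e4 cm^2 per litre; it is an explicit model input because colloid batches
#' differ.
#'
#' @param r_np Particle radius, cm (default 12e-7 cm = 12 nm, half the 24 nm
#'   mean diameter).
#' @param d_au Gold density, g/cm^3 (19.32).
#' @param mass_concentration Gold mass per litre of colloid, g/L.
#' @param rho Thiophenol equatorial cross-section, cm^2.
#' @param tp_weight_fraction Weight fraction of thiophenol in the reference
#'   solution (10 wt% in ethanol).
#' @param tp_molar_mass Thiophenol molar mass, g/mol (110.18).
#' @param tp_density,solvent_density Component densities, g/mL (1.0766 and
#'   0.789 for thiophenol and ethanol).
#' @return A list of class `"colloid_model"`.
#' @export
colloid_model <- function(r_np = 12e-7,
                          d_au = 19.32,
                          mass_concentration = 0.294,
                          rho = 5.7e-15,
                          tp_weight_fraction = 0.10,
                          tp_molar_mass = 110.18,
                          tp_density = 1.0766,
                          solvent_density = 0.789) {
  stopifnot(r_np > 0, d_au > 0, mass_concentration > 0, rho > 0,
            tp_weight_fraction > 0, tp_weight_fraction < 1,
            tp_molar_mass > 0, tp_density > 0, solvent_density > 0)
  structure(as.list(environment()), class = "colloid_model")
}

#' Sphere volume and surface of a nanoparticle
#'
#' `V = (4/3) pi r^3`, `S = 4 pi r^2`; the identity `3V/S = r` holds exactly.
#'
#' @param r_np Particle radius in cm (> 0).
#' @return One-row tibble with `v_np` (cm^3) and `s_np` (cm^2).
#' @export
#' @examples
#' particle_geometry(12e-7)  # ~7.24e-18 cm^3, ~1.81e-11 cm^2
particle_geometry <- function(r_np) {
  if (!is.numeric(r_np) || any(r_np <= 0)) {
    abort("`r_np` must be a positive radius in cm.",
          class = "sersuptake_physical_error")
  }
  tibble(v_np = 4 / 3 * pi * r_np^3, s_np = 4 * pi * r_np^2)
}

#' Mass of a single nanoparticle
#'
#' @param v_np Particle volume, cm^3.
#' @param d_au Gold density, g/cm^3.
#' @return Mass in grams.
#' @export
particle_mass <- function(v_np, d_au = 19.32) {
  stopifnot(all(v_np > 0), all(d_au > 0))
  v_np * d_au
}

#' Gold surface budget and SERS-active molecule count per litre
#'
#' Number density of particles `N_NP = mass_concentration / m_NP`, total gold
#' surface per litre `S_T = S_NP * N_NP`, thiophenol molecules packed as a
#' monolayer on one particle `S_NP / rho` (reported rounded to the nearest
#' integer; the unrounded value is kept for downstream math), and the number
#' of SERS-active bound molecules per litre `N_SERS = S_T / rho`.
#'
#' @param mass_concentration Gold mass per litre of colloid, g/L.
#' @param m_np Single-particle mass, g.
#' @param s_np Single-particle surface, cm^2.
#' @param rho Molecular equatorial cross-section, cm^2.
#' @return One-row tibble: `n_np_per_l`, `s_t_cm2_per_l`, `molecules_per_np`
#'   (integer), `molecules_per_np_exact`, `n_sers_per_l`.
#' @export
surface_budget <- function(mass_concentration, m_np, s_np, rho = 5.7e-15) {
  stopifnot(mass_concentration > 0, m_np > 0, s_np > 0, rho > 0)
  n_np <- mass_concentration / m_np
  s_t <- s_np * n_np
  tibble(
    n_np_per_l = n_np,
    s_t_cm2_per_l = s_t,
    molecules_per_np = round(s_np / rho),
    molecules_per_np_exact = s_np / rho,
    n_sers_per_l = s_t / rho
  )
}

#' Molecule count per litre of the reference solution
#'
#' Molarity of a thiophenol/ethanol `w` weight-fraction solution under ideal
#' mixing (`1/rho_mix = w/rho_TP + (1-w)/rho_EtOH`), times Avogadro's number.
#'
#' @param tp_weight_fraction Weight fraction in (0, 1).
#' @param tp_molar_mass Molar mass, g/mol.
#' @param tp_density,solvent_density Component densities, g/mL.
#' @return Molecules per litre.
#' @export
#' @examples
#' reference_number_density(0.10)  # ~4.43e23 L^-1
reference_number_density <- function(tp_weight_fraction = 0.10,
                                     tp_molar_mass = 110.18,
                                     tp_density = 1.0766,
                                     solvent_density = 0.789) {
  w <- tp_weight_fraction
  if (!is.numeric(w) || length(w) != 1L || w <= 0 || w >= 1) {
    abort("`tp_weight_fraction` must lie strictly between 0 and 1.",
          class = "sersuptake_physical_error")
  }
  rho_mix <- 1 / (w / tp_density + (1 - w) / solvent_density)  # g/mL
  molarity <- w * rho_mix * 1000 / tp_molar_mass               # mol/L
  molarity * AVOGADRO
}

#' SERS enhancement factor
#'
#' `EF = (I_SERS / I_REF) * (N_REF / N_SERS)`, with both intensities already
#' normalized for exposure time.
#'
#' @param i_sers,i_ref Exposure-normalized integrated band intensities
#'   (counts/s) of the SERS band (1576 cm^-1) and its Raman counterpart
#'   (1587 cm^-1).
#' @param n_ref_per_l,n_sers_per_l Molecule number densities, L^-1.
#' @return Dimensionless enhancement factor.
#' @export
enhancement_factor <- function(i_sers, i_ref, n_ref_per_l, n_sers_per_l) {
  vals <- c(i_sers, i_ref, n_ref_per_l, n_sers_per_l)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All intensities and number densities must be positive.",
          class = "sersuptake_physical_error")
  }
  (i_sers / i_ref) * (n_ref_per_l / n_sers_per_l)
}

#' Full enhancement-factor chain
#'
#' Runs the whole quantity chain from particle radius and colloid mass
#' concentration to the enhancement factor: volume, mass and surface of one
#' particle, particle number density, total gold surface per litre, monolayer
#' molecule count, SERS-active and reference molecule densities, and EF.
#'
#' @param model A [colloid_model()].
#' @param i_sers,i_ref Exposure-normalized integrated intensities of the
#'   1576 cm^-1 SERS band and the 1587 cm^-1 Raman reference band, counts/s.
#' @return An object of class `"ef_result"` (named list of the full chain).
#' @export
ef_chain <- function(model = colloid_model(), i_sers, i_ref) {
  stopifnot(inherits(model, "colloid_model"))
  geom <- particle_geometry(model$r_np)
  m_np <- particle_mass(geom$v_np, model$d_au)
  budget <- surface_budget(model$mass_concentration, m_np, geom$s_np,
                           model$rho)
  n_ref <- reference_number_density(model$tp_weight_fraction,
                                    model$tp_molar_mass,
                                    model$tp_density,
                                    model$solvent_density)
  ef <- enhancement_factor(i_sers, i_ref, n_ref, budget$n_sers_per_l)
  structure(list(
    r_np = model$r_np,
    v_np = geom$v_np,
    m_np = m_np,
    s_np = geom$s_np,
    n_np_per_l = budget$n_np_per_l,
    s_t_cm2_per_l = budget$s_t_cm2_per_l,
    molecules_per_np = budget$molecules_per_np,
    n_sers_per_l = budget$n_sers_per_l,
    n_ref_per_l = n_ref,
    i_sers = i_sers,
    i_ref = i_ref,
    ef = ef
  ), class = "ef_result")
}

#' @export
print.ef_result <- function(x, ...) {
  cat(sprintf(
    paste0("SERS enhancement-factor chain\n",
           "  V_NP = %.3g cm^3   m_NP = %.3g g   S_NP = %.3g cm^2\n",
           "  N_NP = %.3g /L   S_T = %.3g cm^2/L\n",
           "  molecules per NP = %d   N_SERS = %.3g /L   N_REF = %.3g /L\n",
           "  I_SERS/I_REF = %.3g   EF = %.3g\n"),
    x$v_np, x$m_np, x$s_np, x$n_np_per_l, x$s_t_cm2_per_l,
    x$molecules_per_np, x$n_sers_per_l, x$n_ref_per_l,
    x$i_sers / x$i_ref, x$ef))
  invisible(x)
}

#' @rdname ef_chain
#' @param x An `ef_result`.
#' @param ... Unused.
#' @export
tidy.ef_result <- function(x, ...) {
  tibble(
    quantity = c("v_np", "m_np", "s_np", "n_np_per_l", "s_t_cm2_per_l",
                 "molecules_per_np", "n_sers_per_l", "n_ref_per_l",
                 "i_sers", "i_ref", "ef"),
    value = c(x$v_np, x$m_np, x$s_np, x$n_np_per_l, x$s_t_cm2_per_l,
              x$molecules_per_np, x$n_sers_per_l, x$n_ref_per_l,
              x$i_sers, x$i_ref, x$ef),
    units = c("cm^3", "g", "cm^2", "L^-1", "cm^2 L^-1", "molecules",
              "L^-1", "L^-1", "counts/s", "counts/s", "1")
  )
}

#' @rdname ef_chain
#' @export
glance.ef_result <- function(x, ...) {
  tibble(ef = x$ef, molecules_per_np = x$molecules_per_np,
         n_sers_per_l = x$n_sers_per_l, n_ref_per_l = x$n_ref_per_l)
}

#' Default SERS/Raman intensity calibration of the synthetic generators
#'
#' The synthetic paired spectra are calibrated so that the exposure-normalized
#' intensity ratio of the 1576 cm^-1 SERS band to the 1587 cm^-1 Raman band
#' corresponds, through the surface-packing model with default parameters, to
#' the enhancement factor measured for this probe (1.5e6). Inverting the EF
#' definition, `ratio = EF * N_SERS / N_REF`, which is ~22.6 for the default
#' colloid model.
#'
#' @param model A [colloid_model()].
#' @param ef Enhancement factor the calibration reproduces.
#' @return The default `scale` for `simulate_tp_spectrum("sers", ...)`
#'   relative to a Raman reference simulated at `scale = 1`.
#' @export
default_sers_scale <- function(model = colloid_model(), ef = 1.5e6) {
  geom <- particle_geometry(model$r_np)
  m_np <- particle_mass(geom$v_np, model$d_au)
  budget <- surface_budget(model$mass_concentration, m_np, geom$s_np,
                           model$rho)
  n_ref <- reference_number_density(model$tp_weight_fraction,
                                    model$tp_molar_mass,
                                    model$tp_density,
                                    model$solvent_density)
  ef * budget$n_sers_per_l / n_ref
}
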