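#' Adsorbate volume fraction from a fitted layer SLD
#'
#' Inverts the linear SLD mixing of a solvated layer,
#' \deqn{\phi_l = (\rho_s - \rho_l)/(\rho_s - \rho_a),}
#' where \eqn{\rho_s} is the solvent SLD, \eqn{\rho_l} the fitted layer SLD
#' and \eqn{\rho_a} the SLD of the pure adsorbed material. Values outside
#' `[0, 1]` are physically suspect (slight overshoot is common for real fitted
#' SLDs) and are returned with a warning rather than an error.
#'
#' @param rho_s,rho_l,rho_a SLDs in \eqn{\mathrm{\AA}^{-2}} (vectorised).
#' @return Volume fraction(s) \eqn{\phi_l}.
#' @examples
#' volume_fraction(6.36e-6, 0.4 * 3.1e-6 + 0.6 * 6.36e-6, 3.1e-6) # 0.4
#' @export
volume_fraction <- function(rho_s, rho_l, rho_a) {
  if (any(rho_s == rho_a)) {
    abort("rho_s equals rho_a: contrast-degenerate, volume fraction undefined")
  }
  phi <- (rho_s - rho_l) / (rho_s - rho_a)
  if (any(phi < 0 | phi > 1)) {
    warn("volume fraction outside [0, 1]: physically suspect inputs")
  }
  phi
}

#' Surface coverage of an adsorbed layer
#'
#' Mass of adsorbate per unit area,
#' \deqn{\Gamma = \phi_l\, \tau\, \rho'_p,}
#' with \eqn{\phi_l} the layer volume fraction, \eqn{\tau} the layer thickness
#' and \eqn{\rho'_p} the adsorbate mass density. Thickness is taken in \AA{}
#' and the result returned in mg m^-2 (the conversion factor is 0.1 for these
#' units). Linear in every argument, so coverage of stacked sublayers is
#' additive.
#'
#' @param phi volume fraction in `[0, 1]` (vectorised).
#' @param tau layer thickness in \AA.
#' @param rho_p mass density in g cm^-3 (default 1.42, typical protein).
#' @return Coverage \eqn{\Gamma} in mg m^-2.
#' @examples
#' surface_coverage(0.40, 31) # ~1.76 mg m^-2
#' @export
surface_coverage <- function(phi, tau, rho_p = 1.42) {
  if (any(phi < 0 | phi > 1)) abort("phi must lie in [0, 1]")
  if (any(tau < 0)) abort("tau must be >= 0")
  if (any(rho_p <= 0)) abort("rho_p must be positive")
  # phi * (tau * 1e-8 cm) * rho_p g/cm^3 = g/cm^2; * 1e7 -> mg/m^2
  phi * tau * rho_p * 0.1
}

#' Average interfacial area per adsorbed molecule
#'
#' Converts a surface coverage into the mean area available to each molecule:
#' the number of molecules per square metre is \eqn{\Gamma N_A / M_w}
#' (coverage in g m^-2), and the area each occupies is its reciprocal,
#' expressed in \eqn{\mathrm{\AA}^2}.
#'
#' @param gamma coverage in mg m^-2; must be positive.
#' @param molecular_weight in Da.
#' @param constants see [refl_constants()].
#' @return Area per molecule in \eqn{\mathrm{\AA}^2}.
#' @examples
#' area_per_molecule(1.7, 165e3) # ~16,100 A^2 per IgG
#' @export
area_per_molecule <- function(gamma, molecular_weight,
                              constants = refl_constants()) {
  if (any(gamma <= 0) || any(molecular_weight <= 0)) {
    abort("gamma and molecular_weight must be positive")
  }
  n_per_m2 <- gamma * 1e-3 * constants$avogadro / molecular_weight
  1e20 / n_per_m2
}

#' Packing ratio: available area over molecular footprint
#'
#' How many times its minimum footprint each adsorbed molecule has available;
#' a ratio near 1 indicates a close-packed layer.
#'
#' @param available_area area per molecule, \eqn{\mathrm{\AA}^2}.
#' @param footprint minimum area required by one molecule,
#'   \eqn{\mathrm{\AA}^2}; must be positive.
#' @return Dimensionless ratio.
#' @export
packing_ratio <- function(available_area, footprint) {
  if (any(footprint <= 0)) abort("footprint must be positive")
  available_area / footprint
}

#' Ligand coverage on a porous chromatography resin
#'
#' Desk-scale comparison of a planar surface coverage with the effective
#' ligand coverage inside a porous affinity resin. From bead diameter and
#' packing efficiency it computes beads per mL and their outer (envelope)
#' surface area; the internal pore area is bracketed by the supplied
#' outer:inner area ratios; and the ligand concentration spread over that
#' area gives coverage bounds (larger area, lower coverage). Coverage times
#' inner area recovers the ligand mass per mL exactly.
#'
#' The ligand concentration can be given directly or derived as
#' `dbc * ligand_mw / igg_mw` from the resin's dynamic binding capacity,
#' assuming 1:1 binding.
#'
#' @param bead_diameter in micrometres.
#' @param packing_efficiency volume fraction of beads in the packed bed.
#' @param ligand_conc ligand mass per resin volume, mg mL^-1; if `NULL`,
#'   derived from `dbc`.
#' @param dbc dynamic binding capacity, mg mL^-1 (used when `ligand_conc` is
#'   `NULL`).
#' @param ligand_mw,igg_mw molecular weights (Da) for the DBC-derived ligand
#'   concentration.
#' @param area_ratio_bounds outer:inner pore-area ratios `c(low, high)`.
#' @param per_molecule_area optional area per ligand molecule
#'   (\eqn{\mathrm{\AA}^2}) from which a characteristic length
#'   \eqn{\sqrt{A}} is reported.
#' @return A one-row tibble: `beads_per_ml`, `outer_area_m2`,
#'   `inner_area_low_m2`, `inner_area_high_m2`, `coverage_low_mg_m2`,
#'   `coverage_high_mg_m2`, `ligand_conc_mg_ml`, `characteristic_length_a`.
#' @examples
#' resin_comparison() # 60 um beads, packing 0.75, 13 mg/mL ligand
#' @export
resin_comparison <- function(bead_diameter = 60,
                             packing_efficiency = 0.75,
                             ligand_conc = 13,
                             dbc = 48,
                             ligand_mw = 55e3,
                             igg_mw = 165e3,
                             area_ratio_bounds = c(60, 800),
                             per_molecule_area = NULL) {
  if (bead_diameter <= 0) abort("bead_diameter must be positive")
  if (packing_efficiency <= 0 || packing_efficiency > 1) {
    abort("packing_efficiency must lie in (0, 1]")
  }
  if (length(area_ratio_bounds) != 2 || any(area_ratio_bounds <= 0) ||
    area_ratio_bounds[1] > area_ratio_bounds[2]) {
    abort("area_ratio_bounds must be positive and ordered (low, high)")
  }
  if (is.null(ligand_conc)) ligand_conc <- dbc * ligand_mw / igg_mw
  r_cm <- bead_diameter / 2 * 1e-4
  beads_per_ml <- packing_efficiency / (4 / 3 * pi * r_cm^3)
  outer_area_m2 <- beads_per_ml * 4 * pi * r_cm^2 * 1e-4
  inner <- outer_area_m2 * area_ratio_bounds
  tibble(
    beads_per_ml = beads_per_ml,
    outer_area_m2 = outer_area_m2,
    inner_area_low_m2 = inner[1],
    inner_area_high_m2 = inner[2],
    # more internal area spreads the same ligand thinner
    coverage_low_mg_m2 = ligand_conc / inner[2],
    coverage_high_mg_m2 = ligand_conc / inner[1],
    ligand_conc_mg_ml = ligand_conc,
    characteristic_length_a =
      if (is.null(per_molecule_area)) NA_real_ else sqrt(per_molecule_area)
  )
}

#' Round a value the way a report would print it
#'
#' Companion "as-printed" rounding (2 significant figures by default) for
#' quoting full-precision metric outputs at report precision.
#'
#' @param x numeric.
#' @param digits significant figures.
#' @return `signif(x, digits)`.
#' @export
as_printed <- function(x, digits = 2) signif(x, digits)

#' Coverage metrics for a table of fitted layers
#'
#' Tidy wrapper applying [surface_coverage()] (and optionally
#' [area_per_molecule()] and [packing_ratio()]) row-wise to a layer table.
#'
#' @param layers data frame with columns `phi` and `tau` (thickness, \AA);
#'   optional column `rho_p` overrides the default mass density per layer.
#' @param rho_p default mass density, g cm^-3.
#' @param molecular_weight optional MW (Da): adds `area_per_molecule`.
#' @param footprint optional minimum footprint (\eqn{\mathrm{\AA}^2}): adds
#'   `packing_ratio`.
#' @return The input tibble with `gamma_mg_m2` (and optional columns) added.
#' @examples
#' interface_metrics(
#'   tibble::tibble(layer = "inner", phi = 0.40, tau = 31),
#'   molecular_weight = 165e3, footprint = 13600
#' )
#' @export
interface_metrics <- function(layers, rho_p = 1.42, molecular_weight = NULL,
                              footprint = NULL) {
  layers <- as_tibble(layers)
  if (!all(c("phi", "tau") %in% names(layers))) {
    abort("layers needs columns 'phi' and 'tau'")
  }
  dens <- if ("rho_p" %in% names(layers)) layers$rho_p else rho_p
  out <- dplyr::mutate(layers, gamma_mg_m2 = surface_coverage(.data$phi, .data$tau, dens))
  if (!is.null(molecular_weight)) {
    out$area_per_molecule_a2 <- area_per_molecule(out$gamma_mg_m2, molecular_weight)
    if (!is.null(footprint)) {
      out$packing_ratio <- packing_ratio(out$area_per_molecule_a2, footprint)
    }
  }
  out
}
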