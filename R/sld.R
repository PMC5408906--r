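#' Solvent specification for contrast variation
#'
#' A solvent is a D2O/H2O mixture characterised by its D2O volume fraction.
#' Presets: `"D2O"` (fraction 1), `"H2O"` (fraction 0) and `"SMW"`
#' (silicon-matched water, the mixture whose SLD equals that of silicon so the
#' substrate becomes invisible; about 38% D2O with the default constants).
#'
#' @param x preset name (`"D2O"`, `"H2O"`, `"SMW"`) or a numeric D2O volume
#'   fraction in `[0, 1]`.
#' @param sld_pure_d2o,sld_pure_h2o SLDs of the pure components
#'   (\eqn{\mathrm{\AA}^{-2}}).
#' @param constants constant set, see [refl_constants()].
#' @return An object of class `solvent_spec`.
#' @examples
#' solvent("SMW")$d2o_volume_fraction # ~0.38
#' water_sld(solvent(0.5))
#' @export
solvent <- function(x = "D2O",
                    sld_pure_d2o = constants$sld_d2o,
                    sld_pure_h2o = constants$sld_h2o,
                    constants = refl_constants()) {
  if (sld_pure_d2o <= sld_pure_h2o) {
    abort("sld_pure_d2o must exceed sld_pure_h2o")
  }
  name <- NULL
  if (is.character(x)) {
    name <- toupper(x)
    frac <- switch(name,
      "D2O" = 1.0,
      "H2O" = 0.0,
      "SMW" = match_point(constants$sld_silicon,
        sld_pure_d2o = sld_pure_d2o, sld_pure_h2o = sld_pure_h2o
      ),
      abort(paste0("unknown solvent preset '", x, "' (use D2O, H2O, SMW or a fraction)"))
    )
  } else {
    frac <- as.numeric(x)
  }
  if (!is.finite(frac) || frac < 0 || frac > 1) {
    abort("d2o volume fraction must lie in [0, 1]")
  }
  structure(
    list(
      name = name %||% sprintf("%.0f%% D2O", 100 * frac),
      d2o_volume_fraction = frac,
      sld_pure_d2o = sld_pure_d2o,
      sld_pure_h2o = sld_pure_h2o
    ),
    class = "solvent_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' SLD of a D2O/H2O mixture
#'
#' Linear volume mixing of the two pure-water SLDs:
#' \eqn{\rho_s = x\,\rho_{D_2O} + (1-x)\,\rho_{H_2O}} with `x` the D2O volume
#' fraction.
#'
#' @param solv a [solvent()] specification.
#' @return Solvent SLD \eqn{\rho_s} in \eqn{\mathrm{\AA}^{-2}}.
#' @export
water_sld <- function(solv) {
  stopifnot(inherits(solv, "solvent_spec"))
  x <- solv$d2o_volume_fraction
  x * solv$sld_pure_d2o + (1 - x) * solv$sld_pure_h2o
}

#' Contrast match point: D2O fraction for a target SLD
#'
#' Exact inversion of the linear mixing rule of [water_sld()]: the D2O volume
#' fraction at which the water mixture matches `target_sld`. With the default
#' water constants, matching silicon (2.07e-6) gives 38% D2O — the
#' silicon-matched-water recipe.
#'
#' @param target_sld desired mixture SLD (\eqn{\mathrm{\AA}^{-2}}); must lie
#'   between the pure H2O and pure D2O SLDs.
#' @inheritParams solvent
#' @return D2O volume fraction in `[0, 1]`.
#' @examples
#' match_point(2.07e-6) # ~0.38
#' @export
match_point <- function(target_sld,
                        sld_pure_d2o = constants$sld_d2o,
                        sld_pure_h2o = constants$sld_h2o,
                        constants = refl_constants()) {
  if (target_sld < sld_pure_h2o || target_sld > sld_pure_d2o) {
    abort("target SLD is outside the range reachable by D2O/H2O mixing")
  }
  (target_sld - sld_pure_h2o) / (sld_pure_d2o - sld_pure_h2o)
}

#' Material composition for SLD bookkeeping
#'
#' Describes a molecular species by its summed bound coherent scattering
#' length (with every exchangeable position occupied by protium), its
#' molecular volume, and the number of labile (exchangeable) hydrogens. These
#' three numbers, together with the solvent, determine the material's SLD in
#' any D2O/H2O mixture via [material_sld()].
#'
#' @param name label.
#' @param b_total summed bound coherent scattering length in fm, all labile
#'   positions as protium.
#' @param molecular_volume molecular volume in \eqn{\mathrm{\AA}^3}; must be
#'   positive.
#' @param n_labile_h number of exchangeable hydrogens (>= 0).
#' @param mass_density optional mass density in g cm^-3 (used by coverage
#'   metrics).
#' @param molecular_weight optional molecular weight in Da.
#' @return An object of class `material_composition`.
#' @seealso [protein_material()] for a heuristic protein builder.
#' @export
material <- function(name, b_total, molecular_volume, n_labile_h = 0,
                     mass_density = NULL, molecular_weight = NULL) {
  if (!is.finite(molecular_volume) || molecular_volume <= 0) {
    abort("molecular_volume must be positive")
  }
  if (n_labile_h < 0) abort("n_labile_h must be non-negative")
  if (!is.null(mass_density) && mass_density <= 0) {
    abort("mass_density must be positive when given")
  }
  structure(
    list(
      name = name, b_total = b_total, molecular_volume = molecular_volume,
      n_labile_h = n_labile_h, mass_density = mass_density,
      molecular_weight = molecular_weight
    ),
    class = "material_composition"
  )
}

#' Heuristic protein material from molecular weight
#'
#' Builds a [material()] for a globular protein from its molecular weight
#' using field-typical averages: partial specific volume 0.73 cm^3/g, about
#' 1.8 exchangeable hydrogens per ~110 Da residue, and a hydrogenous-form SLD
#' of 1.8e-6 \eqn{\mathrm{\AA}^{-2}} (from which `b_total` is back-computed).
#' These stand in for a per-sequence calculation when the exact composition is
#' not needed; pass an explicit `b_total`/`n_labile_h` to override.
#'
#' @param name label.
#' @param molecular_weight Da.
#' @param mass_density g cm^-3 (default 1.42, typical for protein).
#' @param specific_volume partial specific volume, cm^3 g^-1.
#' @param sld_hydrogenous assumed SLD of the fully protiated material,
#'   \eqn{\mathrm{\AA}^{-2}}.
#' @param labile_h_per_da exchangeable hydrogens per dalton.
#' @param constants see [refl_constants()].
#' @return A `material_composition`.
#' @examples
#' igg <- protein_material("IgG4", 165e3)
#' material_sld(igg, solvent("D2O"))
#' @export
protein_material <- function(name, molecular_weight,
                             mass_density = constants$protein_mass_density,
                             specific_volume = 0.73,
                             sld_hydrogenous = 1.8e-6,
                             labile_h_per_da = 1.8 / 110,
                             constants = refl_constants()) {
  volume <- molecular_weight * specific_volume / constants$avogadro * 1e24 # A^3
  b_total <- sld_hydrogenous * volume / constants$fm_per_angstrom # fm
  material(
    name = name, b_total = b_total, molecular_volume = volume,
    n_labile_h = round(molecular_weight * labile_h_per_da),
    mass_density = mass_density, molecular_weight = molecular_weight
  )
}

#' SLD of a material in a given solvent with labile H/D exchange
#'
#' The fraction of labile hydrogens appearing as deuterium is modelled as
#' `exchange_fraction` times the solvent's D2O volume fraction (proportional
#' mixing), so a material in pure D2O at the default `exchange_fraction = 0.9`
#' has 90% of its labile positions deuterated, and intermediate mixtures such
#' as silicon-matched water interpolate linearly:
#' \deqn{\rho = \frac{b_{tot} + n_{lab}\, f_{ex}\, x_{D_2O}\,(b_D - b_H)}{V}.}
#'
#' @param mat a [material()].
#' @param solv a [solvent()].
#' @param exchange_fraction fraction of labile H exchanged in pure D2O,
#'   in `[0, 1]`.
#' @param constants see [refl_constants()] (supplies `b_h`, `b_d`).
#' @return SLD in \eqn{\mathrm{\AA}^{-2}}.
#' @export
material_sld <- function(mat, solv,
                         exchange_fraction = constants$exchange_fraction,
                         constants = refl_constants()) {
  stopifnot(inherits(mat, "material_composition"), inherits(solv, "solvent_spec"))
  if (exchange_fraction < 0 || exchange_fraction > 1) {
    abort("exchange_fraction must lie in [0, 1]")
  }
  b_eff <- mat$b_total +
    mat$n_labile_h * exchange_fraction * solv$d2o_volume_fraction *
      (constants$b_d - constants$b_h)
  b_eff * constants$fm_per_angstrom / mat$molecular_volume
}

#' @export
print.material_composition <- function(x, ...) {
  cat(sprintf(
    "<material> %s: b = %.1f fm, V = %.0f A^3, labile H = %d%s\n",
    x$name, x$b_total, x$molecular_volume, x$n_labile_h,
    if (!is.null(x$mass_density)) sprintf(", density = %.2f g/cm^3", x$mass_density) else ""
  ))
  invisible(x)
}

#' @export
print.solvent_spec <- function(x, ...) {
  cat(sprintf(
    "<solvent> %s (x_D2O = %.3f, SLD = %.3g A^-2)\n",
    x$name, x$d2o_volume_fraction, water_sld(x)
  ))
  invisible(x)
}

# built-in material presets used by the scenario registry
.material_presets <- function(constants = refl_constants()) {
  list(
    igg4 = protein_material("IgG4", 165e3, constants = constants),
    rspa = protein_material("rSPA", 55e3, constants = constants),
    bsa  = protein_material("BSA", 66.5e3,
      mass_density = 1.37, constants = constants
    ),
    # hydrogenous heterobifunctional cross-linker layer (SPDP-like): no
    # exchangeable H worth tracking, SLD ~0.4e-6 in its protiated form
    spdp = material("SPDP", b_total = 20, molecular_volume = 500, n_labile_h = 1),
    # PEG block: CH2CH2O repeat, essentially no labile H, SLD ~0.6e-6
    peg  = material("PEG6000", b_total = 413, molecular_volume = 6.88e3, n_labile_h = 1)
  )
}

#' Built-in material presets
#'
#' Named materials used by the synthetic-data scenario registry: `igg4`
#' (165 kDa antibody), `rspa` (recombinant staphylococcal protein A, five
#' ~7 kDa IgG-binding domains plus a truncated X domain, taken as 55 kDa),
#' `bsa`, `spdp` (cross-linker layer) and `peg` (PEG6000 block). Protein
#' entries come from [protein_material()] heuristics and are free inputs, not
#' measured compositions.
#'
#' @param name preset name; omit to list available names.
#' @return A `material_composition`, or a character vector of names.
#' @export
material_preset <- function(name = NULL) {
  presets <- .material_presets()
  if (is.null(name)) {
    return(names(presets))
  }
  m <- presets[[tolower(name)]]
  if (is.null(m)) {
    abort(paste0(
      "unknown material preset '", name, "'; available: ",
      paste(names(presets), collapse = ", ")
    ))
  }
  m
}
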