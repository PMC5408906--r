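#' Physical constants and package-wide defaults
#'
#' All physical constants used by the package live here so that every default
#' is auditable and overridable in one place. Scattering lengths are bound
#' coherent values in fm; SLDs are in \eqn{\mathrm{\AA}^{-2}}.
#'
#' Defaults:
#' \describe{
#'   \item{sld_d2o, sld_h2o}{SLD of pure D2O (6.36e-6) and pure H2O
#'     (-0.56e-6), \eqn{\mathrm{\AA}^{-2}}.}
#'   \item{b_h, b_d}{bound coherent scattering lengths of protium (-3.739 fm)
#'     and deuterium (6.671 fm).}
#'   \item{sld_silicon, sld_sio2}{SLD of crystalline silicon (2.07e-6) and of
#'     the native oxide (3.43e-6).}
#'   \item{protein_mass_density}{default protein mass density, 1.42 g cm^-3.}
#'   \item{exchange_fraction}{default fraction of labile hydrogens exchanged
#'     in fully deuterated solvent, 0.9.}
#'   \item{avogadro}{Avogadro's number.}
#' }
#'
#' @param ... named overrides of any default.
#' @return A named list of constants.
#' @examples
#' refl_constants()$sld_d2o
#' refl_constants(sld_d2o = 6.33e-6)$sld_d2o
#' @export
refl_constants <- function(...) {
  defaults <- list(
    sld_d2o = 6.36e-6,
    sld_h2o = -0.56e-6,
    b_h = -3.739,
    b_d = 6.671,
    sld_silicon = 2.07e-6,
    sld_sio2 = 3.43e-6,
    protein_mass_density = 1.42,
    exchange_fraction = 0.9,
    avogadro = 6.02214076e23,
    fm_per_angstrom = 1e-5 # 1 fm = 1e-5 Angstrom
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      abort(paste0("unknown constant(s): ", paste(bad, collapse = ", ")))
    }
    defaults <- modifyList(defaults, overrides)
  }
  defaults
}
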