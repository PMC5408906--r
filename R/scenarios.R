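# Named synthetic scenarios reproducing the fitted interfacial structures the
# package is designed to analyse: IgG4 adsorbed directly to silica at pH 4.1
# and pH 6.2, and protein A (rSPA) cross-linked to silica with BSA or PEG
# blocking and IgG capture. Layer thicknesses come from the reported layer
# models; volume fractions and roughnesses that are not reported per layer
# are best-effort assumptions recorded here (and flagged in the vignette) —
# they define the package's study conditions, not measured truth.

.scenario_registry <- function() {
  list(
    bare_wafer = list(
      description = "native oxide on silicon, no adsorbate",
      layers = refl_layer("sio2", 10, 3, sld = 3.43e-6)
    ),
    igg_silica_ph4_adsorbed = list(
      description = "IgG4 on silica, pH 4.1, protein solution in cell",
      layers = dplyr::bind_rows(
        refl_layer("sio2", 10, 3, sld = 3.43e-6),
        refl_layer("proximal", 8, 3, material = "igg4", phi = 0.05),
        refl_layer("inner", 31, 4, material = "igg4", phi = 0.40),
        refl_layer("outer", 53, 6, material = "igg4", phi = 0.05)
      )
    ),
    igg_silica_ph4_rinsed = list(
      description = "IgG4 on silica, pH 4.1, after buffer rinse",
      layers = dplyr::bind_rows(
        refl_layer("sio2", 10, 3, sld = 3.43e-6),
        refl_layer("proximal", 8, 3, material = "igg4", phi = 0.05),
        refl_layer("inner", 31, 4, material = "igg4", phi = 0.40),
        refl_layer("outer", 31, 6, material = "igg4", phi = 0.05)
      )
    ),
    igg_silica_ph62 = list(
      description = "IgG4 on silica, pH 6.2 adsorption (70 A total)",
      layers = dplyr::bind_rows(
        refl_layer("sio2", 10, 3, sld = 3.43e-6),
        refl_layer("proximal", 15, 5, material = "igg4", phi = 0.16),
        refl_layer("inner", 30, 8, material = "igg4", phi = 0.45),
        refl_layer("outer", 25, 8, material = "igg4", phi = 0.16)
      )
    ),
    rspa_crosslinked = list(
      description = "rSPA cross-linked to silanised silica",
      layers = dplyr::bind_rows(
        refl_layer("sio2", 10, 3, sld = 3.43e-6),
        refl_layer("linker", 20, 4, material = "spdp", phi = 0.30),
        refl_layer("rspa", 69, 6, material = "rspa", phi = 0.05)
      )
    ),
    rspa_bsa = list(
      description = "rSPA layer after BSA blocking (+~1.5% volume fraction)",
      layers = dplyr::bind_rows(
        refl_layer("sio2", 10, 3, sld = 3.43e-6),
        refl_layer("linker", 20, 4, material = "spdp", phi = 0.30),
        refl_layer("rspa", 69, 6, material = "rspa", phi = 0.065)
      )
    ),
    rspa_bsa_igg = list(
      description = "IgG4 captured on rSPA/BSA surface (5-layer model)",
      layers = dplyr::bind_rows(
        refl_layer("sio2", 10, 3, sld = 3.43e-6),
        refl_layer("linker", 20, 4, material = "spdp", phi = 0.30),
        refl_layer("igg_inner", 61, 6, material = "igg4", phi = 0.25),
        refl_layer("igg_mid", 52, 8, material = "igg4", phi = 0.20),
        refl_layer("igg_outer", 67, 9, material = "igg4", phi = 0.09)
      )
    ),
    rspa_peg_igg = list(
      description = "IgG4 captured on rSPA/PEG surface (extended, ~250 A)",
      layers = dplyr::bind_rows(
        refl_layer("sio2", 10, 3, sld = 3.43e-6),
        refl_layer("peg", 20, 4, material = "peg", phi = 0.20),
        refl_layer("igg_inner", 70, 6, material = "igg4", phi = 0.15),
        refl_layer("igg_mid", 90, 9, material = "igg4", phi = 0.12),
        refl_layer("igg_outer", 90, 10, material = "igg4", phi = 0.06)
      )
    )
  )
}

#' Names of the registered synthetic scenarios
#'
#' @return Character vector of scenario names usable with [build_scenario()].
#' @export
scenario_names <- function() names(.scenario_registry())

#' Noise model for synthetic reflectivity
#'
#' Emulates counting-statistics uncertainty on reduced (normalised) data:
#' Gaussian noise with a relative floor, a flat instrumental background, and
#' constant relative Q resolution. The per-point sigma is
#' `max(relative_error_floor * R_true, background_level / 3)`.
#'
#' @param relative_error_floor relative 1-sigma error on R (default 2%).
#' @param background_level flat background reflectivity (default 1e-6).
#' @param dq_over_q relative resolution width sigma/Q (default 3%).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(relative_error_floor = 0.02,
                        background_level = 1e-6,
                        dq_over_q = 0.03) {
  if (relative_error_floor < 0 || background_level < 0 || dq_over_q < 0) {
    abort("noise model fields must be non-negative")
  }
  structure(
    list(
      relative_error_floor = relative_error_floor,
      background_level = background_level,
      dq_over_q = dq_over_q
    ),
    class = "noise_model"
  )
}

#' Default measurement Q grids
#'
#' Log-spaced grids spanning the two instrument styles the package emulates:
#' a monochromatic range of 0.008-0.250 \eqn{\mathrm{\AA}^{-1}} and a
#' time-of-flight range of 0.01-0.20 \eqn{\mathrm{\AA}^{-1}}.
#'
#' @param n number of points.
#' @return Numeric Q grid.
#' @export
q_grid_isis <- function(n = 120) exp(seq(log(0.01), log(0.20), length.out = n))

#' @rdname q_grid_isis
#' @export
q_grid_ncnr <- function(n = 120) exp(seq(log(0.008), log(0.250), length.out = n))

#' Build the per-contrast stacks of a registered scenario
#'
#' Resolves a scenario's layer table into one [slab_stack()] per contrast:
#' material layers get their SLD from [material_sld()] in that contrast's
#' solvent (at the default 90% labile-H exchange) mixed with the solvent by
#' their volume fraction; raw-SLD layers are contrast-independent.
#'
#' @param name scenario name; see [scenario_names()].
#' @param contrasts character vector of solvent presets.
#' @param exchange_fraction labile-H exchange fraction.
#' @param constants see [refl_constants()].
#' @return A list with `name`, `description`, `layers` (the truth layer
#'   table) and `stacks` (named list of `slab_stack`, one per contrast).
#' @export
build_scenario <- function(name, contrasts = c("D2O", "H2O", "SMW"),
                           exchange_fraction = constants$exchange_fraction,
                           constants = refl_constants()) {
  reg <- .scenario_registry()
  sc <- reg[[name]]
  if (is.null(sc)) {
    abort(paste0(
      "unknown scenario '", name, "'; registered: ",
      paste(names(reg), collapse = ", ")
    ))
  }
  layers <- sc$layers
  stacks <- lapply(contrasts, function(cn) {
    solv <- solvent(cn)
    rho_s <- water_sld(solv)
    sld <- vapply(seq_len(nrow(layers)), function(i) {
      mat <- layers$material[[i]]
      if (is.null(mat)) {
        layers$sld[[i]]
      } else {
        rho_a <- material_sld(mat, solv,
          exchange_fraction = exchange_fraction, constants = constants
        )
        layers$phi[[i]] * rho_a + (1 - layers$phi[[i]]) * rho_s
      }
    }, 1.0)
    slab_stack(
      tibble(
        thickness = layers$thickness, sld = sld,
        roughness = layers$roughness
      ),
      fronting_sld = constants$sld_silicon,
      backing_sld = rho_s,
      backing_roughness = 3,
      constants = constants
    )
  })
  names(stacks) <- contrasts
  list(
    name = name, description = sc$description,
    layers = layers, stacks = stacks,
    exchange_fraction = exchange_fraction
  )
}

#' Simulate noisy multi-contrast reflectivity from stacks
#'
#' For each stack: the true curve is the resolution-smeared forward model;
#' the observed curve adds the flat background plus Gaussian noise with
#' sigma = `max(relative_error_floor * R_true, background_level / 3)`, and the
#' dR column records that sigma. A `dq` column (FWHM = 2.355 sigma_Q) records
#' the resolution used. Deterministic given the seed.
#'
#' @param stacks named list of [slab_stack()] objects (one per contrast), as
#'   produced by [build_scenario()], or a single stack.
#' @param q Q grid (\eqn{\mathrm{\AA}^{-1}}); must be non-empty.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return A named list of [refl_contrast()]-ready curves: for each contrast
#'   a [refl_curve()] with `q`, `r`, `dr`, `dq` plus attribute `r_true`.
#' @export
simulate_experiment <- function(stacks, q = q_grid_isis(),
                                noise = noise_model(), seed = 1) {
  if (inherits(stacks, "slab_stack")) stacks <- list(contrast = stacks)
  if (!length(q)) abort("q grid must be non-empty")
  stopifnot(inherits(noise, "noise_model"))
  .with_seed(seed, {
    out <- lapply(stacks, function(st) {
      r_true <- .reflectivity_smeared(st, q, noise$dq_over_q * q)
      sigma <- pmax(noise$relative_error_floor * r_true, noise$background_level / 3)
      r_obs <- r_true + noise$background_level +
        if (all(sigma == 0)) 0 else rnorm(length(q), 0, sigma)
      dr <- if (all(sigma == 0)) pmax(1e-4 * r_true, 1e-12) else sigma
      curve <- refl_curve(q, pmax(r_obs, 0),
        dr = dr,
        dq = 2.3548200450309493 * noise$dq_over_q * q
      )
      attr(curve, "r_true") <- r_true
      curve
    })
    names(out) <- names(stacks)
    out
  })
}

#' Simulate a full named scenario
#'
#' Convenience wrapper: [build_scenario()] then [simulate_experiment()],
#' returning everything a recovery experiment needs (the simulated curves,
#' the truth layer table, and the noise settings).
#'
#' @inheritParams build_scenario
#' @inheritParams simulate_experiment
#' @return A list with `scenario` (from [build_scenario()]), `experiments`
#'   (named curves) and `noise`.
#' @export
simulate_scenario <- function(name, contrasts = c("D2O", "H2O", "SMW"),
                              q = q_grid_isis(), noise = noise_model(),
                              seed = 1) {
  sc <- build_scenario(name, contrasts)
  list(
    scenario = sc,
    experiments = simulate_experiment(sc$stacks, q = q, noise = noise, seed = seed),
    noise = noise
  )
}

#' Fit problem for a simulated scenario
#'
#' Builds a [refl_problem()] whose layer template and starting values come
#' from the simulation's truth sidecar — the refinement-from-registry
#' workflow used for parameter-recovery experiments. By default thicknesses
#' and volume fractions vary while roughnesses, scale and background stay
#' fixed at their simulated values.
#'
#' @param sim output of [simulate_scenario()].
#' @param vary which parameter kinds to free: any of `"thickness"`, `"phi"`,
#'   `"roughness"`.
#' @return A [refl_problem()].
#' @export
scenario_problem <- function(sim, vary = c("thickness", "phi")) {
  sc <- sim$scenario
  contrasts <- purrr::imap(sim$experiments, function(curve, cn) {
    refl_contrast(curve, solvent(cn),
      scale = 1,
      background = sim$noise$background_level, name = cn
    )
  })
  problem <- refl_problem(
    sc$layers, unname(contrasts),
    dq_over_q = sim$noise$dq_over_q,
    exchange_fraction = sc$exchange_fraction
  )
  for (kind in c("thickness", "phi", "roughness")) {
    sel <- grepl(paste0("\\.", kind, "$"), problem$params$name)
    problem$params$vary[sel] <- kind %in% vary
  }
  # the oxide is a known substrate property in recovery runs, except when it
  # is the only layer present
  if (nrow(sc$layers) > 1 && "sio2.thickness" %in% problem$params$name) {
    problem <- set_param(problem, "sio2.thickness", vary = FALSE)
  }
  problem
}
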