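#' Layered interfacial model (stack of slabs)
#'
#' A stack is an ordered set of uniform slabs between two semi-infinite media:
#' the fronting (the silicon wafer the beam arrives through) and the backing
#' (the bulk solvent). Each slab has a thickness \eqn{\tau} (\AA), an SLD
#' \eqn{\rho_l} (\eqn{\mathrm{\AA}^{-2}}) and a Gaussian roughness \eqn{\sigma}
#' (\AA) describing the interface between the slab and the *preceding* medium;
#' `backing_roughness` handles the final slab/solvent interface.
#'
#' @param layers a data frame with columns `thickness`, `sld` and optionally
#'   `roughness` (default 0), ordered from the fronting toward the backing.
#'   May have zero rows (bare interface).
#' @param fronting_sld SLD of the incident medium (default: silicon).
#' @param backing_sld SLD of the semi-infinite backing (solvent).
#' @param backing_roughness roughness of the last interface (\AA).
#' @param constants see [refl_constants()].
#' @return An object of class `slab_stack`.
#' @examples
#' st <- slab_stack(
#'   tibble::tibble(thickness = 10, sld = 3.43e-6, roughness = 3),
#'   backing_sld = 6.36e-6
#' )
#' abeles_reflectivity(st, q = c(0.01, 0.05, 0.1))
#' @export
slab_stack <- function(layers = NULL,
                       fronting_sld = constants$sld_silicon,
                       backing_sld = constants$sld_d2o,
                       backing_roughness = 0,
                       constants = refl_constants()) {
  if (is.null(layers)) {
    layers <- tibble(thickness = numeric(), sld = numeric(), roughness = numeric())
  }
  layers <- as_tibble(layers)
  if (!all(c("thickness", "sld") %in% names(layers))) {
    abort("layers needs columns 'thickness' and 'sld'")
  }
  if (!"roughness" %in% names(layers)) layers$roughness <- 0
  if (any(layers$thickness < 0)) abort("slab thicknesses must be >= 0")
  if (any(layers$roughness < 0) || backing_roughness < 0) {
    abort("roughnesses must be >= 0")
  }
  # a roughness larger than either adjacent slab makes the erf profile
  # unphysical; warn but allow (common during optimisation excursions)
  if (nrow(layers) > 0) {
    sig <- c(layers$roughness, backing_roughness)
    thick <- layers$thickness
    adj_min <- pmin(c(Inf, thick), c(thick, Inf))
    if (any(sig[adj_min > 0] > adj_min[adj_min > 0])) {
      warn("a roughness exceeds an adjacent slab thickness; profile may be unphysical")
    }
  }
  structure(
    list(
      layers = layers,
      fronting_sld = fronting_sld,
      backing_sld = backing_sld,
      backing_roughness = backing_roughness
    ),
    class = "slab_stack"
  )
}

#' @export
print.slab_stack <- function(x, ...) {
  cat(sprintf(
    "<slab_stack> fronting %.3g | %d slab(s) | backing %.3g (sigma %.1f A)\n",
    x$fronting_sld, nrow(x$layers), x$backing_sld, x$backing_roughness
  ))
  if (nrow(x$layers)) print(x$layers)
  invisible(x)
}

#' Momentum transfer from beam geometry
#'
#' \eqn{Q = 4\pi \sin\theta / \lambda}: the wavevector transfer perpendicular
#' to the surface for specular reflection at grazing angle \eqn{\theta}.
#'
#' @param theta grazing angle in degrees, in (0, 90].
#' @param wavelength neutron wavelength in \AA.
#' @return Q in \eqn{\mathrm{\AA}^{-1}}.
#' @export
q_from_angle <- function(theta, wavelength) {
  if (any(theta < 0) || any(theta > 90)) abort("theta must lie in [0, 90] degrees")
  if (any(wavelength <= 0)) abort("wavelength must be positive")
  4 * pi * sin(theta * pi / 180) / wavelength
}

#' Film thickness from Kiessig fringe spacing
#'
#' The interference fringes of a uniform film of thickness `d` are spaced by
#' \eqn{\Delta Q = 2\pi / d}; this inverts that relation.
#'
#' @param delta_q fringe spacing in \eqn{\mathrm{\AA}^{-1}}; must be positive.
#' @return Thickness in \AA.
#' @export
thickness_from_fringe_spacing <- function(delta_q) {
  if (any(delta_q <= 0)) abort("fringe spacing must be positive")
  2 * pi / delta_q
}

# core optical-matrix (Abeles) calculation, vectorised over q.
# media: vector of SLDs (fronting, slabs..., backing); d: slab thicknesses;
# sigma: roughness at each of the length(media)-1 interfaces.
.abeles <- function(q, media, d, sigma) {
  n_int <- length(media) - 1L
  # perpendicular wavevector in each medium, relative to the fronting;
  # principal complex sqrt gives the decaying (Im >= 0) branch
  k <- lapply(media, function(rho) {
    sqrt(as.complex(q^2 / 4 - 4 * pi * (rho - media[[1]])))
  })
  one <- rep(1 + 0i, length(q))
  m11 <- one; m12 <- 0i * one; m21 <- 0i * one; m22 <- one
  beta_prev <- 0i * one # phase accumulated in the medium above the interface
  for (j in seq_len(n_int)) {
    kj <- k[[j]]; kj1 <- k[[j + 1L]]
    rj <- (kj - kj1) / (kj + kj1) * exp(-2 * kj * kj1 * sigma[[j]]^2)
    e <- exp(1i * beta_prev)
    c11 <- e; c12 <- rj * e; c21 <- rj / e; c22 <- 1 / e
    t11 <- m11 * c11 + m12 * c21
    t12 <- m11 * c12 + m12 * c22
    t21 <- m21 * c11 + m22 * c21
    t22 <- m21 * c12 + m22 * c22
    m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
    if (j <= length(d)) beta_prev <- k[[j + 1L]] * d[[j]]
  }
  r <- Mod(m21 / m11)^2
  pmin(pmax(r, 0), 1)
}

.stack_media <- function(stack) {
  list(
    media = c(stack$fronting_sld, stack$layers$sld, stack$backing_sld),
    d = stack$layers$thickness,
    sigma = c(stack$layers$roughness, stack$backing_roughness)
  )
}

#' Specular reflectivity of a slab stack (Abeles optical matrices)
#'
#' Computes \eqn{R(Q)} exactly for a stack of uniform slabs: per-medium
#' perpendicular wavevectors \eqn{k_i = \sqrt{Q^2/4 - 4\pi(\rho_i -
#' \rho_{front})}} (complex, decaying branch), Fresnel coefficients between
#' adjacent media damped by Nevot-Croce roughness factors
#' \eqn{\exp(-2 k_i k_{i+1} \sigma^2)}, and the characteristic-matrix product.
#' Total reflection plateaus at exactly 1.
#'
#' @param stack a [slab_stack()].
#' @param q positive momentum-transfer grid (\eqn{\mathrm{\AA}^{-1}}).
#' @return A tibble with columns `q`, `r` (class `refl_curve`).
#' @export
abeles_reflectivity <- function(stack, q) {
  stopifnot(inherits(stack, "slab_stack"))
  q <- as.numeric(q)
  if (!length(q) || any(!is.finite(q)) || any(q <= 0)) {
    abort("q must be a non-empty grid of positive values")
  }
  sm <- .stack_media(stack)
  refl_curve(q = q, r = .abeles(q, sm$media, sm$d, sm$sigma))
}

#' Construct a reflectivity curve tibble
#'
#' @param q strictly increasing positive Q grid.
#' @param r reflectivity values (>= 0).
#' @param dr optional 1-sigma uncertainties.
#' @param dq optional resolution widths (FWHM in Q).
#' @return A tibble of class `refl_curve`.
#' @export
refl_curve <- function(q, r, dr = NULL, dq = NULL) {
  if (length(r) != length(q)) abort("q and r lengths differ")
  if (any(q <= 0)) abort("q must be positive")
  if (any(r < -1e-15)) abort("reflectivity must be >= 0")
  out <- tibble(q = as.numeric(q), r = pmax(as.numeric(r), 0))
  if (!is.null(dr)) {
    if (length(dr) != length(q)) abort("dr length differs from q")
    out$dr <- as.numeric(dr)
  }
  if (!is.null(dq)) {
    if (length(dq) != length(q)) abort("dq length differs from q")
    out$dq <- as.numeric(dq)
  }
  class(out) <- c("refl_curve", class(out))
  out
}

# Gaussian quadrature nodes/weights for resolution smearing (fixed design,
# truncated at +/- 3.5 sigma)
.smear_nodes <- function(n = 17, half_width = 3.5) {
  x <- seq(-half_width, half_width, length.out = n)
  w <- dnorm(x)
  list(x = x, w = w / sum(w))
}

# smeared reflectivity of a stack evaluated directly at data q values;
# sigma_q is the per-point Gaussian width in Q
.reflectivity_smeared <- function(stack, q, sigma_q) {
  if (all(sigma_q <= 0)) {
    return(abeles_reflectivity(stack, q)$r)
  }
  nd <- .smear_nodes()
  qs <- outer(q, rep(1, length(nd$x))) + outer(sigma_q, nd$x)
  qs <- pmax(qs, 1e-6)
  sm <- .stack_media(stack)
  rv <- .abeles(as.vector(qs), sm$media, sm$d, sm$sigma)
  dim(rv) <- dim(qs)
  as.vector(rv %*% nd$w)
}

#' Apply Gaussian Q-resolution smearing to a reflectivity curve
#'
#' Convolves the curve with a Gaussian kernel of width
#' \eqn{\sigma_Q = (\mathrm{d}Q/Q)\,Q} at each point (constant relative
#' resolution, truncated at 3.5 sigma). `dq_over_q = 0` returns the curve
#' unchanged. Values beyond the tabulated grid are held at the end values.
#'
#' @param curve a [refl_curve()] (or data frame with `q`, `r`).
#' @param dq_over_q relative resolution width (sigma/Q), >= 0. Default 3%,
#'   typical of the white-beam reflectometers this package emulates.
#' @return A `refl_curve` on the same grid.
#' @export
smear_resolution <- function(curve, dq_over_q = 0.03) {
  if (dq_over_q < 0) abort("dq_over_q must be >= 0")
  if (dq_over_q == 0) {
    return(refl_curve(curve$q, curve$r, dr = curve[["dr"]], dq = curve[["dq"]]))
  }
  nd <- .smear_nodes()
  sig <- dq_over_q * curve$q
  qs <- outer(curve$q, rep(1, length(nd$x))) + outer(sig, nd$x)
  rv <- approx(curve$q, curve$r, xout = as.vector(qs), rule = 2)$y
  dim(rv) <- dim(qs)
  refl_curve(curve$q, as.vector(rv %*% nd$w), dr = curve[["dr"]], dq = curve[["dq"]])
}

#' SLD-versus-depth profile of a stack
#'
#' Piecewise-constant slab SLDs blended at each interface by an error function
#' of width equal to that interface's roughness. Depth `z = 0` sits at the
#' fronting/first-slab boundary and increases toward the backing.
#'
#' @param stack a [slab_stack()].
#' @param z depth grid in \AA; defaults to covering the stack with margins.
#' @param dz grid step for the default grid.
#' @return A tibble with columns `z`, `sld` (class `sld_profile_df`).
#' @export
sld_profile <- function(stack, z = NULL, dz = 0.5) {
  stopifnot(inherits(stack, "slab_stack"))
  total <- sum(stack$layers$thickness)
  margin <- 4 * max(c(stack$layers$roughness, stack$backing_roughness, 5))
  if (is.null(z)) z <- seq(-margin, total + margin, by = dz)
  media <- c(stack$fronting_sld, stack$layers$sld, stack$backing_sld)
  sigma <- c(stack$layers$roughness, stack$backing_roughness)
  z_int <- c(0, cumsum(stack$layers$thickness))
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  sld <- rep(media[[1]], length(z))
  for (j in seq_along(z_int)) {
    s <- sigma[[j]]
    step <- if (s > 0) {
      0.5 * (1 + erf((z - z_int[[j]]) / (s * sqrt(2))))
    } else {
      as.numeric(z >= z_int[[j]])
    }
    sld <- sld + (media[[j + 1L]] - media[[j]]) * step
  }
  out <- tibble(z = z, sld = sld)
  class(out) <- c("sld_profile_df", class(out))
  out
}
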