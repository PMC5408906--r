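# Independent oracles used to cross-check the package's forward model and
# SLD bookkeeping. These deliberately re-derive the physics by different
# routes (recursion instead of matrices, per-atom sums, profile micro-slicing)
# and must stay independent of the implementation under test.

# Parratt recursion for specular reflectivity with Nevot-Croce roughness.
parratt_oracle <- function(q, media, d, sigma) {
  k <- lapply(media, function(rho) {
    sqrt(as.complex(q^2 / 4 - 4 * pi * (rho - media[[1]])))
  })
  n_int <- length(media) - 1L
  rr <- 0 + 0i
  for (j in n_int:1) {
    fres <- (k[[j]] - k[[j + 1]]) / (k[[j]] + k[[j + 1]]) *
      exp(-2 * k[[j]] * k[[j + 1]] * sigma[[j]]^2)
    if (j < n_int) {
      ph <- exp(2i * k[[j + 1]] * d[[j]])
      rr <- (fres + rr * ph) / (1 + fres * rr * ph)
    } else {
      rr <- fres
    }
  }
  pmin(Mod(rr)^2, 1)
}

parratt_stack <- function(stack, q) {
  parratt_oracle(
    q,
    c(stack$fronting_sld, stack$layers$sld, stack$backing_sld),
    stack$layers$thickness,
    c(stack$layers$roughness, stack$backing_roughness)
  )
}

# Rough interfaces approximated by micro-slicing the erf SLD profile into
# thin zero-roughness slabs, then running the Parratt recursion on those.
microslice_reflectivity <- function(stack, q, dz = 0.25, pad = 25) {
  total <- sum(stack$layers$thickness)
  z <- seq(-pad, total + pad, by = dz)
  prof <- sld_profile(stack, z = z)
  media <- c(stack$fronting_sld, prof$sld, stack$backing_sld)
  parratt_oracle(q, media, rep(dz, length(prof$sld)), rep(0, length(media) - 1))
}

# Closed-form Fresnel reflectivity of a single sharp interface.
fresnel_single <- function(q, rho_front, rho_back) {
  k0 <- sqrt(as.complex(q^2 / 4))
  k1 <- sqrt(as.complex(q^2 / 4 - 4 * pi * (rho_back - rho_front)))
  Mod((k0 - k1) / (k0 + k1))^2
}

# Per-atom SLD summation oracle: atoms is a named count vector; labile
# positions are listed separately and filled with a protium/deuterium mix
# according to the exchange model.
atom_sld_oracle <- function(atoms, n_labile, volume, x_d2o, exchange) {
  b <- c(C = 6.6460, N = 9.36, O = 5.803, H = -3.739, S = 2.847) # fm
  b_fixed <- sum(b[names(atoms)] * atoms)
  f_d <- exchange * x_d2o
  b_lab <- n_labile * ((1 - f_d) * (-3.739) + f_d * 6.671)
  (b_fixed + b_lab) * 1e-5 / volume
}

# small helper: random test stack within physically sensible ranges
random_stack <- function(max_slabs = 5) {
  n <- sample(0:max_slabs, 1)
  suppressWarnings(slab_stack(
    tibble::tibble(
      thickness = runif(n, 5, 300),
      sld = runif(n, -0.5e-6, 7e-6),
      roughness = runif(n, 0, 8)
    ),
    fronting_sld = 2.07e-6,
    backing_sld = runif(1, -0.56e-6, 6.36e-6),
    backing_roughness = runif(1, 0, 8)
  ))
}
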