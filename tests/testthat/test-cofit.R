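# Simultaneous multi-contrast fitting: chi-squared definition, optimizer,
# bootstrap intervals and model comparison.

# small single-protein-layer problem used throughout; zero noise unless asked
make_single_layer_problem <- function(noise_floor = 0, seed = 1, nq = 40,
                                      contrasts = c("D2O", "H2O"),
                                      thickness = 40, phi = 0.35) {
  layers <- dplyr::bind_rows(
    refl_layer("sio2", 10, 3, sld = 3.43e-6),
    refl_layer("film", thickness, 4, material = "igg4", phi = phi)
  )
  sc_stacks <- lapply(contrasts, function(cn) {
    solv <- solvent(cn)
    rho_s <- water_sld(solv)
    rho_a <- material_sld(material_preset("igg4"), solv)
    slab_stack(
      tibble::tibble(
        thickness = c(10, thickness),
        sld = c(3.43e-6, phi * rho_a + (1 - phi) * rho_s),
        roughness = c(3, 4)
      ),
      backing_sld = rho_s, backing_roughness = 3
    )
  })
  names(sc_stacks) <- contrasts
  nm <- noise_model(relative_error_floor = noise_floor, background_level = 0)
  sims <- simulate_experiment(sc_stacks, q = q_grid_isis(nq), noise = nm, seed = seed)
  cts <- lapply(contrasts, function(cn) refl_contrast(sims[[cn]], cn, name = cn))
  pb <- refl_problem(layers, cts, dq_over_q = nm$dq_over_q)
  set_param(pb, "sio2.thickness", vary = FALSE)
}

test_that("chi-squared is zero at truth on noiseless data and one at unit residuals", {
  pb <- make_single_layer_problem()
  cs <- chi_squared(pb)
  expect_lt(cs$total, 1e-10)
  expect_equal(nrow(cs$per_contrast), 2)
  # shifting the data by exactly +dR gives chi^2 = 1 per point, per contrast
  pb1 <- pb
  for (i in seq_along(pb1$contrasts)) {
    pb1$contrasts[[i]]$data$r <- pb1$contrasts[[i]]$data$r +
      pb1$contrasts[[i]]$data$dr
  }
  cs1 <- chi_squared(pb1)
  expect_equal(cs1$per_contrast$chisq, c(1, 1), tolerance = 1e-12)
  expect_equal(cs1$total, 1, tolerance = 1e-12)
})

test_that("chi-squared at truth is ~1 under Gaussian noise at the stated dR", {
  totals <- vapply(1:6, function(s) {
    chi_squared(make_single_layer_problem(noise_floor = 0.03, seed = s))$total
  }, 1.0)
  n <- 2 * 40 # points per replicate
  expect_true(all(abs(totals - 1) < 3 / sqrt(n)))
  expect_lt(abs(mean(totals) - 1), 3 / sqrt(n * 6))
})

test_that("chi-squared refuses non-positive dR", {
  pb <- make_single_layer_problem()
  pb$contrasts[[1]]$data$dr[3] <- 0
  expect_error(chi_squared(pb), "floor")
})

test_that("fitting noiseless data from the truth returns the truth", {
  pb <- make_single_layer_problem()
  f <- refl_fit(pb, config = fit_config(de_itermax = 0, nm_maxit = 200), seed = 1)
  expect_lt(f$chisq_total, 1e-6)
  expect_equal(f$params$value[f$params$name == "film.thickness"], 40, tolerance = 1e-3)
})

test_that("fits are deterministic given the seed", {
  pb <- make_single_layer_problem(noise_floor = 0.02)
  cfg <- fit_config(de_itermax = 5, de_pop = 12, nm_maxit = 100)
  f1 <- refl_fit(pb, config = cfg, seed = 42)
  f2 <- refl_fit(pb, config = cfg, seed = 42)
  expect_identical(f1$params$value, f2$params$value)
  expect_identical(f1$chisq_total, f2$chisq_total)
})

test_that("the global stage recovers a perturbed two-layer structure within 5%", {
  sim <- simulate_scenario("rspa_crosslinked",
    q = q_grid_isis(80),
    noise = noise_model(relative_error_floor = 0.02), seed = 11
  )
  pb <- scenario_problem(sim)
  # start well away from the truth: optimizer must find its way back
  pb <- set_param(pb, "rspa.thickness", value = 45, lower = 20, upper = 120)
  pb <- set_param(pb, "rspa.phi", value = 0.2, lower = 0, upper = 0.5)
  pb <- set_param(pb, "linker.thickness", value = 30, lower = 5, upper = 60)
  f <- refl_fit(pb, config = fit_config(de_itermax = 25, de_pop = 20, nm_maxit = 400), seed = 5)
  est <- setNames(f$params$value, f$params$name)
  expect_equal(unname(est["rspa.thickness"]), 69, tolerance = 0.05)
  expect_equal(unname(est["linker.thickness"]), 20, tolerance = 0.05)
  expect_equal(unname(est["rspa.phi"]), 0.05, tolerance = 0.6) # phi abs below
  expect_lt(abs(est["rspa.phi"] - 0.05), 0.03)
})

test_that("fit validates its configuration", {
  pb <- make_single_layer_problem()
  pb$params$vary[] <- FALSE
  expect_error(refl_fit(pb), "at least one")
  pb2 <- make_single_layer_problem()
  pb2$params$upper[pb2$params$name == "film.thickness"] <- Inf
  expect_error(refl_fit(pb2), "finite bounds")
})

test_that("bootstrap intervals collapse on noiseless data and cover under noise", {
  pb <- make_single_layer_problem()
  f <- refl_fit(pb, config = fit_config(de_itermax = 0, nm_maxit = 150), seed = 1)
  fb <- refl_bootstrap(f, n_resamples = 8, seed = 2)
  iv <- fb$bootstrap$intervals
  expect_true(all(iv$conf.high - iv$conf.low < 1e-4 * pmax(abs(iv$estimate), 1e-6)))
  expect_error(refl_bootstrap(f, n_resamples = 1), ">= 2")
  # coverage: the 95% interval for thickness should cover the truth in >= 90%
  # of seeded noisy repetitions
  hits <- 0L
  n_rep <- 50L
  for (s in seq_len(n_rep)) {
    pbs <- make_single_layer_problem(
      noise_floor = 0.03, seed = 1000 + s,
      nq = 25, contrasts = "D2O"
    )
    fs <- refl_fit(pbs, config = fit_config(de_itermax = 0, nm_maxit = 120), seed = s)
    fbs <- refl_bootstrap(fs,
      n_resamples = 40, seed = s,
      config = fit_config(de_itermax = 0, nm_maxit = 80)
    )
    iv <- fbs$bootstrap$intervals
    row <- iv[iv$term == "film.thickness", ]
    if (row$conf.low <= 40 && 40 <= row$conf.high) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("duplicating every point shrinks bootstrap widths by about sqrt(2)", {
  pb <- make_single_layer_problem(noise_floor = 0.03, seed = 9, nq = 30, contrasts = "D2O")
  f <- refl_fit(pb, config = fit_config(de_itermax = 0, nm_maxit = 150), seed = 1)
  fb <- refl_bootstrap(f, n_resamples = 60, seed = 3)
  # duplicate the design: every Q point appears twice (tiny offset keeps the
  # grid strictly increasing)
  pb2 <- pb
  d <- pb$contrasts[[1]]$data
  idx <- rep(seq_len(nrow(d)), each = 2)
  d2 <- d[idx, ]
  d2$q <- d2$q * (1 + rep(c(0, 1e-9), nrow(d)))
  pb2$contrasts[[1]]$data <- d2
  f2 <- refl_fit(pb2, config = fit_config(de_itermax = 0, nm_maxit = 150), seed = 1)
  fb2 <- refl_bootstrap(f2, n_resamples = 60, seed = 3)
  w1 <- with(fb$bootstrap$intervals, conf.high - conf.low)
  w2 <- with(fb2$bootstrap$intervals, conf.high - conf.low)
  ratio <- mean(w1 / w2)
  expect_gt(ratio, sqrt(2) * 0.75)
  expect_lt(ratio, sqrt(2) * 1.35)
})

test_that("a second contrast removes the flat direction of a matched layer", {
  # a material contrast-matched to SMW: its volume fraction is invisible to
  # an SMW-only measurement but pinned once D2O data is added
  rho_smw <- water_sld(solvent("SMW"))
  matched <- material("matched", b_total = rho_smw * 1e4 / 1e-5,
    molecular_volume = 1e4, n_labile_h = 0)
  layers <- refl_layer("film", 50, 3, material = matched, phi = 0.3)
  mk <- function(contrasts) {
    stacks <- lapply(contrasts, function(cn) {
      solv <- solvent(cn)
      rho_s <- water_sld(solv)
      sldv <- 0.3 * material_sld(matched, solv) + 0.7 * rho_s
      slab_stack(tibble::tibble(thickness = 50, sld = sldv, roughness = 3),
        backing_sld = rho_s, backing_roughness = 3)
    })
    names(stacks) <- contrasts
    sims <- simulate_experiment(stacks, q = q_grid_isis(40),
      noise = noise_model(relative_error_floor = 0, background_level = 0), seed = 1)
    cts <- lapply(contrasts, function(cn) refl_contrast(sims[[cn]], cn, name = cn))
    refl_problem(layers, cts, dq_over_q = 0.03)
  }
  degen_count <- function(pb) {
    p <- pb$params
    vi <- which(p$vary)
    x0 <- p$value[vi]
    h <- pmax(1e-4 * abs(x0), 1e-5)
    fn <- function(v) chi_squared(pb, setNames(v, p$name[vi]))$total
    n <- length(vi)
    H <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in i:n) {
        ei <- ej <- numeric(n)
        ei[i] <- h[i]; ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (fn(x0 + ei + ej) - fn(x0 + ei - ej) - fn(x0 - ei + ej) + fn(x0 - ei - ej)) /
            (4 * h[i] * h[j])
      }
    }
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    # absolute floor matters: a fully flat likelihood has all eigenvalues at
    # numerical zero, and each must still count as degenerate
    sum(abs(ev) < 1e-6 * max(abs(ev), 1))
  }
  expect_gte(degen_count(mk("SMW")), 1)
  expect_equal(degen_count(mk(c("SMW", "D2O"))), 0)
})

test_that("single-contrast bootstrap intervals are wider than three-contrast ones", {
  sim3 <- simulate_scenario("rspa_crosslinked",
    contrasts = c("D2O", "H2O", "SMW"),
    q = q_grid_isis(50), noise = noise_model(relative_error_floor = 0.03), seed = 21
  )
  pb3 <- scenario_problem(sim3)
  sim1 <- list(
    scenario = sim3$scenario,
    experiments = sim3$experiments["D2O"],
    noise = sim3$noise
  )
  pb1 <- scenario_problem(sim1)
  cfg <- fit_config(de_itermax = 0, nm_maxit = 200)
  f3 <- refl_bootstrap(refl_fit(pb3, config = cfg, seed = 1),
    n_resamples = 40, seed = 4,
    config = fit_config(de_itermax = 0, nm_maxit = 100)
  )
  f1 <- refl_bootstrap(refl_fit(pb1, config = cfg, seed = 1),
    n_resamples = 40, seed = 4,
    config = fit_config(de_itermax = 0, nm_maxit = 100)
  )
  iv3 <- f3$bootstrap$intervals
  iv1 <- f1$bootstrap$intervals
  shared <- intersect(iv3$term, iv1$term)
  w3 <- with(iv3[match(shared, iv3$term), ], conf.high - conf.low)
  w1 <- with(iv1[match(shared, iv1$term), ], conf.high - conf.low)
  # co-refinement across contrasts tightens every shared structural parameter
  expect_true(all(w1 > w3))
})

test_that("model comparison prefers parsimony on ties and truth otherwise", {
  # data generated from a single uniform film
  one_truth <- make_single_layer_problem(noise_floor = 0.02, seed = 31, nq = 50)
  two <- one_truth
  two$layers <- dplyr::bind_rows(
    one_truth$layers,
    refl_layer("extra", 20, 4, material = "igg4", phi = 0.1)
  )
  two <- refl_problem(two$layers, one_truth$contrasts, dq_over_q = one_truth$dq_over_q)
  two <- set_param(two, "sio2.thickness", vary = FALSE)
  cfg <- fit_config(de_itermax = 10, de_pop = 15, nm_maxit = 250)
  cmp <- refl_compare(list(one_layer = one_truth, two_layer = two),
    seed = 2, config = cfg, delta_threshold = 0.05
  )
  expect_true(cmp$preferred[cmp$model == "one_layer"])
  # identical variant submitted twice gives identical chi-squared
  cmp2 <- refl_compare(list(a = one_truth, b = one_truth), seed = 2, config = cfg)
  expect_equal(cmp2$chisq_total[1], cmp2$chisq_total[2], tolerance = 1e-14)
  # different data is rejected
  other <- make_single_layer_problem(noise_floor = 0.02, seed = 99, nq = 50)
  expect_error(refl_compare(list(one_truth, other), seed = 1), "same contrast data")
})

test_that("a genuinely layered truth beats the underfitted model", {
  sim <- simulate_scenario("igg_silica_ph4_adsorbed",
    q = q_grid_isis(60),
    noise = noise_model(relative_error_floor = 0.02), seed = 13
  )
  pb3 <- scenario_problem(sim)
  # two-layer alternative: merge proximal+inner into one layer
  layers2 <- dplyr::bind_rows(
    refl_layer("sio2", 10, 3, sld = 3.43e-6),
    refl_layer("merged", 39, 4, material = "igg4", phi = 0.3),
    refl_layer("outer", 53, 6, material = "igg4", phi = 0.05)
  )
  pb2 <- refl_problem(layers2, pb3$contrasts, dq_over_q = pb3$dq_over_q)
  pb2 <- set_param(pb2, "sio2.thickness", vary = FALSE)
  for (nm in grep("roughness$|\\.sld$|^scale|^background", pb2$params$name, value = TRUE)) {
    pb2 <- set_param(pb2, nm, vary = FALSE)
  }
  cfg <- fit_config(de_itermax = 15, de_pop = 20, nm_maxit = 300)
  cmp <- refl_compare(list(three = pb3, two = pb2), seed = 3, config = cfg)
  expect_true(cmp$preferred[cmp$model == "three"])
  expect_lt(
    cmp$chisq_total[cmp$model == "three"],
    cmp$chisq_total[cmp$model == "two"]
  )
})

test_that("tidy and glance report the fit in broom shape", {
  pb <- make_single_layer_problem(noise_floor = 0.02)
  f <- refl_fit(pb, config = fit_config(de_itermax = 0, nm_maxit = 100), seed = 1)
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in% names(td)))
  expect_equal(nrow(td), sum(pb$params$vary))
  expect_gt(nrow(tidy(f, all = TRUE)), nrow(td))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_contrasts, 2L)
  expect_equal(gl$chisq_total, f$chisq_total)
})
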