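# Simultaneous multi-contrast fitting of a single layer profile.
#
# A fit problem holds one structural stack template (layers parameterised by
# material + volume fraction, or by raw SLD) plus any number of contrast
# experiments. Solvated-layer SLDs are recomputed per contrast as
# phi * rho_a(solvent) + (1 - phi) * rho_s, so structural parameters are
# shared across contrasts automatically.

#' Define one layer of a fit problem
#'
#' A layer is parameterised either by a [material()] plus a solvent volume
#' fraction `phi` (its SLD is then recomputed for every contrast, coupling
#' the contrasts through shared structure), or by a raw `sld` (useful for
#' non-protein layers such as the oxide or a cross-linker film, whose SLD is
#' taken contrast-independent).
#'
#' @param name unique layer label; a layer named `"sio2"` receives the
#'   conventional native-oxide defaults (SLD box-constrained to
#'   3.43e-6 +/- 2%, thickness bounded 5-20 \AA).
#' @param thickness \AA.
#' @param roughness \AA{} (interface with the preceding medium).
#' @param material a `material_composition`, or a [material_preset()] name.
#' @param phi adsorbate volume fraction in `[0, 1]` (with `material`).
#' @param sld raw SLD in \eqn{\mathrm{\AA}^{-2}} (alternative to
#'   `material` + `phi`).
#' @return A one-row layer tibble; rows from several calls are combined with
#'   [dplyr::bind_rows()] and passed to [refl_problem()].
#' @examples
#' dplyr::bind_rows(
#'   refl_layer("sio2", 10, 3, sld = 3.43e-6),
#'   refl_layer("inner", 31, 4, material = "igg4", phi = 0.40)
#' )
#' @export
refl_layer <- function(name, thickness, roughness = 3,
                       material = NULL, phi = NULL, sld = NULL) {
  if (is.character(material)) material <- material_preset(material)
  has_mat <- !is.null(material)
  if (has_mat && is.null(phi)) abort("a material layer needs 'phi'")
  if (!has_mat && is.null(sld)) abort("give either material + phi or a raw sld")
  if (has_mat && !is.null(sld)) abort("give material + phi OR sld, not both")
  tibble(
    name = name,
    thickness = thickness,
    roughness = roughness,
    phi = if (has_mat) phi else NA_real_,
    sld = if (has_mat) NA_real_ else sld,
    material = list(material)
  )
}

#' Define one contrast experiment
#'
#' Couples a measured (or simulated) reflectivity curve to the solvent it was
#' measured in, with a multiplicative scale and an additive constant
#' background. Background-subtracted data is represented by
#' `background = 0` held fixed; time-of-flight style data carries its
#' background into the model instead.
#'
#' @param data a [refl_curve()] with a `dr` column (and optionally `dq`,
#'   FWHM resolution widths, which take precedence over the problem-level
#'   constant dQ/Q).
#' @param solvent a [solvent()] or preset name.
#' @param scale multiplicative intensity scale (> 0).
#' @param background additive constant reflectivity (>= 0).
#' @param backing_sld optional override of the semi-infinite backing SLD
#'   (defaults to the solvent SLD; override for e.g. imperfectly deuterated
#'   buffer).
#' @param name label; defaults to the solvent name.
#' @return An object of class `refl_contrast`.
#' @export
refl_contrast <- function(data, solvent, scale = 1, background = 0,
                          backing_sld = NULL, name = NULL) {
  if (is.character(solvent)) solvent <- solvent(solvent)
  stopifnot(inherits(solvent, "solvent_spec"))
  if (scale <= 0) abort("scale must be positive")
  if (background < 0) abort("background must be >= 0")
  data <- as_tibble(data)
  if (!all(c("q", "r") %in% names(data))) abort("data needs columns q, r")
  structure(
    list(
      data = data, solvent = solvent, scale = scale, background = background,
      backing_sld = backing_sld %||% water_sld(solvent),
      name = name %||% solvent$name
    ),
    class = "refl_contrast"
  )
}

#' Assemble a multi-contrast fit problem
#'
#' Builds the shared parameter table from the layer template and contrasts.
#' Parameters are named `<layer>.thickness`, `<layer>.phi`, `<layer>.roughness`,
#' `<layer>.sld`, `backing_roughness`, `scale.<contrast>` and
#' `background.<contrast>`. Defaults: thicknesses and volume fractions vary;
#' roughnesses, raw SLDs, scales and backgrounds are fixed (free them with
#' [set_param()]). An `"sio2"` layer gets thickness bounds `[5, 20]` \AA{} and
#' SLD bounds 3.43e-6 +/- 2%.
#'
#' @param layers layer tibble from [refl_layer()] rows.
#' @param contrasts list of [refl_contrast()] objects (at least one).
#' @param fronting_sld incident-medium SLD (default silicon).
#' @param backing_roughness \AA.
#' @param dq_over_q constant relative resolution (sigma/Q) applied when a
#'   contrast has no `dq` column; 0 disables smearing.
#' @param exchange_fraction labile-H exchange fraction passed to
#'   [material_sld()].
#' @param constants see [refl_constants()].
#' @return An object of class `refl_problem` with a `$params` tibble
#'   (`name`, `value`, `lower`, `upper`, `vary`).
#' @export
refl_problem <- function(layers, contrasts,
                         fronting_sld = constants$sld_silicon,
                         backing_roughness = 3,
                         dq_over_q = 0.03,
                         exchange_fraction = constants$exchange_fraction,
                         constants = refl_constants()) {
  layers <- as_tibble(layers)
  if (inherits(contrasts, "refl_contrast")) contrasts <- list(contrasts)
  if (!length(contrasts)) abort("at least one contrast is required")
  if (anyDuplicated(layers$name)) abort("layer names must be unique")
  cnames <- vapply(contrasts, function(ct) ct$name, "")
  if (anyDuplicated(cnames)) {
    cnames <- make.unique(cnames, sep = "_")
    for (i in seq_along(contrasts)) contrasts[[i]]$name <- cnames[[i]]
  }
  params <- list()
  add <- function(name, value, lower, upper, vary) {
    params[[length(params) + 1L]] <<- tibble(
      name = name, value = value, lower = lower, upper = upper, vary = vary
    )
  }
  for (i in seq_len(nrow(layers))) {
    ly <- layers[i, ]
    is_oxide <- grepl("sio2", tolower(ly$name), fixed = TRUE)
    if (is_oxide) {
      add(paste0(ly$name, ".thickness"), min(max(ly$thickness, 5), 20), 5, 20, TRUE)
    } else {
      add(
        paste0(ly$name, ".thickness"), ly$thickness,
        max(0, 0.5 * ly$thickness), 1.5 * ly$thickness + 10, TRUE
      )
    }
    add(paste0(ly$name, ".roughness"), ly$roughness, 0, 15, FALSE)
    if (!is.null(ly$material[[1]])) {
      add(paste0(ly$name, ".phi"), ly$phi, 0, 0.7, TRUE)
    } else if (is_oxide) {
      add(paste0(ly$name, ".sld"), ly$sld, 3.43e-6 * 0.98, 3.43e-6 * 1.02, FALSE)
    } else {
      add(paste0(ly$name, ".sld"), ly$sld, ly$sld - 1e-6, ly$sld + 1e-6, FALSE)
    }
  }
  add("backing_roughness", backing_roughness, 0, 15, FALSE)
  for (ct in contrasts) {
    add(paste0("scale.", ct$name), ct$scale, 0.8, 1.2, FALSE)
    add(paste0("background.", ct$name), ct$background, 0, 1e-4, FALSE)
  }
  structure(
    list(
      layers = layers, contrasts = contrasts,
      fronting_sld = fronting_sld,
      dq_over_q = dq_over_q,
      exchange_fraction = exchange_fraction,
      constants = constants,
      params = dplyr::bind_rows(params)
    ),
    class = "refl_problem"
  )
}

#' @export
print.refl_problem <- function(x, ...) {
  cat(sprintf(
    "<refl_problem> %d layer(s), %d contrast(s) [%s], %d/%d parameters varying\n",
    nrow(x$layers), length(x$contrasts),
    paste(vapply(x$contrasts, function(ct) ct$name, ""), collapse = ", "),
    sum(x$params$vary), nrow(x$params)
  ))
  invisible(x)
}

#' Adjust a fit parameter
#'
#' @param problem a [refl_problem()].
#' @param name parameter name(s) as listed in `problem$params$name`.
#' @param value,lower,upper,vary fields to update (left unchanged if `NULL`).
#' @return The modified problem.
#' @export
set_param <- function(problem, name, value = NULL, lower = NULL, upper = NULL,
                      vary = NULL) {
  idx <- match(name, problem$params$name)
  if (anyNA(idx)) {
    abort(paste0("unknown parameter(s): ", paste(name[is.na(idx)], collapse = ", ")))
  }
  if (!is.null(value)) problem$params$value[idx] <- value
  if (!is.null(lower)) problem$params$lower[idx] <- lower
  if (!is.null(upper)) problem$params$upper[idx] <- upper
  if (!is.null(vary)) problem$params$vary[idx] <- vary
  problem
}

.par_values <- function(problem) {
  setNames(problem$params$value, problem$params$name)
}

# stack for one contrast at the given parameter values
.contrast_stack <- function(problem, pv, ct) {
  layers <- problem$layers
  n <- nrow(layers)
  sld <- numeric(n)
  rho_s <- ct$backing_sld
  for (i in seq_len(n)) {
    nm <- layers$name[[i]]
    mat <- layers$material[[i]]
    if (!is.null(mat)) {
      rho_a <- material_sld(mat, ct$solvent,
        exchange_fraction = problem$exchange_fraction,
        constants = problem$constants
      )
      phi <- pv[[paste0(nm, ".phi")]]
      sld[[i]] <- phi * rho_a + (1 - phi) * rho_s
    } else {
      sld[[i]] <- pv[[paste0(nm, ".sld")]]
    }
  }
  suppressWarnings(slab_stack(
    tibble(
      thickness = pv[paste0(layers$name, ".thickness")],
      sld = sld,
      roughness = pv[paste0(layers$name, ".roughness")]
    ),
    fronting_sld = problem$fronting_sld,
    backing_sld = rho_s,
    backing_roughness = pv[["backing_roughness"]],
    constants = problem$constants
  ))
}

# Precomputed evaluation cache: everything independent of parameter values,
# with parameter lookups resolved to positional indices. This keeps the
# optimizer objective free of data-frame construction.
.fit_cache <- function(problem) {
  pnames <- problem$params$name
  layers <- problem$layers
  n <- nrow(layers)
  nd <- .smear_nodes()
  lapply(problem$contrasts, function(ct) {
    rho_a <- vapply(seq_len(n), function(i) {
      mat <- layers$material[[i]]
      if (is.null(mat)) {
        NA_real_
      } else {
        material_sld(mat, ct$solvent,
          exchange_fraction = problem$exchange_fraction,
          constants = problem$constants
        )
      }
    }, 1.0)
    q <- ct$data$q
    sigma_q <- if (!is.null(ct$data[["dq"]])) {
      ct$data[["dq"]] / 2.3548200450309493
    } else {
      problem$dq_over_q * q
    }
    qs <- if (all(sigma_q <= 0)) {
      NULL
    } else {
      pmax(outer(q, rep(1, length(nd$x))) + outer(sigma_q, nd$x), 1e-6)
    }
    list(
      rho_s = ct$backing_sld, rho_a = rho_a, raw = is.na(rho_a),
      q = q, qs = qs, w = nd$w,
      robs = ct$data$r, dr = ct$data[["dr"]],
      i_thick = match(paste0(layers$name, ".thickness"), pnames),
      i_phi = match(paste0(layers$name, ".phi"), pnames),
      i_sld = match(paste0(layers$name, ".sld"), pnames),
      i_rough = match(paste0(layers$name, ".roughness"), pnames),
      i_brough = match("backing_roughness", pnames),
      i_scale = match(paste0("scale.", ct$name), pnames),
      i_bg = match(paste0("background.", ct$name), pnames),
      fronting = problem$fronting_sld
    )
  })
}

# smeared, scaled model for one cached contrast at a positional value vector
.model_fast <- function(cc, pvec) {
  sld <- numeric(length(cc$rho_a))
  if (any(cc$raw)) sld[cc$raw] <- pvec[cc$i_sld[cc$raw]]
  if (any(!cc$raw)) {
    phi <- pvec[cc$i_phi[!cc$raw]]
    sld[!cc$raw] <- phi * cc$rho_a[!cc$raw] + (1 - phi) * cc$rho_s
  }
  media <- c(cc$fronting, sld, cc$rho_s)
  d <- pvec[cc$i_thick]
  sigma <- c(pvec[cc$i_rough], pvec[cc$i_brough])
  r <- if (is.null(cc$qs)) {
    .abeles(cc$q, media, d, sigma)
  } else {
    rv <- .abeles(as.vector(cc$qs), media, d, sigma)
    dim(rv) <- dim(cc$qs)
    as.vector(rv %*% cc$w)
  }
  r * pvec[cc$i_scale] + pvec[cc$i_bg]
}

.chisq_per_contrast <- function(cache, pvec) {
  vapply(cache, function(cc) {
    mean(((.model_fast(cc, pvec) - cc$robs) / cc$dr)^2)
  }, 1.0)
}

# model reflectivity (smeared, scaled, with background) at a contrast's q grid
.contrast_model <- function(problem, pv, ct) {
  stack <- .contrast_stack(problem, pv, ct)
  q <- ct$data$q
  sigma_q <- if (!is.null(ct$data[["dq"]])) {
    ct$data[["dq"]] / 2.3548200450309493 # FWHM -> sigma
  } else {
    problem$dq_over_q * q
  }
  r <- .reflectivity_smeared(stack, q, sigma_q)
  r * pv[[paste0("scale.", ct$name)]] + pv[[paste0("background.", ct$name)]]
}

#' Chi-squared of a fit problem
#'
#' Per contrast, the per-point-normalised statistic
#' \eqn{\chi^2 = N^{-1} \sum ((R_{model} - R_{obs})/\mathrm{d}R)^2}; the total
#' is the mean over contrasts, so contrasts with different point counts weigh
#' equally in the co-refinement.
#'
#' @param problem a [refl_problem()].
#' @param par optional named vector overriding (a subset of) parameter values.
#' @return A list with `per_contrast` (tibble: `contrast`, `n`, `chisq`) and
#'   `total`.
#' @export
chi_squared <- function(problem, par = NULL) {
  pv <- .par_values(problem)
  if (!is.null(par)) pv[names(par)] <- par
  for (ct in problem$contrasts) {
    if (is.null(ct$data[["dr"]])) abort("contrast data carries no dR column")
    if (any(ct$data[["dr"]] <= 0)) {
      abort("dR must be positive everywhere; apply an uncertainty floor before fitting")
    }
  }
  cache <- .fit_cache(problem)
  chis <- .chisq_per_contrast(cache, unname(pv))
  per <- tibble(
    contrast = vapply(problem$contrasts, function(ct) ct$name, ""),
    n = vapply(problem$contrasts, function(ct) length(ct$data$q), 1L),
    chisq = chis
  )
  list(per_contrast = per, total = mean(per$chisq))
}

#' Optimizer configuration
#'
#' @param de_itermax differential-evolution generations (0 skips the global
#'   stage and polishes from the problem's current values).
#' @param de_pop population size; default `15 * n_varying`.
#' @param de_f,de_cr DE mutation weight and crossover probability.
#' @param nm_maxit,nm_reltol Nelder-Mead polish budget and tolerance.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(de_itermax = 60, de_pop = NULL, de_f = 0.8, de_cr = 0.9,
                       nm_maxit = 500, nm_reltol = 1e-9) {
  structure(
    list(
      de_itermax = de_itermax, de_pop = de_pop, de_f = de_f, de_cr = de_cr,
      nm_maxit = nm_maxit, nm_reltol = nm_reltol
    ),
    class = "fit_config"
  )
}

# evaluate code under a seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# bounded rand/1/bin differential evolution; deterministic under the caller's
# RNG state. Returns list(par, value, evals).
.de_search <- function(fn, lower, upper, init, pop, itermax, f = 0.8, cr = 0.9) {
  npar <- length(lower)
  P <- matrix(runif(pop * npar, lower, upper), ncol = npar, byrow = TRUE)
  P[1, ] <- pmin(pmax(init, lower), upper)
  fvals <- apply(P, 1, fn)
  evals <- pop
  for (gen in seq_len(itermax)) {
    for (i in seq_len(pop)) {
      idx <- sample(setdiff(seq_len(pop), i), 3L)
      v <- P[idx[1], ] + f * (P[idx[2], ] - P[idx[3], ])
      v <- pmin(pmax(v, lower), upper)
      mask <- runif(npar) < cr
      mask[sample.int(npar, 1L)] <- TRUE
      trial <- ifelse(mask, v, P[i, ])
      ft <- fn(trial)
      evals <- evals + 1L
      if (ft <= fvals[i]) {
        P[i, ] <- trial
        fvals[i] <- ft
      }
    }
  }
  best <- which.min(fvals)
  list(par = P[best, ], value = fvals[best], evals = evals)
}

#' Fit a multi-contrast reflectivity problem
#'
#' Seeded global stochastic search (differential evolution over the varying
#' parameters within their bounds) followed by a Nelder-Mead polish. The
#' result is deterministic given the seed. Multimodal fringe-fitting
#' landscapes are the reason for the global stage; when starting values are
#' already near the optimum, `fit_config(de_itermax = 0)` gives a fast local
#' refinement.
#'
#' @param problem a [refl_problem()] with at least one varying parameter; all
#'   varying parameters must have finite bounds.
#' @param config a [fit_config()].
#' @param seed integer seed for the stochastic search.
#' @return An object of class `refl_fit`: the problem updated to the best
#'   parameters, per-contrast and total chi-squared, and bookkeeping. Methods:
#'   [tidy()], [glance()], [autoplot()], [refl_bootstrap()].
#' @export
refl_fit <- function(problem, config = fit_config(), seed = 1) {
  stopifnot(inherits(problem, "refl_problem"))
  p <- problem$params
  vi <- which(p$vary)
  if (!length(vi)) abort("at least one parameter must vary")
  if (any(!is.finite(p$lower[vi])) || any(!is.finite(p$upper[vi]))) {
    abort("every varying parameter needs finite bounds")
  }
  vnames <- p$name[vi]
  lower <- p$lower[vi]
  upper <- p$upper[vi]
  for (ct in problem$contrasts) {
    if (is.null(ct$data[["dr"]]) || any(ct$data[["dr"]] <= 0)) {
      abort("every contrast needs strictly positive dR before fitting")
    }
  }
  cache <- .fit_cache(problem)
  pvec <- p$value
  evals <- 0L
  objective <- function(v) {
    evals <<- evals + 1L
    if (any(v < lower) || any(v > upper)) {
      return(1e10 * (1 + sum(pmax(lower - v, 0) + pmax(v - upper, 0))))
    }
    pvl <- pvec
    pvl[vi] <- v
    mean(.chisq_per_contrast(cache, pvl))
  }
  init <- p$value[vi]
  best <- .with_seed(seed, {
    start <- pmin(pmax(init, lower), upper)
    if (config$de_itermax > 0) {
      pop <- config$de_pop %||% (15L * length(vi))
      de <- .de_search(
        objective, lower, upper, start,
        pop = max(pop, 5L), itermax = config$de_itermax,
        f = config$de_f, cr = config$de_cr
      )
      start <- de$par
    }
    if (length(vi) == 1L) {
      o <- optim(start, objective,
        method = "Brent", lower = lower, upper = upper,
        control = list(maxit = config$nm_maxit)
      )
    } else {
      o <- optim(start, objective,
        method = "Nelder-Mead",
        control = list(maxit = config$nm_maxit, reltol = config$nm_reltol)
      )
    }
    o
  })
  problem$params$value[vi] <- pmin(pmax(best$par, lower), upper)
  chis <- chi_squared(problem)
  structure(
    list(
      problem = problem,
      params = problem$params,
      chisq_per_contrast = chis$per_contrast,
      chisq_total = chis$total,
      n_evals = evals,
      convergence = best$convergence,
      seed = seed,
      config = config,
      bootstrap = NULL
    ),
    class = "refl_fit"
  )
}

#' @export
print.refl_fit <- function(x, ...) {
  cat(sprintf(
    "<refl_fit> chi^2 = %.4g (%s), %d varying parameter(s), seed %s\n",
    x$chisq_total,
    paste(sprintf("%s: %.3g", x$chisq_per_contrast$contrast, x$chisq_per_contrast$chisq),
      collapse = ", "
    ),
    sum(x$params$vary), format(x$seed)
  ))
  print(tidy(x))
  invisible(x)
}

#' Residual-resampling bootstrap intervals for a fit
#'
#' Standardised residuals are resampled with replacement within each contrast
#' (the Q points are a fixed design, so case resampling would be
#' inappropriate), pseudo-data are rebuilt around the best-fit model, and the
#' fit is repeated from the best parameters with a local polish. Percentile
#' 2.5%/97.5% intervals per varying parameter are attached to the fit.
#' Deterministic given the seed.
#'
#' @param fit a [refl_fit()] result.
#' @param n_resamples number of bootstrap datasets (>= 2).
#' @param seed integer seed.
#' @param config optimizer budget for the refits; default is a local polish
#'   from the best-fit values.
#' @return The fit with a `$bootstrap` element: `intervals` (tibble `term`,
#'   `estimate`, `conf.low`, `conf.high`), the raw `draws` matrix, and
#'   bookkeeping. [tidy()] then reports the intervals.
#' @export
refl_bootstrap <- function(fit, n_resamples = 100, seed = 1,
                           config = fit_config(de_itermax = 0, nm_maxit = 250)) {
  stopifnot(inherits(fit, "refl_fit"))
  if (n_resamples < 2) abort("n_resamples must be >= 2")
  problem <- fit$problem
  pv <- .par_values(problem)
  models <- lapply(problem$contrasts, function(ct) .contrast_model(problem, pv, ct))
  std_res <- lapply(seq_along(problem$contrasts), function(i) {
    ct <- problem$contrasts[[i]]
    (ct$data$r - models[[i]]) / ct$data$dr
  })
  vnames <- problem$params$name[problem$params$vary]
  draws <- .with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_resamples, ncol = length(vnames))
    for (b in seq_len(n_resamples)) {
      pb <- problem
      for (i in seq_along(pb$contrasts)) {
        res <- sample(std_res[[i]], replace = TRUE)
        pb$contrasts[[i]]$data$r <- pmax(
          models[[i]] + res * pb$contrasts[[i]]$data$dr, 0
        )
      }
      refit <- refl_fit(pb, config = config, seed = seed + b)
      out[b, ] <- refit$params$value[refit$params$vary]
    }
    out
  })
  colnames(draws) <- vnames
  intervals <- tibble(
    term = vnames,
    estimate = pv[vnames],
    conf.low = apply(draws, 2, quantile, probs = 0.025, names = FALSE),
    conf.high = apply(draws, 2, quantile, probs = 0.975, names = FALSE)
  )
  fit$bootstrap <- list(
    intervals = intervals, draws = draws,
    n_resamples = n_resamples, seed = seed
  )
  fit
}

#' Fit and rank competing layer models on the same data
#'
#' Fits each candidate problem (all must reference identical data) and ranks
#' by total chi-squared. Models whose chi-squared lies within
#' `delta_threshold` of the best are treated as ties and the tie is broken
#' toward fewer layers (parsimony). With `bootstrap_n > 0`, per-parameter
#' bootstrap relative interval widths are reported as the robustness
#' diagnostic.
#'
#' @param problems named list of [refl_problem()] variants sharing the same
#'   contrast data.
#' @param seed integer seed used for every fit.
#' @param config a [fit_config()].
#' @param delta_threshold chi-squared tie threshold.
#' @param bootstrap_n bootstrap resamples per model (0 to skip).
#' @return A tibble ranked by chi-squared with a logical `preferred` column;
#'   the fitted objects are attached as `attr(, "fits")`.
#' @export
refl_compare <- function(problems, seed = 1, config = fit_config(),
                         delta_threshold = 0.05, bootstrap_n = 0) {
  if (inherits(problems, "refl_problem")) abort("pass a list of problems")
  if (is.null(names(problems))) {
    names(problems) <- paste0("model", seq_along(problems))
  }
  ref <- problems[[1]]$contrasts
  for (pb in problems[-1]) {
    if (length(pb$contrasts) != length(ref)) {
      abort("model variants must share the same contrast data")
    }
    for (i in seq_along(ref)) {
      if (!isTRUE(all.equal(pb$contrasts[[i]]$data$q, ref[[i]]$data$q)) ||
        !isTRUE(all.equal(pb$contrasts[[i]]$data$r, ref[[i]]$data$r))) {
        abort("model variants must share the same contrast data")
      }
    }
  }
  fits <- lapply(problems, refl_fit, config = config, seed = seed)
  rows <- purrr::imap(fits, function(f, nm) {
    row <- tibble(
      model = nm,
      n_layers = nrow(f$problem$layers),
      n_par = sum(f$params$vary),
      chisq_total = f$chisq_total
    )
    if (bootstrap_n > 0) {
      fb <- refl_bootstrap(f, n_resamples = bootstrap_n, seed = seed)
      iv <- fb$bootstrap$intervals
      row$max_rel_interval_width <-
        max(abs(iv$conf.high - iv$conf.low) / pmax(abs(iv$estimate), 1e-12))
    }
    row
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$chisq_total)
  tied <- out$chisq_total <= min(out$chisq_total) + delta_threshold
  pick <- out$model[tied][order(out$n_layers[tied], out$n_par[tied])][1]
  out$delta_chisq <- out$chisq_total - min(out$chisq_total)
  out$preferred <- out$model == pick
  attr(out, "fits") <- fits
  out
}
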