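---
title: "Slab-model analysis of neutron reflectivity from adsorbed protein layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slab-model analysis of neutron reflectivity from adsorbed protein layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 3.5)
library(slabfit)
library(dplyr)
```

## The measurement and the model

Specular neutron reflectometry measures the fraction of a collimated neutron
beam reflected from a flat interface as a function of the momentum transfer
perpendicular to the surface, $Q = 4\pi\sin\theta/\lambda$. For a silicon
wafer immersed in buffer, anything adsorbed at the solid--liquid interface --
an oxide film, a cross-linker layer, a protein film -- perturbs the
reflectivity curve $R(Q)$, and interference between reflections from the two
faces of a film of thickness $d$ produces fringes spaced by
$\Delta Q = 2\pi/d$.

The quantity that sets the contrast is the neutron scattering length density
(SLD): the summed bound coherent scattering lengths of a material's atoms per
molecular volume, in $\mathrm{\AA^{-2}}$. Because protium and deuterium have
very different scattering lengths ($b_H = -3.739$ fm, $b_D = +6.671$ fm),
the solvent SLD can be tuned over a wide range by mixing D$_2$O
($6.36\times10^{-6}\,\mathrm{\AA^{-2}}$) and H$_2$O
($-0.56\times10^{-6}\,\mathrm{\AA^{-2}}$). The mixture matching silicon's
SLD ($2.07\times10^{-6}$) -- *silicon-matched water* -- contains 38% D$_2$O:

```{r}
match_point(refl_constants()$sld_silicon)
```

`slabfit` models the interface as a stack of uniform slabs between
semi-infinite silicon and solvent. Each slab has a thickness $\tau$, an SLD
$\rho_l$, and a Gaussian roughness $\sigma$ at its interface with the
preceding medium. Reflectivity is computed exactly with the Abeles
optical-matrix formalism: per-medium perpendicular wavevectors
$k_i = \sqrt{Q^2/4 - 4\pi(\rho_i - \rho_{\mathrm{Si}})}$ on the decaying
complex branch, Fresnel coefficients damped by Névot--Croce factors
$\exp(-2k_ik_{i+1}\sigma^2)$, and a characteristic-matrix product whose
off-diagonal ratio gives the reflection amplitude. Total external reflection
plateaus at exactly 1.

```{r}
wafer <- slab_stack(
  tibble::tibble(thickness = 10, sld = 3.43e-6, roughness = 3),
  backing_sld = 6.36e-6, backing_roughness = 3
)
autoplot(abeles_reflectivity(wafer, q_grid_isis()))
```

### Numerical conventions

* **Roughness** is the Gaussian width $\sigma$ (not FWHM) of an
  error-function SLD transition, applied as Névot--Croce damping rather than
  by micro-slicing the profile. This is the standard choice for slab models
  where $\sigma$ is small against the slab thicknesses; the test suite
  cross-checks it against a micro-sliced erf profile (agreement to ~2% for
  $\sigma \sim 4\,\mathrm{\AA}$). One consequence worth knowing: a
  zero-thickness slab bracketed by rough interfaces is only strictly
  invisible when its SLD matches a neighbour, because the damping factors
  involve the wavevector of the vanishing medium.
* **Resolution smearing** convolves $R(Q)$ with a Gaussian kernel of width
  $\sigma_Q = (\mathrm{d}Q/Q)\,Q$, truncated at $\pm3.5\sigma$ and evaluated
  on a 17-node quadrature. The default $\mathrm{d}Q/Q$ of 3% is typical of
  the white-beam reflectometers whose data layout the package emulates; a
  per-point `dq` column (FWHM) in a data file takes precedence.
* $Q$ is the independent variable throughout; instrument geometry enters
  only through `q_from_angle()`.

## SLD bookkeeping with H/D exchange

Protein SLDs depend on the solvent because labile (exchangeable) hydrogens
pick up deuterium. `material_sld()` models the deuterated fraction of
labile sites as `exchange_fraction` times the solvent's D$_2$O volume
fraction; the default `exchange_fraction = 0.9` reproduces the conventional
assumption that 90% of labile hydrogens exchange in pure D$_2$O, and
interpolates linearly in mixtures such as SMW. The resulting SLD is affine
in the D$_2$O fraction with slope
$n_{\mathrm{lab}}\,f_{\mathrm{ex}}\,(b_D-b_H)/V$.

Reference compositions for the proteins the package ships
(`material_preset()`) are heuristic: molecular volume from a partial
specific volume of 0.73 cm$^3$/g, roughly 1.8 labile hydrogens per 110 Da
residue, and a fully protiated SLD of $1.8\times10^{-6}\,\mathrm{\AA^{-2}}$.
They are free inputs -- convenient, realistic defaults, not measured
compositions -- and any serious analysis of real data should substitute
per-sequence values.

## Simultaneous multi-contrast fitting

A single structural profile is refined against curves measured in several
solvent contrasts at once. Layers carrying a material are parameterised by
$(\mathrm{material}, \phi, \tau, \sigma)$: their SLD is recomputed per
contrast as $\phi\rho_a + (1-\phi)\rho_s$, which couples the contrasts
through the shared structure and makes the co-refinement automatic. Raw-SLD
layers remain available for the oxide and other non-protein films.

Choices the data does not dictate, made once and documented here:

* **Chi-squared** is per-point-normalised within each contrast,
  $\chi^2 = N^{-1}\sum((R_{\mathrm{model}} - R_{\mathrm{obs}})/\mathrm{d}R)^2$,
  and the total is the unweighted mean over contrasts, so a contrast with
  more points does not dominate the co-refinement.
* **Optimisation** is seeded differential evolution (rand/1/bin, population
  $15\times$ the number of varying parameters by default) inside the
  parameter bounds, followed by a Nelder--Mead polish. Fringe-fitting
  landscapes are multimodal in thickness, hence the global stage; fits that
  start near the optimum can skip it (`fit_config(de_itermax = 0)`).
  Identical problem + seed gives bit-identical results.
* **Backgrounds** are additive constants per contrast: fitted for
  time-of-flight style data, fixed at zero for background-subtracted data.
  Whether intensity scales float is likewise per-contrast configuration;
  both default to fixed.
* **The oxide layer** defaults to SLD $3.43\times10^{-6}\,\mathrm{\AA^{-2}}$
  box-constrained to $\pm2\%$ and thickness bounded 5--20 $\mathrm{\AA}$,
  the conventional treatment of a native oxide that typically refines to
  about 10 $\mathrm{\AA}$.
* **Bootstrap errors** resample standardised residuals with replacement
  within each contrast, rebuild pseudo-data around the best-fit model, and
  refit with a local polish; intervals are 2.5/97.5 percentiles. Residual
  (not case) resampling because the $Q$ points are a fixed design.
* **Model comparison** ranks variants by total $\chi^2$ and breaks ties
  (default $\Delta\chi^2 < 0.05$) toward fewer layers, with bootstrap
  relative interval widths available as the robustness diagnostic.

```{r}
sim <- simulate_scenario("rspa_crosslinked",
  q = q_grid_isis(60),
  noise = noise_model(), seed = 7
)
problem <- scenario_problem(sim)
fit <- refl_fit(problem, config = fit_config(de_itermax = 0, nm_maxit = 300), seed = 1)
glance(fit)
tidy(fit)
```

## Interpretation metrics

From a fitted layer the package computes the interpretation chain used for
adsorbed protein films. The volume fraction inverts the SLD mixing,
$\phi_l = (\rho_s-\rho_l)/(\rho_s-\rho_a)$; values slightly outside $[0,1]$
are flagged with a warning rather than an error because real fitted SLDs can
overshoot. Surface coverage is $\Gamma = \phi_l\,\tau\,\rho'_p$ (mg m$^{-2}$
with $\tau$ in $\mathrm{\AA}$ and the default protein mass density
$\rho'_p = 1.42$ g cm$^{-3}$); the area per molecule follows from
$\Gamma N_A/M_w$; and `packing_ratio()` compares it with a molecular
footprint. A 31 $\mathrm{\AA}$ layer at $\phi = 0.40$:

```{r}
interface_metrics(
  tibble::tibble(layer = "inner", phi = 0.40, tau = 31),
  molecular_weight = 165e3, footprint = 13600
)
```

Outputs are full precision; `as_printed()` (2 significant figures) is the
companion rounding for quoting results. Worked-example chains in reports
often propagate *rounded* intermediates, so recomputing a printed chain from
its printed inputs can land a unit or two off in the last digit -- e.g.
$0.40 \times 31 \times 1.42 \times 0.1 = 1.76$, which a chain built on an
unrounded table value quotes as 1.7. The package always reports what the
arithmetic gives.

`resin_comparison()` carries the same coverage units onto a porous affinity
resin: beads per mL from bead diameter and packing efficiency, envelope
surface area, internal pore area bracketed by outer:inner area ratios, and
the ligand concentration spread over that area. The ligand concentration can
be derived from a dynamic binding capacity and the ligand/antibody
molecular-weight ratio, or given directly; both are explicit inputs because
published roundings of this chain are not always mutually consistent.

```{r}
resin_comparison(per_molecule_area = 17100)
```

## The synthetic-data generator

No public instrument data accompanies the systems this package targets, so
`simulate_scenario()` generates multi-contrast experiments from a registry
of named layer structures: a bare oxide-coated wafer; an antibody adsorbed
directly to silica at pH 4.1 (8/31/53 $\mathrm{\AA}$ layers at
$\phi \approx 0.05/0.40/0.05$, and its rinsed variant), and at pH 6.2 (70
$\mathrm{\AA}$ total); protein A cross-linked to silanised silica (20
$\mathrm{\AA}$ linker + 69 $\mathrm{\AA}$ protein A at $\phi = 0.05$), with
BSA blocking, and with captured antibody (61/52/67 $\mathrm{\AA}$ layers);
and a PEG-blocked variant with a more extended (~250 $\mathrm{\AA}$)
profile. Where a structure's per-layer volume fractions or roughnesses are
not individually reported, the registry records a plausible assumption (for
example the pH 6.2 layer split of 15/30/25 $\mathrm{\AA}$, and all linker
$\phi$ values); those entries define reproducible test conditions and must
not be read as fitted truth.

The noise model emulates *reduced* data: Gaussian noise with
$\sigma = \max(0.02\,R_{\mathrm{true}},\ \mathrm{bkg}/3)$, a flat
$10^{-6}$ background, and 3% $\mathrm{d}Q/Q$ smearing. Gaussian rather than
Poisson because normalised curves are scaled counts, for which the
square-root counting error becomes a relative Gaussian width. Defaults
emulate a measurement with ~2% relative precision. At that level the dense
layers of every registered structure are well identified, while the
thinnest, most dilute layers (a hydration layer of a few \AA{} at
$\phi \approx 0.05$) sit at the identifiability edge: their thickness
estimate can wander by several percent from seed to seed because the joint
noisy optimum itself moves, not because the optimizer fails to find it.

What passing recovery tests shows -- and what it does not: simulated data
share the forward model, the resolution kernel and the noise law with the
fitter, so recovery demonstrates identifiability of the layer structures
under realistic counting statistics, not robustness to the imperfections of
real reduced data (stitching artefacts, $\lambda$-dependent backgrounds,
imperfect footprint correction, buffer SLD drift). The
`backing_sld` override on a contrast exists precisely because real
deuterated buffers rarely sit at the nominal pure-D$_2$O SLD.

## Problem sizes used by the test suite

The shipped tests run the forward-model equivalence on 1000 random stacks of
up to 5 slabs; bootstrap coverage on 50 seeded single-contrast repetitions
of a one-layer film (25 $Q$ points, 40 resamples); and the full-scenario
recovery on all eight registered structures at three contrasts, 20 seeds
each, on the default 120-point grid, refitting thicknesses and volume
fractions from the registry starting values with a Nelder--Mead budget.
These sizes are chosen so the whole suite runs on a laptop in minutes while
leaving the statistical checks meaningful; the same code paths scale to
denser grids and full global searches by changing `fit_config()`.

## Known limitations

* Real-valued SLDs only: absorption is ignored, appropriate for
  silicon/water/protein systems but not for strong absorbers.
* Raw-SLD layers are contrast-independent; a solvated non-material layer
  should be modelled via a material with an effective composition.
* No off-specular scattering, polarisation or magnetic SLDs.
* The bootstrap quantifies statistical uncertainty around a single optimum;
  it does not explore distinct local minima. Use `refl_compare()` across
  structural variants for that question.
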