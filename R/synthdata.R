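#' @title Synthetic-data generators
#' @description
#' The beamline spectra and spectropolarimeter scans behind a metal-binding
#' study are rarely deposited; this module regenerates every input the
#' pipeline consumes with known ground truth, so that parameter recovery can
#' be tested end to end. All generators are pure functions of their
#' parameters and an explicit seed.
#' @name synthdata
NULL

# evaluate expr under set.seed(seed) without disturbing the session RNG
.with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed)) stop("a finite integer seed is required")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Phenomenological XANES reference profile
#'
#' Describes a near-edge reference spectrum as an arctangent edge step plus
#' Gaussian features: an optional pre-edge peak (the weak 1s->3d transition
#' seen for octahedral first-row transition-metal sites) and any number of
#' post-edge resonances, with an optional linear post-edge slope.
#'
#' @param e0 Edge energy, eV.
#' @param width Edge width (arctangent scale), eV, > 0.
#' @param pre_edge Optional `list(center=, height=, width=)` for the
#'   pre-edge Gaussian; `center` must lie below `e0`.
#' @param features List of `list(center=, height=, width=)` post-edge
#'   Gaussians.
#' @param slope Linear slope applied above the edge (per eV).
#'
#' @return An object of class `reference_profile`.
#' @export
reference_profile <- function(e0, width, pre_edge = NULL, features = list(),
                              slope = 0) {
  if (width <= 0) stop("edge width must be positive")
  chk <- function(f, what) {
    if (!all(c("center", "height", "width") %in% names(f)))
      stop(what, " needs center, height and width")
    if (f$width <= 0) stop(what, " width must be positive")
  }
  if (!is.null(pre_edge)) {
    chk(pre_edge, "pre_edge")
    if (pre_edge$center >= e0) stop("pre-edge center must lie below e0")
  }
  for (f in features) chk(f, "feature")
  structure(list(e0 = e0, width = width, pre_edge = pre_edge,
                 features = features, slope = slope),
            class = "reference_profile")
}

.gauss <- function(e, center, height, width) {
  height * exp(-(e - center)^2 / (2 * width^2))
}

#' Generate a reference XANES spectrum
#'
#' Evaluates a [reference_profile] on an energy grid: a unit arctangent edge
#' step (so \eqn{\mu(E_0) = 0.5} for a bare edge) plus the profile's
#' Gaussian features; the pre-edge region is flat at zero and the post-edge
#' slope is switched on smoothly by the step itself. Deterministic.
#'
#' @param profile A [reference_profile].
#' @param grid Energy grid, eV; must span `[e0 - 200, e0 + 300]`.
#' @return An [xas_spectrum].
#' @export
make_reference_xanes <- function(profile, grid) {
  stopifnot(inherits(profile, "reference_profile"))
  grid <- as.numeric(grid)
  e0 <- profile$e0
  if (min(grid) > e0 - 200 || max(grid) < e0 + 300)
    stop("grid must span [e0 - 200, e0 + 300] eV around the edge at ", e0)
  for (f in profile$features)
    if (f$center < min(grid) || f$center > max(grid))
      stop("feature center ", f$center, " outside the energy grid")
  step <- 0.5 + atan((grid - e0) / profile$width) / pi
  mu <- step + profile$slope * (grid - e0) * step
  if (!is.null(profile$pre_edge)) {
    p <- profile$pre_edge
    mu <- mu + .gauss(grid, p$center, p$height, p$width)
  }
  for (f in profile$features) mu <- mu + .gauss(grid, f$center, f$height, f$width)
  xas_spectrum(grid, mu, "reference")
}

#' Mix spectra point by point
#'
#' Forms the linear combination \eqn{\mu_{mix}(E) = \sum_i f_i \mu_i(E)} of
#' spectra sharing one energy grid, plus seeded Gaussian noise. This is the
#' generative twin of linear-combination fitting: a spectrum of a partially
#' bound sample is a mixture of the bound-complex and free-ion references.
#'
#' @param components List of [xas_spectrum] on identical grids.
#' @param fractions Non-negative weights summing to 1 (tolerance 1e-9).
#' @param noise_sd Gaussian noise standard deviation in mu units
#'   (default 0.002; use 0 for noiseless data).
#' @param seed Integer seed (required).
#' @return An [xas_spectrum].
#' @export
make_mixture <- function(components, fractions, noise_sd = 0.002, seed) {
  fractions <- as.numeric(fractions)
  if (length(components) != length(fractions))
    stop("one fraction per component required")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be non-negative and sum to 1")
  grid <- components[[1]]$energies
  for (s in components[-1])
    if (length(s$energies) != length(grid) || any(s$energies != grid))
      stop("all components must share the same energy grid")
  mu <- Reduce(`+`, Map(function(s, f) f * s$mu, components, fractions))
  if (noise_sd > 0)
    mu <- mu + .with_seed(seed, stats::rnorm(length(mu), 0, noise_sd))
  else .with_seed(seed, NULL)  # still validates the seed
  xas_spectrum(grid, mu, "mixture")
}

#' Build an octahedral metal-site geometry
#'
#' Places the absorber at the origin and up to six oxygen ligands on the
#' octahedral axes at their shell distances. Axes are assigned in the fixed
#' order +x, -x, +y, -y, +z, -z, filling shells by descending coordination
#' number, so the geometry is reproducible. Each shell gets its own residue
#' id (`LG1`, `LG2`, ...), so shell grouping on the synthetic site yields
#' one rigid group per shell.
#'
#' @param shells List of `c(count, distance_A)` pairs (or an n x 2 matrix).
#' @param absorber Absorber element symbol (default `"Co"`).
#' @return An [atom_records] table: absorber first, then the ligands.
#' @export
make_site_geometry <- function(shells, absorber = "Co") {
  if (is.matrix(shells)) shells <- split(shells, row(shells)[, 1])
  ns <- vapply(shells, function(s) as.integer(s[1]), integer(1))
  rs <- vapply(shells, function(s) as.numeric(s[2]), numeric(1))
  if (sum(ns) > 6L) stop("octahedral placement supports at most 6 ligands")
  axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  ord <- order(-ns)
  xyz <- matrix(c(0, 0, 0), 1, 3)
  elem <- absorber; resname <- "ION"; resno <- 1L; aname <- absorber
  ax <- 1L
  for (j in ord) {
    if (ns[j] == 0L) next
    for (m in seq_len(ns[j])) {
      xyz <- rbind(xyz, axes[ax, ] * rs[j])
      elem <- c(elem, "O")
      resname <- c(resname, paste0("LG", j))
      resno <- c(resno, 1L + j)
      aname <- c(aname, "O")
      ax <- ax + 1L
    }
  }
  atom_records(elem, xyz[, 1], xyz[, 2], xyz[, 3],
               resname = resname, resno = resno, atom = aname)
}

#' Generate mu(E) with embedded EXAFS oscillations
#'
#' Inverts the extraction step: a smooth cubic-spline background
#' \eqn{b(E)} through the supplied control points carries the fine structure
#' as \eqn{\mu(E) = b(E)[1 + \chi(k(E))]} above the edge, with \eqn{\chi}
#' evaluated from the single-scattering forward model. Below the edge
#' \eqn{\mu = b(E)}. The oscillation is ramped in over \eqn{k < 1}
#' \eqn{\AA^{-1}} where the EXAFS equation is singular.
#'
#' @param model A [metal_site_model]; its `e0` anchors the wavenumber.
#' @param table A scatter table (see [default_scatter_table]).
#' @param grid Energy grid, eV; must extend at least 500 eV above `e0`.
#' @param bkg_knots Data frame with columns `E`, `mu`: spline control points
#'   below and above the edge (see [default_bkg_knots]).
#' @param noise_sd Gaussian noise sd in mu units (default 0.002).
#' @param seed Integer seed (required).
#' @return An [xas_spectrum].
#' @export
make_exafs_spectrum <- function(model, table, grid, bkg_knots,
                                noise_sd = 0.002, seed) {
  stopifnot(inherits(model, "metal_site_model"))
  grid <- as.numeric(grid)
  e0 <- model$e0
  if (max(grid) < e0 + 500)
    stop("grid must extend at least 500 eV above the edge")
  bf <- stats::splinefun(bkg_knots$E, bkg_knots$mu, method = "natural")
  bkg <- bf(grid)
  post <- grid > e0
  if (any(bkg[post] <= 0))
    stop("background is non-positive above the edge; adjust control points")
  mu <- bkg
  if (length(model$shells)) {
    k <- sqrt(.K_CONST * pmax(grid[post] - e0, 0))
    # the EXAFS equation is singular at k' = 0; ramp the oscillation in
    # below kfloor (1/A) instead of evaluating it there
    kfloor <- max(1, sqrt(max(0, -.K_CONST * model$ef)) + 0.2)
    ramp <- pmin(k / kfloor, 1)
    chi <- .chi_eval(model, table, pmax(k, kfloor)) * ramp
    mu[post] <- bkg[post] * (1 + chi)
  }
  if (noise_sd > 0)
    mu <- mu + .with_seed(seed, stats::rnorm(length(mu), 0, noise_sd))
  else .with_seed(seed, NULL)
  xas_spectrum(grid, mu, "synthetic exafs")
}

#' Default smooth background control points
#'
#' A typical fluorescence-mode absorption background: low, gently sloping
#' pre-edge, a jump at the edge, and a slow post-edge decay. Intended as the
#' `bkg_knots` argument of [make_exafs_spectrum].
#'
#' @param e0 Edge energy, eV.
#' @return A data frame with columns `E` and `mu`.
#' @export
default_bkg_knots <- function(e0) {
  data.frame(
    E  = e0 + c(-250, -150, -80, -30, 15, 60, 150, 300, 450, 600, 800),
    mu = c(0.100, 0.105, 0.110, 0.118, 1.060, 1.040, 1.000,
           0.950, 0.905, 0.865, 0.820))
}

#' Two-state unfolding transition
#'
#' Parameters of one van't Hoff two-state transition contributing to a CD
#' melt: midpoint `tm`, van't Hoff enthalpy `dh` (assumed
#' temperature-independent, i.e. \eqn{\Delta C_p = 0}), the fraction of the
#' total signal amplitude this transition carries, and linear native and
#' unfolded baselines in ellipticity units.
#'
#' @param tm Melting temperature, degC.
#' @param dh Van't Hoff enthalpy, kJ/mol, > 0.
#' @param amplitude Fraction of the curve amplitude in (0, 1].
#' @param native `c(intercept, slope)` of the folded baseline
#'   (deg cm^2 dmol^-1, slope per degC; default a flat helical signal).
#' @param unfolded `c(intercept, slope)` of the unfolded baseline.
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(tm, dh, amplitude = 1,
                             native = c(-20000, 0), unfolded = c(-2000, 0)) {
  if (dh <= 0) stop("van't Hoff enthalpy must be positive")
  if (amplitude <= 0 || amplitude > 1) stop("amplitude must be in (0, 1]")
  structure(list(tm = tm, dh = dh, amplitude = amplitude,
                 native = native, unfolded = unfolded),
            class = "transition_model")
}

#' Generate a CD thermal scan
#'
#' Sums one or two van't Hoff two-state transitions:
#' \eqn{\Theta(T) = \sum_j a_j [\theta_{N,j}(T) + (\theta_{U,j}(T) -
#' \theta_{N,j}(T)) f_{U,j}(T)]} with
#' \eqn{f_U = K/(1+K)}, \eqn{K = \exp[-(\Delta H/R)(1/T - 1/T_m)]}
#' (temperatures in kelvin), plus seeded Gaussian noise. At \eqn{T = T_m}
#' each transition is exactly half unfolded.
#'
#' @param transitions List of one or two [transition_model]s; amplitudes
#'   must sum to 1.
#' @param grid Temperature grid, degC, within `[20, 95]` (the standard
#'   scan protocol); nominally 0.5 degC steps.
#' @param noise_sd Gaussian noise sd in ellipticity units (default 0).
#' @param seed Integer seed (required).
#' @return A [melting_curve].
#' @export
make_melting_curve <- function(transitions, grid = seq(20, 95, by = 0.5),
                               noise_sd = 0, seed) {
  if (inherits(transitions, "transition_model")) transitions <- list(transitions)
  if (!length(transitions)) stop("at least one transition is required")
  if (length(transitions) > 2L) stop("at most two transitions are supported")
  amps <- vapply(transitions, `[[`, numeric(1), "amplitude")
  if (abs(sum(amps) - 1) > 1e-9) stop("transition amplitudes must sum to 1")
  grid <- as.numeric(grid)
  if (min(grid) < 20 - 1e-9 || max(grid) > 95 + 1e-9)
    stop("temperature grid must lie within [20, 95] degC")
  R <- 8.31446261815324  # J mol^-1 K^-1
  Tk <- grid + 273.15
  theta <- numeric(length(grid))
  for (tr in transitions) {
    tmk <- tr$tm + 273.15
    K <- exp(-(tr$dh * 1000 / R) * (1 / Tk - 1 / tmk))
    fU <- K / (1 + K)
    thN <- tr$native[1] + tr$native[2] * grid
    thU <- tr$unfolded[1] + tr$unfolded[2] * grid
    theta <- theta + tr$amplitude * (thN + (thU - thN) * fU)
  }
  if (noise_sd > 0)
    theta <- theta + .with_seed(seed, stats::rnorm(length(theta), 0, noise_sd))
  else .with_seed(seed, NULL)
  melting_curve(grid, theta, "synthetic melt")
}
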