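#' @title EXAFS extraction, forward modelling and shell refinement
#' @description
#' Extraction of the fine-structure signal \eqn{\chi(k)} from \eqn{\mu(E)}
#' by spline background removal, a single-scattering forward EXAFS model,
#' grouping of a site geometry into coordination shells, and constrained
#' least-squares refinement of shell distances and the Fermi-energy shift.
#' @name exafs
NULL

# 2 m_e / hbar^2 in eV^-1 A^-2: converts photoelectron energy above the
# edge to k^2
.K_CONST <- 0.262468

#' EXAFS fine-structure signal
#'
#' @param k Photoelectron wavenumber, inverse Angstrom, strictly increasing,
#'   non-negative.
#' @param chi Dimensionless fine structure, same length.
#' @param k_weight Integer 0-3: the k-weight already applied to `chi`
#'   (0 for a plain signal).
#' @return An object of class `exafs_signal`.
#' @export
exafs_signal <- function(k, chi, k_weight = 0L) {
  k <- as.numeric(k); chi <- as.numeric(chi)
  if (length(k) != length(chi)) stop("k and chi must have the same length")
  if (any(k < 0)) stop("k must be non-negative")
  if (any(diff(k) <= 0)) stop("k must be strictly increasing")
  if (!k_weight %in% 0:3) stop("k_weight must be an integer in 0..3")
  structure(list(k = k, chi = chi, k_weight = as.integer(k_weight)),
            class = "exafs_signal")
}

#' Coordination shell
#'
#' One group of like scatterers at approximately equal distance from the
#' absorber: coordination number N, mean distance R and Debye-Waller factor
#' \eqn{\sigma^2} (mean-square radial disorder).
#'
#' @param n Coordination number, positive integer.
#' @param r Absorber-scatterer distance, Angstrom, in (1, 6).
#' @param sigma2 Debye-Waller factor, Angstrom^2, in \[0, 0.05\]
#'   (default 0.003, typical of a well-ordered first shell).
#' @param element Scatterer element (default `"O"`).
#' @return An object of class `scattering_shell`.
#' @export
scattering_shell <- function(n, r, sigma2 = 0.003, element = "O") {
  n <- as.integer(n)
  if (n < 1L) stop("coordination number must be a positive integer")
  if (r <= 1 || r >= 6) stop("shell distance must lie in (1, 6) Angstrom")
  if (sigma2 < 0 || sigma2 > 0.05)
    stop("sigma2 must lie in [0, 0.05] Angstrom^2")
  structure(list(n = n, r = r, sigma2 = sigma2, element = element),
            class = "scattering_shell")
}

#' Metal-site EXAFS model
#'
#' Everything the EXAFS equation needs: the absorber, the energy zero
#' \eqn{E_0}, the refinable Fermi-energy shift \eqn{\Delta E_F}, the
#' many-body amplitude reduction \eqn{S_0^2}, the coordination shells, and a
#' rigid-group map assigning shells to groups that move with one shared
#' radial offset during refinement.
#'
#' @param shells List of [scattering_shell]s.
#' @param e0 Edge energy, eV.
#' @param ef Fermi-energy shift, eV, |ef| <= 15 (default 0).
#' @param s02 Amplitude reduction factor, in (0.5, 1.1\] (default 0.9).
#' @param absorber Absorber element (default `"Co"`).
#' @param groups Character vector of rigid-group labels, one per shell
#'   (default: each shell its own group).
#' @return An object of class `metal_site_model`.
#' @export
metal_site_model <- function(shells, e0, ef = 0, s02 = 0.9,
                             absorber = "Co", groups = NULL) {
  if (inherits(shells, "scattering_shell")) shells <- list(shells)
  for (sh in shells)
    if (!inherits(sh, "scattering_shell")) stop("shells must be scattering_shell objects")
  if (abs(ef) > 15) stop("|Fermi shift| must not exceed 15 eV")
  if (s02 <= 0.5 || s02 > 1.1) stop("S0^2 must lie in (0.5, 1.1]")
  if (is.null(groups)) groups <- sprintf("g%d", seq_along(shells))
  if (length(groups) != length(shells))
    stop("one rigid-group label per shell is required")
  structure(list(absorber = absorber, e0 = e0, ef = ef, s02 = s02,
                 shells = shells, groups = as.character(groups)),
            class = "metal_site_model")
}

#' @export
print.metal_site_model <- function(x, ...) {
  cat(sprintf("<metal_site_model> %s edge at %.1f eV, dE_F = %.2f eV, S0^2 = %.2f\n",
              x$absorber, x$e0, x$ef, x$s02))
  for (i in seq_along(x$shells)) {
    sh <- x$shells[[i]]
    cat(sprintf("  shell %d [%s]: %d %s at R = %.3f A, sigma2 = %.4f A^2\n",
                i, x$groups[i], sh$n, sh$element, sh$r, sh$sigma2))
  }
  invisible(x)
}

#' Backscattering amplitude, phase and mean free path
#'
#' The element-specific ingredients of the EXAFS equation: backscattering
#' amplitude \eqn{f(k)}, total phase shift \eqn{\phi(k)} and photoelectron
#' mean free path \eqn{\lambda(k)}. The default oxygen table is a smooth
#' phenomenological parameterization -- amplitude decaying with k, a
#' near-linear phase, and a mean free path growing with k -- used both by
#' the signal generator and the fitter, which makes distance recovery
#' self-consistent. Measured or computed tables can be supplied as
#' four-column text via [read_scatter_table].
#'
#' @param f,phase,lambda Functions of k (inverse Angstrom) returning the
#'   amplitude (dimensionless), phase (rad) and mean free path (Angstrom).
#' @param provenance Free-text tag recording where the table came from.
#' @return An object of class `scatter_table`.
#' @export
scatter_table <- function(f, phase, lambda, provenance = "user") {
  stopifnot(is.function(f), is.function(phase), is.function(lambda))
  structure(list(f = f, phase = phase, lambda = lambda,
                 provenance = provenance),
            class = "scatter_table")
}

#' @rdname scatter_table
#' @export
default_scatter_table <- function() {
  scatter_table(
    f = function(k) 0.90 * exp(-0.15 * k),
    phase = function(k) pi - 0.90 * k,
    lambda = function(k) 4 + 0.8 * k,
    provenance = "built-in phenomenological oxygen table")
}

#' @rdname scatter_table
#' @param path Whitespace-delimited text with `#` comments and four numeric
#'   columns: k (1/A), f(k), phi(k) (rad), lambda(k) (A); interpolated
#'   linearly.
#' @export
read_scatter_table <- function(path) {
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 4L) stop("scatter table needs 4 columns: k, f, phi, lambda")
  if (any(tab[[2]] <= 0)) stop("backscattering amplitude must be positive")
  k <- tab[[1]]
  mk <- function(col) {
    y <- tab[[col]]
    function(kk) stats::approx(k, y, xout = kk, rule = 2)$y
  }
  scatter_table(mk(2), mk(3), mk(4),
                provenance = paste("file:", basename(path)))
}

#' Single-scattering forward EXAFS model
#'
#' Evaluates the standard plane-wave single-scattering EXAFS equation
#' \deqn{\chi(k) = S_0^2 \sum_i \frac{N_i f_i(k')}{k' R_i^2}
#'   e^{-2 k'^2 \sigma_i^2} e^{-2 R_i/\lambda(k')}
#'   \sin(2 k' R_i + \phi_i(k'))}
#' with the wavenumber re-referenced by the Fermi shift,
#' \eqn{k' = \sqrt{k^2 + c\,\Delta E_F}}, \eqn{c = 0.262468}
#' eV\eqn{^{-1}}A\eqn{^{-2}}. Deterministic; linear in \eqn{S_0^2} and in
#' each \eqn{N_i}.
#'
#' @param model A [metal_site_model].
#' @param table A [scatter_table].
#' @param kgrid Wavenumber grid, inverse Angstrom, > 0.
#' @return An [exafs_signal] (k-weight 0).
#' @export
forward_chi <- function(model, table, kgrid) {
  exafs_signal(as.numeric(kgrid), .chi_eval(model, table, as.numeric(kgrid)), 0L)
}

# raw evaluation of the EXAFS equation on an arbitrary k vector
.chi_eval <- function(model, table, k) {
  stopifnot(inherits(model, "metal_site_model"), inherits(table, "scatter_table"))
  k2 <- k^2 + .K_CONST * model$ef
  if (any(k2 <= 0))
    stop(sprintf(
      "Fermi shift %.2f eV makes k' imaginary for k <= %.3f 1/A on this grid",
      model$ef, sqrt(max(0, -.K_CONST * model$ef))))
  kp <- sqrt(k2)
  chi <- numeric(length(k))
  for (sh in model$shells) {
    chi <- chi + sh$n * table$f(kp) / (kp * sh$r^2) *
      exp(-2 * kp^2 * sh$sigma2) * exp(-2 * sh$r / table$lambda(kp)) *
      sin(2 * kp * sh$r + table$phase(kp))
  }
  model$s02 * chi
}

#' Extract chi(k) by spline background removal
#'
#' AUTOBK-style extraction: above the edge the normalized absorption is
#' re-gridded onto uniform k, and a cubic B-spline background with
#' `floor(2 * dk * rbkg / pi) + 1` coefficients is determined by linear
#' least squares so that the magnitude of the Fourier transform of the
#' k-weighted residual \eqn{\mu_{norm} - b(k)} is minimal below `rbkg`. The
#' knot count caps the spline's information content at distances below
#' `rbkg`, so the background can absorb the smooth atomic absorption but
#' not the structural oscillations. \eqn{\chi = \mu_{norm} - b(k)} (the
#' edge step is already 1).
#'
#' @param n A `normalized_xanes` extending at least 400 eV above the edge.
#' @param rbkg Background cutoff distance, Angstrom, > 0 (default 1.0).
#' @param k_weight k-weight used in the background determination
#'   (default 2).
#' @param dk Uniform k-grid spacing of the output (default 0.05 1/A).
#' @return An [exafs_signal] with `chi` unweighted (k-weight 0).
#' @export
extract_chi <- function(n, rbkg = 1.0, k_weight = 2, dk = 0.05) {
  stopifnot(inherits(n, "normalized_xanes"))
  if (rbkg <= 0) stop("rbkg must be positive")
  if (max(n$energies) < n$e0 + 400)
    stop("need at least 400 eV of data above the edge to extract chi(k)")
  post <- n$energies > n$e0
  kdat <- sqrt(.K_CONST * (n$energies[post] - n$e0))
  mudat <- n$norm_mu[post]
  kmax <- max(kdat)
  kg <- seq(dk, floor(kmax / dk) * dk, by = dk)
  mu <- stats::approx(kdat, mudat, xout = kg, rule = 2)$y
  nb <- floor(2 * (max(kg) - min(kg)) * rbkg / pi) + 1L
  nb <- max(nb, 4L)
  B <- splines::bs(kg, df = nb, degree = 3, intercept = TRUE)
  w <- kg^k_weight
  # discrete FT rows (real and imaginary parts) on an R grid below rbkg
  rg <- seq(rbkg / (4 * nb), rbkg, length.out = 4L * nb)
  ph <- outer(rg, kg, function(r, k) 2 * r * k)
  Fc <- cos(ph); Fs <- sin(ph)
  Wt <- t(B * w)                       # nb x nk
  A <- rbind(Fc %*% t(Wt), Fs %*% t(Wt)) * dk
  y <- c(Fc %*% (mu * w), Fs %*% (mu * w)) * dk
  coefs <- stats::lm.fit(A, y)$coefficients
  coefs[!is.finite(coefs)] <- 0
  bkg <- as.numeric(B %*% coefs)
  exafs_signal(kg, mu - bkg, 0L)
}

#' Excise a sphere around the absorbing metal
#'
#' Keeps every atom within `radius` of the unique atom of element `center`
#' (closed boundary; the center itself is retained). Mirrors the standard
#' practice of cutting the local cluster that contributes to the XAS signal
#' out of a larger model.
#'
#' @param atoms An [atom_records] table.
#' @param center Element symbol of the absorber; must occur exactly once.
#' @param radius Sphere radius, Angstrom, >= 0.
#' @return The retained [atom_records].
#' @export
excise_sphere <- function(atoms, center = "Co", radius = 5.0) {
  stopifnot(inherits(atoms, "atom_records"))
  idx <- which(atoms$elem == center)
  if (length(idx) != 1L)
    stop("expected exactly one ", center, " atom, found ", length(idx))
  c0 <- as.numeric(atoms[idx, c("x", "y", "z")])
  d <- sqrt((atoms$x - c0[1])^2 + (atoms$y - c0[2])^2 + (atoms$z - c0[3])^2)
  out <- atoms[d <= radius + 1e-12, , drop = FALSE]
  class(out) <- c("atom_records", "data.frame")
  out
}

#' Group a site geometry into coordination shells
#'
#' Sorts ligand distances ascending and clusters them greedily: a new shell
#' starts whenever the next distance exceeds the running mean of the
#' current shell by more than `tol`. Each shell's R is the mean member
#' distance and N its member count. Rigid-group labels are carried from
#' residue identity (residue name + number) when a shell is drawn from a
#' single residue, otherwise the shell stands alone.
#'
#' @param site An [atom_records] table containing the absorber and ligands.
#' @param absorber Absorber element symbol.
#' @param tol Distance tolerance for shell splitting, Angstrom
#'   (default 0.1).
#' @param e0 Edge energy passed to the model, eV (default 7709, the Co
#'   K-edge).
#' @param ... Passed to [metal_site_model] (`ef`, `s02`).
#' @return A [metal_site_model] with shells sorted by ascending R.
#' @export
group_shells <- function(site, absorber = "Co", tol = 0.1, e0 = 7709, ...) {
  stopifnot(inherits(site, "atom_records"))
  idx <- which(site$elem == absorber)
  if (length(idx) != 1L)
    stop("expected exactly one ", absorber, " atom, found ", length(idx))
  lig <- site[-idx, , drop = FALSE]
  if (!nrow(lig)) stop("site contains no ligand atoms")
  c0 <- as.numeric(site[idx, c("x", "y", "z")])
  d <- sqrt((lig$x - c0[1])^2 + (lig$y - c0[2])^2 + (lig$z - c0[3])^2)
  ord <- order(d)
  d <- d[ord]; lig <- lig[ord, , drop = FALSE]
  shell_id <- integer(length(d))
  cur <- 1L; members <- d[1]; shell_id[1] <- 1L
  for (i in seq_along(d)[-1]) {
    if (d[i] - mean(members) > tol) {
      cur <- cur + 1L; members <- d[i]
    } else members <- c(members, d[i])
    shell_id[i] <- cur
  }
  shells <- list(); groups <- character(0)
  for (g in seq_len(cur)) {
    m <- shell_id == g
    el <- names(sort(table(lig$elem[m]), decreasing = TRUE))[1]
    shells[[g]] <- scattering_shell(sum(m), mean(d[m]), element = el)
    res <- unique(paste0(lig$resname[m], lig$resno[m]))
    groups[g] <- if (length(res) == 1L) res else paste0("shell", g)
  }
  metal_site_model(shells, e0 = e0, absorber = absorber, groups = groups, ...)
}

#' Misfit R-factor between two EXAFS signals
#'
#' \eqn{R = 100 \sum |k^w \chi_{obs} - k^w \chi_{mod}| /
#' \sum |k^w \chi_{obs}|}, in percent. Normalized by the observed signal,
#' so the arguments are not interchangeable; invariant to rescaling both
#' signals together.
#'
#' @param obs,model [exafs_signal]s on a common k grid.
#' @param k_weight k-weight applied before comparison (default 2).
#' @return R-factor in percent.
#' @export
r_factor <- function(obs, model, k_weight = 2) {
  stopifnot(inherits(obs, "exafs_signal"), inherits(model, "exafs_signal"))
  if (length(obs$k) != length(model$k) ||
      max(abs(obs$k - model$k)) > 1e-9)
    stop("observed and model signals must share one k grid")
  w <- obs$k^k_weight
  denom <- sum(abs(obs$chi * w))
  if (denom == 0) stop("observed signal is identically zero")
  100 * sum(abs(obs$chi * w - model$chi * w)) / denom
}

#' Constrained refinement of shell distances and Fermi shift
#'
#' Bounded Levenberg-Marquardt least squares on the k-weighted difference
#' between observed and modelled \eqn{\chi(k)} over `k_range`. The free
#' parameters are the Fermi-energy shift and one radial offset per rigid
#' group: shells sharing a rigid-group label move together, the
#' distance-only analogue of treating a coordinating residue as a rigid
#' body. Coordination numbers, \eqn{\sigma^2} and \eqn{S_0^2} stay fixed.
#' Box constraints keep every refined shell inside the validity bounds of
#' [scattering_shell].
#'
#' @param obs Observed [exafs_signal] (unweighted chi) covering `k_range`.
#' @param m0 Starting [metal_site_model].
#' @param table A [scatter_table].
#' @param free Character vector among `"ef"`, `"radii"`; both by default.
#' @param k_range Fit window in k, default `c(3, 12)` 1/A.
#' @param k_weight k-weight of the residual, default 2.
#' @return An object of class `exafs_fit`: `model` (refined), `deltas`
#'   (named parameter changes), `r_factor` (percent), `k_range`,
#'   `converged`.
#' @export
refine_site <- function(obs, m0, table = default_scatter_table(),
                        free = c("ef", "radii"), k_range = c(3, 12),
                        k_weight = 2) {
  stopifnot(inherits(obs, "exafs_signal"), inherits(m0, "metal_site_model"))
  free <- match.arg(free, c("ef", "radii"), several.ok = TRUE)
  if (!length(m0$shells)) stop("the starting model must have at least one shell")
  sel <- obs$k >= k_range[1] & obs$k <= k_range[2]
  if (sum(sel) < 10L) stop("observed signal does not cover the k range")
  kfit <- obs$k[sel]; cobs <- obs$chi[sel]; w <- kfit^k_weight
  glabs <- if ("radii" %in% free) unique(m0$groups) else character(0)
  r0 <- vapply(m0$shells, `[[`, numeric(1), "r")
  p0 <- c(if ("ef" %in% free) c(ef = m0$ef),
          stats::setNames(rep(0, length(glabs)), glabs))
  if (!length(p0)) stop("free parameter mask is empty")
  lower <- upper <- numeric(length(p0))
  names(lower) <- names(upper) <- names(p0)
  if ("ef" %in% free) { lower["ef"] <- -15; upper["ef"] <- 15 }
  for (g in glabs) {
    memb <- which(m0$groups == g)
    lower[g] <- max(1.000001 - r0[memb])
    upper[g] <- min(5.999999 - r0[memb])
  }
  build <- function(p) {
    sh <- m0$shells
    if (length(glabs))
      for (i in seq_along(sh)) sh[[i]]$r <- r0[i] + p[[m0$groups[i]]]
    metal_site_model(sh, e0 = m0$e0,
                     ef = if ("ef" %in% free) p[["ef"]] else m0$ef,
                     s02 = m0$s02, absorber = m0$absorber,
                     groups = m0$groups)
  }
  resid_fn <- function(p) {
    p <- stats::setNames(as.numeric(p), names(p0))
    r <- w * (forward_chi(build(p), table, kfit)$chi - cobs)
    if (any(!is.finite(r))) stop("non-finite residuals during refinement")
    r
  }
  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-10, maxiter = 500))
  phat <- stats::setNames(as.numeric(fit$par), names(p0))
  refined <- build(phat)
  rfac <- r_factor(exafs_signal(kfit, cobs),
                   forward_chi(refined, table, kfit), k_weight)
  deltas <- c(if ("ef" %in% free) c(ef = refined$ef - m0$ef),
              stats::setNames(phat[glabs], paste0("dr_", glabs)))
  structure(list(model = refined, deltas = deltas, r_factor = rfac,
                 k_range = k_range, k_weight = k_weight,
                 converged = fit$info %in% 1:4),
            class = "exafs_fit")
}

#' @export
print.exafs_fit <- function(x, ...) {
  cat(sprintf("<exafs_fit> R-factor = %.3f%% over k = [%g, %g] 1/A (k-weight %d)%s\n",
              x$r_factor, x$k_range[1], x$k_range[2], x$k_weight,
              if (x$converged) "" else " [NOT converged]"))
  print(x$model)
  invisible(x)
}
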