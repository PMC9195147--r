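#' @title XANES normalization and linear-combination fitting
#' @description
#' Athena-style edge-step normalization, pre-edge peak characterization, and
#' constrained two-component linear-combination fitting (LCF) that
#' decomposes a sample spectrum into bound-complex and free-ion references.
#' @name xanes
NULL

#' Locate the absorption edge
#'
#' Returns the energy of the maximum first derivative of \eqn{\mu(E)},
#' refined by quadratic interpolation over the three derivative points
#' around the discrete maximum. A linear slope added to the spectrum leaves
#' the result unchanged (constant derivative offset).
#'
#' @param s An [xas_spectrum] (or `normalized_xanes`).
#' @return Edge energy \eqn{E_0}, eV.
#' @export
edge_energy <- function(s) {
  e <- if (inherits(s, "normalized_xanes")) s$energies else s$energies
  mu <- if (inherits(s, "normalized_xanes")) s$norm_mu else s$mu
  span <- max(mu) - min(mu)
  noise <- stats::median(abs(diff(mu, differences = 2))) / sqrt(6)
  if (span <= 10 * max(noise, .Machine$double.eps))
    stop("no absorption edge found: spectrum is flat relative to its noise")
  d <- diff(mu) / diff(e)
  em <- (e[-1] + e[-length(e)]) / 2
  i <- which.max(d)
  if (i == 1L || i == length(d)) return(em[i])
  # quadratic through (em[i-1..i+1], d[i-1..i+1]); vertex of the parabola
  x <- em[(i - 1):(i + 1)]; y <- d[(i - 1):(i + 1)]
  den <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / den
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / den
  if (a >= 0) return(em[i])
  -b / (2 * a)
}

#' Normalize a XANES spectrum to unit edge step
#'
#' Standard edge-step normalization: a straight line fitted over the
#' pre-edge range is subtracted everywhere; a quadratic fitted over the
#' post-edge range defines the edge step as its value at \eqn{E_0} minus the
#' pre-edge line there; the result is divided by the step and flattened
#' above the edge by removing the residual curvature of the post-edge
#' polynomial. The post-edge of the output averages 1 by construction, so
#' spectra measured on different scales become comparable.
#'
#' @param s An [xas_spectrum].
#' @param pre_range Offsets from \eqn{E_0} bounding the pre-edge fit,
#'   default `c(-150, -30)` eV.
#' @param post_range Offsets bounding the post-edge fit, default
#'   `c(50, 300)` eV.
#' @param e0 Edge energy; located with [edge_energy] when `NULL`.
#' @return An object of class `normalized_xanes`: list with `energies`,
#'   `norm_mu`, `e0`, `edge_step`, `label`.
#' @export
normalize_xanes <- function(s, pre_range = c(-150, -30),
                            post_range = c(50, 300), e0 = NULL) {
  if (inherits(s, "normalized_xanes"))
    s <- xas_spectrum(s$energies, s$norm_mu, s$label)
  stopifnot(inherits(s, "xas_spectrum"))
  if (is.null(e0)) e0 <- edge_energy(s)
  e <- s$energies; mu <- s$mu
  pre <- e >= e0 + pre_range[1] & e <= e0 + pre_range[2]
  post <- e >= e0 + post_range[1] & e <= e0 + post_range[2]
  if (sum(pre) < 5L) stop("pre-edge range contains fewer than 5 points")
  if (sum(post) < 5L) stop("post-edge range contains fewer than 5 points")
  lin <- stats::lm.fit(cbind(1, e[pre]), mu[pre])$coefficients
  qua <- stats::lm.fit(cbind(1, e[post], e[post]^2), mu[post])$coefficients
  line <- lin[1] + lin[2] * e
  quad <- qua[1] + qua[2] * e + qua[3] * e^2
  step <- (qua[1] + qua[2] * e0 + qua[3] * e0^2) - (lin[1] + lin[2] * e0)
  if (!is.finite(step) || step <= 0)
    stop("non-positive edge step: spectrum is inverted or has no edge")
  nm <- (mu - line) / step
  above <- e > e0
  nm[above] <- nm[above] - (quad[above] - step - line[above]) / step
  structure(list(energies = e, norm_mu = nm, e0 = e0, edge_step = step,
                 label = s$label),
            class = "normalized_xanes")
}

#' @export
print.normalized_xanes <- function(x, ...) {
  cat(sprintf("<normalized_xanes> '%s': e0 = %.2f eV, edge step = %.4g\n",
              x$label, x$e0, x$edge_step))
  invisible(x)
}

#' Characterize the pre-edge peak
#'
#' Locates and quantifies the weak 1s->3d pre-edge feature in the window
#' \eqn{[E_0-25, E_0-2]} eV of a normalized spectrum. A candidate center is
#' first identified as the most prominent interior local maximum of the
#' residual from a straight-line fit over the window -- the rising edge
#' tail at the window's upper end is monotonic and therefore never a
#' candidate. The window is then fitted with the standard pre-edge model:
#' a Gaussian peak on a base of straight line plus arctangent edge onset,
#' so the tail of the main edge cannot leak into the peak height. The
#' feature is flagged absent when no interior candidate exists or the
#' fitted height is below three times the fit residual standard deviation.
#'
#' @param n A `normalized_xanes`.
#' @param window Offsets from \eqn{E_0}, default `c(-25, -2)` eV.
#' @return List with `center` (eV), `height`, `detected` (logical) and
#'   `residual_sd`.
#' @export
pre_edge_peak <- function(n, window = c(-25, -2)) {
  stopifnot(inherits(n, "normalized_xanes"))
  sel <- n$energies >= n$e0 + window[1] & n$energies <= n$e0 + window[2]
  if (sum(sel) < 10L) stop("pre-edge window lies outside the data")
  e <- n$energies[sel]; y <- n$norm_mu[sel]
  e0 <- n$e0
  base <- stats::lm.fit(cbind(1, e), y)
  r <- as.numeric(y - cbind(1, e) %*% base$coefficients)
  interior <- 2:(length(r) - 1)
  cand <- interior[r[interior] > r[interior - 1] &
                   r[interior] >= r[interior + 1] & r[interior] > 0]
  if (!length(cand))
    return(list(center = NA_real_, height = 0, detected = FALSE,
                residual_sd = stats::sd(r)))
  c0 <- e[cand[which.max(r[cand])]]
  h0 <- max(r[cand], 1e-4)
  fit <- try(minpack.lm::nlsLM(
    y ~ a + b * e + s * (0.5 + atan((e - ec) / we) / pi) +
      h * exp(-(e - cc)^2 / (2 * w^2)),
    start = list(a = 0, b = 0, s = 1, ec = e0, we = 2,
                 h = h0, cc = c0, w = 1.5),
    lower = c(-Inf, -Inf, 0.05, e0 - 8, 0.5, 0, c0 - 3, 0.3),
    upper = c(Inf, Inf, 5, e0 + 15, 10, Inf, c0 + 3, 5),
    control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(center = NA_real_, height = 0, detected = FALSE,
                residual_sd = stats::sd(r)))
  p <- stats::coef(fit)
  rs <- stats::sd(stats::residuals(fit))
  list(center = unname(p["cc"]), height = unname(p["h"]),
       detected = unname(p["h"]) >= 3 * rs, residual_sd = rs)
}

#' Two-component linear-combination fit
#'
#' Models a normalized target spectrum as \eqn{f \mu_A + (1-f) \mu_B} and
#' minimizes the pointwise squared difference over the fit window. With the
#' complementary-fraction constraint the optimum is the closed form
#' \eqn{f^* = \sum (t-b)(a-b) / \sum (a-b)^2}, clipped to `[0, 1]`.
#' Components are interpolated linearly onto the target's grid.
#'
#' @param target,comp_a,comp_b `normalized_xanes` objects; `comp_a` is the
#'   bound-complex reference, `comp_b` the free-ion (buffer) reference.
#' @param fit_range Offsets from the target's \eqn{E_0} bounding the fit
#'   window, default `c(-20, 80)` eV.
#' @return An object of class `lcf_result`: `fractions` (named, summing to
#'   1), `residual` (RMS misfit), `fit_range` (absolute eV), plus the fit
#'   grid and model values used by [difference_spectrum].
#' @export
lcf <- function(target, comp_a, comp_b, fit_range = c(-20, 80)) {
  stopifnot(inherits(target, "normalized_xanes"),
            inherits(comp_a, "normalized_xanes"),
            inherits(comp_b, "normalized_xanes"))
  lo <- target$e0 + fit_range[1]; hi <- target$e0 + fit_range[2]
  sel <- target$energies >= lo & target$energies <= hi
  if (sum(sel) < 5L) stop("fit range contains fewer than 5 target points")
  e <- target$energies[sel]
  t <- target$norm_mu[sel]
  a <- stats::approx(comp_a$energies, comp_a$norm_mu, xout = e, rule = 1)$y
  b <- stats::approx(comp_b$energies, comp_b$norm_mu, xout = e, rule = 1)$y
  if (anyNA(a) || anyNA(b))
    stop("components do not cover the fit range [", lo, ", ", hi, "] eV")
  den <- sum((a - b)^2)
  if (den < 1e-12)
    stop("degenerate components: the two references are indistinguishable")
  f <- sum((t - b) * (a - b)) / den
  f <- min(max(f, 0), 1)
  model <- f * a + (1 - f) * b
  structure(list(fractions = c(bound = f, free = 1 - f),
                 residual = sqrt(mean((t - model)^2)),
                 fit_range = c(lo, hi), energies = e, model = model,
                 target = t),
            class = "lcf_result")
}

#' @export
print.lcf_result <- function(x, ...) {
  cat(sprintf(
    "<lcf_result> bound = %.3f, free = %.3f, RMS residual = %.4g over [%.0f, %.0f] eV\n",
    x$fractions["bound"], x$fractions["free"], x$residual,
    x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Difference spectrum of an LCF fit
#'
#' Pointwise `target - model` on the fit grid: the part of the sample
#' spectrum the two-component model does not explain.
#'
#' @param result An [lcf] result.
#' @return An [xas_spectrum] over the fit window.
#' @export
difference_spectrum <- function(result) {
  stopifnot(inherits(result, "lcf_result"))
  xas_spectrum(result$energies, result$target - result$model, "difference")
}
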