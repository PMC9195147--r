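#' @title Melting-temperature extraction from CD thermal scans
#' @description
#' The melting temperature of a protein is read off a thermal scan of the
#' 222 nm ellipticity as the position of the extremum of its first
#' derivative; a two-step denaturation shows up as two resolvable maxima.
#' @name melting
NULL

# prominence of each local maximum of y: height above the higher of the two
# minima separating it from taller peaks (or from the record ends)
.peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    lmin <- min(y[1:p]); i <- p
    while (i > 1) {
      i <- i - 1
      if (y[i] > y[p]) { lmin <- min(y[i:p]); break }
    }
    if (i == 1 && y[1] <= y[p]) lmin <- min(y[1:p])
    rmin <- min(y[p:length(y)]); i <- p
    while (i < length(y)) {
      i <- i + 1
      if (y[i] > y[p]) { rmin <- min(y[p:i]); break }
    }
    if (i == length(y) && y[length(y)] <= y[p]) rmin <- min(y[p:length(y)])
    y[p] - max(lmin, rmin)
  }, numeric(1))
}

# Refine derivative-peak positions by modelling |dTheta/dT| as a sum of
# sech^2-shaped components (the derivative of a two-state transition is
# sech^2 in the van't Hoff variable) on a linear base. When two
# transitions overlap, each raw local maximum is pulled toward the other
# by the neighbour's tail; fitting the components jointly removes that
# bias. Falls back to the interpolated raw positions if the fit fails or
# wanders.
.refine_peak_centers <- function(tt, ad, peaks, tm0) {
  w0 <- rep(2.5, length(peaks))
  a0 <- ad[peaks]
  df <- data.frame(T = tt, y = ad)
  form <- if (length(peaks) == 2L)
    y ~ b0 + b1 * T + a1 / cosh((T - c1) / w1)^2 + a2 / cosh((T - c2) / w2)^2
  else
    y ~ b0 + b1 * T + a1 / cosh((T - c1) / w1)^2
  start <- c(list(b0 = 0, b1 = 0, a1 = a0[1], c1 = tm0[1], w1 = w0[1]),
             if (length(peaks) == 2L)
               list(a2 = a0[2], c2 = tm0[2], w2 = w0[2]))
  lower <- c(-Inf, -Inf, 0, min(tt), 0.5,
             if (length(peaks) == 2L) c(0, min(tt), 0.5))
  upper <- c(Inf, Inf, Inf, max(tt), 15,
             if (length(peaks) == 2L) c(Inf, max(tt), 15))
  fit <- try(minpack.lm::nlsLM(form, data = df, start = start,
                               lower = lower, upper = upper,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 300)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(tm0)
  p <- stats::coef(fit)
  centers <- unname(p[grep("^c", names(p))])
  if (any(abs(centers - tm0) > 2.5)) return(tm0)
  centers
}

#' Extract melting temperature(s) from a thermal scan
#'
#' Smooths the ellipticity with a Savitzky-Golay filter, takes the
#' central-difference first derivative, and finds local maxima of
#' \eqn{|d\Theta/dT|} whose prominence reaches `prominence_frac` of the
#' global derivative maximum. The top (at most two) peaks by prominence are
#' returned; ties in prominence resolve toward the lower temperature. Peak
#' positions are first interpolated quadratically around each discrete
#' maximum and then refined by fitting the derivative as a sum of
#' sech^2-shaped transition components on a linear base, which removes the
#' mutual pull of two overlapping transitions (closely spaced two-step
#' melts would otherwise read a fraction of a degree too close together).
#' Working on \eqn{|d\Theta/dT|} makes the result independent
#' of the sign convention and of any affine rescaling of the ellipticity.
#'
#' @param curve A [melting_curve] with at least 40 points on a near-uniform
#'   grid.
#' @param smooth_window Savitzky-Golay window, odd number of points,
#'   default 11 (5.5 degC at 0.5 degC sampling); polynomial order 3.
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   global derivative maximum, default 0.05.
#' @return An object of class `melting_result`: `tms` (degC, ascending,
#'   length 1 or 2), `derivative` (data frame `temperature`, `dtheta`),
#'   `prominences` (in `tms` order) and `two_step`.
#' @export
extract_tms <- function(curve, smooth_window = 11, prominence_frac = 0.05) {
  stopifnot(inherits(curve, "melting_curve"))
  tt <- curve$temperatures; th <- curve$theta222
  if (length(tt) < 40L) stop("need at least 40 scan points")
  steps <- diff(tt)
  if (max(steps) / min(steps) > 1.5)
    stop("temperature grid is too non-uniform for derivative analysis")
  if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1
  sm <- if (smooth_window >= 5)
    signal::sgolayfilt(th, p = 3, n = smooth_window) else th
  nI <- length(tt)
  d <- numeric(nI)
  d[2:(nI - 1)] <- (sm[3:nI] - sm[1:(nI - 2)]) / (tt[3:nI] - tt[1:(nI - 2)])
  d[1] <- d[2]; d[nI] <- d[nI - 1]
  ad <- abs(d)
  gmax <- max(ad)
  if (gmax <= 0) stop("no thermal transition detected: flat scan")
  interior <- 2:(nI - 1)
  peaks <- interior[ad[interior] > ad[interior - 1] &
                    ad[interior] >= ad[interior + 1]]
  if (!length(peaks)) stop("no thermal transition detected")
  prom <- .peak_prominence(ad, peaks)
  keep <- prom >= prominence_frac * gmax
  if (!any(keep))
    stop("no transition above the prominence threshold; scan may be baseline only")
  peaks <- peaks[keep]; prom <- prom[keep]
  ord <- order(-prom, tt[peaks])          # ties toward lower temperature
  take <- ord[seq_len(min(2L, length(ord)))]
  peaks <- peaks[take]; prom <- prom[take]
  tm <- vapply(seq_along(peaks), function(j) {
    p <- peaks[j]
    x <- tt[(p - 1):(p + 1)]; y <- ad[(p - 1):(p + 1)]
    den <- (y[1] - 2 * y[2] + y[3])
    if (den >= 0) return(tt[p])
    tt[p] + 0.5 * (x[2] - x[1]) * (y[1] - y[3]) / den
  }, numeric(1))
  tm <- .refine_peak_centers(tt, ad, peaks, tm)
  o <- order(tm)
  structure(list(tms = tm[o], prominences = prom[o],
                 derivative = data.frame(temperature = tt, dtheta = d),
                 two_step = length(tm) == 2L),
            class = "melting_result")
}

#' @export
print.melting_result <- function(x, ...) {
  cat(sprintf("<melting_result> %s degC%s\n",
              paste(sprintf("%.2f", x$tms), collapse = ", "),
              if (x$two_step) " (two-step denaturation)" else ""))
  invisible(x)
}

#' Metal-induced melting-temperature shift
#'
#' First (lowest) melting temperature with metal minus the first without:
#' destabilization upon metal binding comes out negative.
#'
#' @param with_metal,without [extract_tms] results for the metal-loaded and
#'   metal-free samples.
#' @return Tm shift in degC.
#' @export
delta_tm <- function(with_metal, without) {
  stopifnot(inherits(with_metal, "melting_result"),
            inherits(without, "melting_result"))
  with_metal$tms[1] - without$tms[1]
}

#' Check thermal reversibility
#'
#' Compares heating and cooling scans on their common temperature range:
#' the melt is called reversible (no hysteresis) when the maximum
#' ellipticity deviation stays within `tol` times the dynamic range of the
#' signal.
#'
#' @param heat,cool [melting_curve]s with overlapping temperature ranges.
#' @param tol Tolerance as a fraction of the ellipticity range,
#'   default 0.05.
#' @return List with `reversible` (logical), `max_deviation` (ellipticity
#'   units) and `threshold`.
#' @export
check_reversibility <- function(heat, cool, tol = 0.05) {
  stopifnot(inherits(heat, "melting_curve"), inherits(cool, "melting_curve"))
  lo <- max(min(heat$temperatures), min(cool$temperatures))
  hi <- min(max(heat$temperatures), max(cool$temperatures))
  if (lo >= hi) stop("heating and cooling scans do not overlap in temperature")
  sel <- heat$temperatures >= lo & heat$temperatures <= hi
  tg <- heat$temperatures[sel]
  hy <- heat$theta222[sel]
  cy <- stats::approx(cool$temperatures, cool$theta222, xout = tg, rule = 2)$y
  dev <- max(abs(hy - cy))
  rng <- diff(range(c(hy, cy)))
  thr <- tol * rng
  list(reversible = dev <= thr, max_deviation = dev, threshold = thr)
}
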