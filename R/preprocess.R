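# Spectral conditioning: common-grid interpolation, linear baseline over the
# Amide I window, normalisation to 1 at the Amide I maximum, scaled reference
# (water) subtraction judged by flatness near the 2100 cm^-1 libration band,
# and the water-vapour diagnostic integrals.

window_idx <- function(s, lo, hi) {
  which(s$wavenumbers >= lo & s$wavenumbers <= hi)
}

interp_at <- function(s, at) {
  stats::approx(s$wavenumbers, s$absorbance, xout = at, ties = "ordered")$y
}

#' Interpolate a spectrum onto a common grid
#'
#' Linear interpolation; the target grid must lie inside the spectrum's span
#' (no extrapolation).  Reference and test spectra must share a grid before
#' any Euclidean distance is meaningful.
#'
#' @param s An [ir_spectrum()].
#' @param grid Target wavenumber vector.
#' @return An [ir_spectrum()] on `grid`.
#' @export
interpolate_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "ir_spectrum"))
  grid <- as.numeric(grid)
  if (min(grid) < min(s$wavenumbers) || max(grid) > max(s$wavenumbers))
    stop(sprintf(
      "grid [%.6g, %.6g] outside spectrum span [%.6g, %.6g]; no extrapolation",
      min(grid), max(grid), min(s$wavenumbers), max(s$wavenumbers)),
      call. = FALSE)
  ir_spectrum(grid, interp_at(s, grid), label = s$label)
}

#' Linear baseline over a window
#'
#' Draws a straight line between the spectrum's values at `lo` and `hi`
#' (1600 and 1700 cm^-1 by default, the Amide I band edges), subtracts it,
#' and restricts the output to \[lo, hi\].  The result is zero at both
#' anchors.
#'
#' @param s An [ir_spectrum()] covering \[lo, hi\].
#' @param lo,hi Anchor wavenumbers (cm^-1), `lo < hi`.
#' @return A baselined [ir_spectrum()] on the grid points inside \[lo, hi\].
#' @export
baseline_linear <- function(s, lo = 1600, hi = 1700) {
  stopifnot(inherits(s, "ir_spectrum"))
  if (lo >= hi) stop("lo must be strictly below hi", call. = FALSE)
  if (lo < min(s$wavenumbers) || hi > max(s$wavenumbers))
    stop("baseline anchors outside spectrum span", call. = FALSE)
  y_lo <- interp_at(s, lo)
  y_hi <- interp_at(s, hi)
  idx <- window_idx(s, lo, hi)
  if (length(idx) < 3)
    stop("fewer than 3 grid points inside the baseline window", call. = FALSE)
  w <- s$wavenumbers[idx]
  line <- y_lo + (y_hi - y_lo) * (w - lo) / (hi - lo)
  ir_spectrum(w, s$absorbance[idx] - line, label = s$label)
}

#' Normalise to 1 at the Amide I maximum
#'
#' Divides the whole spectrum by its maximum absorbance inside the Amide I
#' window so that the band maximum is exactly 1.
#'
#' @param s An [ir_spectrum()].
#' @param window Wavenumber window searched for the maximum (default
#'   1600-1700 cm^-1).
#' @return List with `spectrum` (normalised) and `factor` (the divisor).
#' @export
normalize_amide1 <- function(s, window = c(1600, 1700)) {
  stopifnot(inherits(s, "ir_spectrum"))
  idx <- window_idx(s, window[1], window[2])
  if (!length(idx)) stop("no grid points inside the Amide I window",
                         call. = FALSE)
  m <- max(s$absorbance[idx])
  if (!is.finite(m) || m <= 0)
    stop("non-positive maximum in the Amide I window; cannot normalise",
         call. = FALSE)
  list(spectrum = ir_spectrum(s$wavenumbers, s$absorbance / m, label = s$label),
       factor = m)
}

#' Scaled reference subtraction judged by flatness
#'
#' Finds the scale k minimising the residual of `s - k*ref` about its own
#' best-fit straight line inside `flat_window` (default 2050-2150 cm^-1,
#' around the water libration band), then subtracts `k*ref` from the whole
#' spectrum.  This operationalises the visual criterion of scaling a water
#' (or vapour) reference until the region looks flat.  The optimal k has a
#' closed form: with P the projection removing the affine component over the
#' window, k = <P s, P ref> / ||P ref||^2.
#'
#' @param s Sample [ir_spectrum()].
#' @param ref Reference [ir_spectrum()] to subtract (e.g. water).
#' @param flat_window Wavenumber window judged for flatness.
#' @return List with `spectrum` (corrected) and `report` containing
#'   `water_scale` (k) and `flatness_residual` (root-mean-square deviation of
#'   the corrected window from its best straight line).
#' @export
subtract_scaled_reference <- function(s, ref, flat_window = c(2050, 2150)) {
  stopifnot(inherits(s, "ir_spectrum"), inherits(ref, "ir_spectrum"))
  lo <- flat_window[1]; hi <- flat_window[2]
  for (sp in list(s, ref))
    if (lo < min(sp$wavenumbers) || hi > max(sp$wavenumbers))
      stop("flat_window outside spectrum span", call. = FALSE)
  idx <- window_idx(s, lo, hi)
  if (length(idx) < 4)
    stop("fewer than 4 grid points inside flat_window", call. = FALSE)
  w <- s$wavenumbers[idx]
  ys <- s$absorbance[idx]
  yr <- interp_at(ref, w)
  detrend <- function(y) stats::residuals(stats::lm(y ~ w))
  pr <- detrend(yr)
  denom <- sum(pr^2)
  if (denom < .Machine$double.eps * length(pr))
    stop("reference is flat (affine) inside flat_window; scale is undefined",
         call. = FALSE)
  ps <- detrend(ys)
  k <- sum(ps * pr) / denom
  resid <- ps - k * pr
  ref_full <- interp_at(ref, s$wavenumbers)
  if (anyNA(ref_full))
    stop("reference does not cover the sample spectrum's span", call. = FALSE)
  corrected <- ir_spectrum(s$wavenumbers, s$absorbance - k * ref_full,
                           label = s$label)
  list(spectrum = corrected,
       report = list(water_scale = k,
                     flatness_residual = sqrt(mean(resid^2)),
                     flat_window = flat_window))
}

#' Water-vapour diagnostic integral
#'
#' Trapezoidal integral of |absorbance| over a region dominated by water
#' vapour lines (1717-1772 cm^-1 by default; 3800-3900 cm^-1 is the common
#' alternative).  Used as a diagnostic to judge whether vapour correction is
#' needed; no automatic correction is applied.
#'
#' @param s An [ir_spectrum()].
#' @param region Integration limits (cm^-1).
#' @return Integrated absolute absorbance (absorbance * cm^-1).
#' @export
vapour_integral <- function(s, region = c(1717, 1772)) {
  stopifnot(inherits(s, "ir_spectrum"))
  lo <- region[1]; hi <- region[2]
  if (lo >= hi) stop("region must be increasing", call. = FALSE)
  if (lo < min(s$wavenumbers) || hi > max(s$wavenumbers))
    stop("region outside spectrum span", call. = FALSE)
  inner <- s$wavenumbers[s$wavenumbers > lo & s$wavenumbers < hi]
  x <- c(lo, inner, hi)
  y <- abs(interp_at(s, x))
  pracma::trapz(x, y)
}
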