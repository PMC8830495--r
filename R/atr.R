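# Conversion between ATR and transmission spectra.  ATR band intensities are
# weighted by the wavenumber-dependent evanescent-field penetration depth
# d_p and attenuated by water absorption; the conversion divides these
# effects out (and its inverse puts them back).

#' ATR geometry
#'
#' Optical parameters of the ATR experiment.  Defaults describe a
#' single-bounce 45-degree incidence ZnSe crystal (refractive index 2.43)
#' with an aqueous sample (index 1.33).  Total internal reflection requires
#' `sin(theta) > n2/n1`.
#'
#' @param n1 Crystal refractive index.
#' @param n2 Sample refractive index.
#' @param theta_deg Angle of incidence in degrees.
#' @param f Dimensionless light-intensity factor multiplying the penetration
#'   depth (the conversion depends only on the product `d_p * f`).
#' @param path_length_cm Transmission-equivalent path length in cm (1e-4 cm
#'   = 1 micron, a typical no-spacer transmission cell).
#' @return List of class `atr_geometry`.
#' @export
atr_geometry <- function(n1 = 2.43, n2 = 1.33, theta_deg = 45,
                         f = 1, path_length_cm = 1e-4) {
  if (!(n1 > n2 && n2 > 0)) stop("need n1 > n2 > 0", call. = FALSE)
  if (f <= 0) stop("intensity factor f must be > 0", call. = FALSE)
  if (path_length_cm <= 0) stop("path length must be > 0", call. = FALSE)
  if (sin(theta_deg * pi / 180) <= n2 / n1)
    stop(sprintf(
      "no total internal reflection: sin(%.4g deg) = %.4f <= n2/n1 = %.4f",
      theta_deg, sin(theta_deg * pi / 180), n2 / n1), call. = FALSE)
  structure(list(n1 = n1, n2 = n2, theta_deg = theta_deg, f = f,
                 path_length_cm = path_length_cm),
            class = "atr_geometry")
}

#' Evanescent-wave penetration depth
#'
#' `d_p = 1 / (2 pi nu n1 sqrt(sin^2(theta) - (n2/n1)^2))` with the
#' wavenumber nu in cm^-1 (wavelength = 1/nu), giving d_p in cm.  The depth
#' scales as 1/nu and diverges at the critical angle.
#'
#' @param wavenumber Wavenumber(s) in cm^-1, > 0.
#' @param geometry An [atr_geometry()].
#' @return Penetration depth(s) in cm.
#' @export
penetration_depth <- function(wavenumber, geometry = atr_geometry()) {
  stopifnot(inherits(geometry, "atr_geometry"))
  if (any(wavenumber <= 0)) stop("wavenumber must be > 0", call. = FALSE)
  st <- sin(geometry$theta_deg * pi / 180)
  disc <- st^2 - (geometry$n2 / geometry$n1)^2
  # constructor guarantees disc > 0
  1 / (2 * pi * wavenumber * geometry$n1 * sqrt(disc))
}

#' Water absorbance model
#'
#' Per-path-length water absorbance `(epsilon C)_water = A/l` (cm^-1) on a
#' wavenumber grid, used in both conversion directions.  A measured water
#' spectrum divided by its path length is the physical input;
#' [water_model_flat()] provides a constant synthetic placeholder for
#' testing only (it is not a physical water spectrum).
#'
#' @param grid Wavenumber vector (cm^-1).
#' @param epsilonC Non-negative absorbance-per-cm values, same length.
#' @return List of class `water_model`.
#' @export
water_model <- function(grid, epsilonC) {
  grid <- as.numeric(grid); epsilonC <- as.numeric(epsilonC)
  if (length(grid) != length(epsilonC))
    stop("grid and epsilonC must have equal length", call. = FALSE)
  if (any(epsilonC < 0)) stop("epsilonC must be non-negative", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("grid must be ascending", call. = FALSE)
  structure(list(grid = grid, epsilonC = epsilonC), class = "water_model")
}

#' @rdname water_model
#' @param value Constant epsilonC value (default 0: no water absorption).
#' @export
water_model_flat <- function(grid, value = 0) {
  water_model(grid, rep(value, length(grid)))
}

water_at <- function(water, wavenumbers) {
  out <- stats::approx(water$grid, water$epsilonC, xout = wavenumbers,
                       rule = 1, ties = "ordered")$y
  if (anyNA(out))
    stop("water model does not cover the spectrum's wavenumber range",
         call. = FALSE)
  out
}

atr_denominator <- function(wavenumbers, water, geometry) {
  dpf <- penetration_depth(wavenumbers, geometry) * geometry$f
  eps <- water_at(water, wavenumbers)
  denom <- 1 - log(10) * dpf * eps
  if (any(denom <= 0)) {
    bad <- wavenumbers[denom <= 0]
    stop(sprintf(
      "saturation: 1 - ln(10) dp f (epsC)water <= 0 at %s cm^-1",
      paste(format(utils::head(bad, 5)), collapse = ", ")), call. = FALSE)
  }
  list(dpf = dpf, denom = denom)
}

#' Convert an ATR spectrum to transmission equivalent
#'
#' Pointwise `A_T = A_ATR * l / (dp f (1 - ln(10) dp f (epsC)_water))`, the
#' inverse of [transmission_to_atr()].  Removing the `dp ~ 1/nu` weighting
#' restores the relative intensity of high-wavenumber bands.
#'
#' @param atr An [ir_spectrum()] collected in ATR mode.
#' @param water A [water_model()].
#' @param geometry An [atr_geometry()].
#' @return Transmission-equivalent [ir_spectrum()].
#' @export
atr_to_transmission <- function(atr, water, geometry = atr_geometry()) {
  stopifnot(inherits(atr, "ir_spectrum"), inherits(water, "water_model"))
  parts <- atr_denominator(atr$wavenumbers, water, geometry)
  a_t <- atr$absorbance * geometry$path_length_cm /
    (parts$dpf * parts$denom)
  ir_spectrum(atr$wavenumbers, a_t, label = atr$label)
}

#' Convert a transmission spectrum to ATR equivalent
#'
#' Exact pointwise inverse of [atr_to_transmission()] with the same water
#' model and geometry: `A_ATR = A_T dp f (1 - ln(10) dp f (epsC)_water) / l`.
#' The relation is linear in the protein absorbance, so overall scale (and
#' hence concentration and path length) drops out once spectra are
#' normalised.
#'
#' @param trans An [ir_spectrum()] in transmission mode.
#' @inheritParams atr_to_transmission
#' @return ATR-equivalent [ir_spectrum()].
#' @export
transmission_to_atr <- function(trans, water, geometry = atr_geometry()) {
  stopifnot(inherits(trans, "ir_spectrum"), inherits(water, "water_model"))
  parts <- atr_denominator(trans$wavenumbers, water, geometry)
  a_atr <- trans$absorbance * parts$dpf * parts$denom /
    geometry$path_length_cm
  ir_spectrum(trans$wavenumbers, a_atr, label = trans$label)
}

#' Convert and renormalise
#'
#' Converts in either direction and renormalises to 1 at the Amide I
#' maximum, so the result is independent of the path length and of any
#' overall scaling of the input -- the form used when spectra feed a
#' normalised reference set.
#'
#' @param s Input [ir_spectrum()].
#' @param water A [water_model()].
#' @param geometry An [atr_geometry()].
#' @param direction `"atr2trans"` or `"trans2atr"`.
#' @param window Normalisation window (cm^-1).
#' @return Converted, normalised [ir_spectrum()].
#' @export
normalised_conversion <- function(s, water, geometry = atr_geometry(),
                                  direction = c("atr2trans", "trans2atr"),
                                  window = c(1600, 1700)) {
  direction <- match.arg(direction)
  conv <- switch(direction,
                 atr2trans = atr_to_transmission(s, water, geometry),
                 trans2atr = transmission_to_atr(s, water, geometry))
  normalize_amide1(conv, window = window)$spectrum
}
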