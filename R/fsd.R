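# Fourier self-deconvolution: band narrowing by dividing out an assumed
# Lorentzian line shape in the retardation (Fourier) domain, with an
# apodization window controlling noise amplification.

#' Fourier self-deconvolution
#'
#' Kauppinen-style FSD.  The spectrum is mean-padded to the next power of
#' two, transformed to the retardation domain, multiplied by
#' `exp(2*pi*gamma*|x|)` (the inverse transform of a Lorentzian of half
#' width at half maximum `gamma`) and by a triangular-squared apodization
#' window that falls to zero at a fraction `smoothing` of the maximum
#' retardation, then transformed back.  A `smoothing` of 1 disables
#' apodization (the window's support already covers the whole retardation
#' range), so `gamma = 0, smoothing = 1` is the identity up to FFT
#' round-off.
#'
#' @param s An [ir_spectrum()] on a uniform grid.
#' @param gamma Assumed Lorentzian half-width to deconvolve (cm^-1), >= 0.
#' @param smoothing Apodization cutoff as a fraction of the maximum
#'   retardation, in (0, 1].
#' @return Deconvolved [ir_spectrum()] on the original grid.
#' @export
fsd <- function(s, gamma, smoothing) {
  stopifnot(inherits(s, "ir_spectrum"))
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (!(smoothing > 0 && smoothing <= 1))
    stop("smoothing must lie in (0, 1]", call. = FALSE)
  if (any(!is.finite(s$absorbance)))
    stop("spectrum must be finite", call. = FALSE)
  h <- check_uniform_grid(s)
  n <- length(s$absorbance)
  m <- 2^ceiling(log2(n))
  a <- c(s$absorbance, rep(mean(s$absorbance), m - n))
  # retardation (cm) for each FFT bin; x_max = 1/(2h)
  idx <- 0:(m - 1)
  freq <- pmin(idx, m - idx)
  x <- freq / (m * h)
  x_max <- 1 / (2 * h)
  cutoff <- smoothing * x_max
  apod <- if (smoothing >= 1) rep(1, m) else {
    w <- pmax(0, 1 - x / cutoff)^2
    w
  }
  pos <- apod > 0
  if (max(2 * pi * gamma * x[pos]) > log(1e15))
    stop("deconvolution factor overflows; reduce gamma or smoothing",
         call. = FALSE)
  mult <- numeric(m)
  mult[pos] <- exp(2 * pi * gamma * x[pos]) * apod[pos]
  out <- Re(stats::fft(stats::fft(a) * mult, inverse = TRUE)) / m
  ir_spectrum(s$wavenumbers, out[seq_len(n)], label = s$label)
}

#' Re-zero and re-normalise a spectrum
#'
#' Subtracts the minimum and divides by the new maximum, the conventional
#' post-processing after self-deconvolution: output has minimum 0 and
#' maximum 1, and is invariant under affine transforms of the input.
#'
#' @param s An [ir_spectrum()] with positive range.
#' @return Rescaled [ir_spectrum()].
#' @export
rezero_renormalize <- function(s) {
  stopifnot(inherits(s, "ir_spectrum"))
  lo <- min(s$absorbance); hi <- max(s$absorbance)
  if (hi - lo <= 0)
    stop("constant spectrum cannot be re-normalised", call. = FALSE)
  ir_spectrum(s$wavenumbers, (s$absorbance - lo) / (hi - lo), label = s$label)
}

#' Full width at half maximum of the main band
#'
#' Measures the FWHM of a spectrum's global maximum by linear interpolation
#' of the half-maximum crossings on either side.  Used to quantify band
#' narrowing by [fsd()].
#'
#' @param s An [ir_spectrum()] with a single dominant band.
#' @return FWHM in cm^-1.
#' @export
measure_fwhm <- function(s) {
  stopifnot(inherits(s, "ir_spectrum"))
  y <- s$absorbance; w <- s$wavenumbers
  ipk <- which.max(y)
  half <- y[ipk] / 2
  cross <- function(side) {
    idx <- if (side == "left") rev(seq_len(ipk - 1)) else (ipk + 1):length(y)
    for (i in idx) {
      if (y[i] <= half) {
        j <- if (side == "left") i + 1 else i - 1
        return(w[i] + (w[j] - w[i]) * (half - y[i]) / (y[j] - y[i]))
      }
    }
    stop("half-maximum crossing not found; band truncated by the grid edge",
         call. = FALSE)
  }
  abs(cross("right") - cross("left"))
}
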