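# Synthetic Amide I spectra: structure-weighted mixtures of class-specific
# component bands at the consensus positions, with center jitter and noise.
# Gives every pipeline stage a test bed with known true fractions.

#' Synthetic Amide I band model
#'
#' Class basis bands at the consensus component positions: helix as a
#' Gaussian at 1654 cm^-1; sheet as a major Gaussian at 1631 cm^-1 plus a
#' minor one at 1678 cm^-1 with a 4:1 area ratio; "other" as one broad
#' Gaussian at 1645 cm^-1 (turn bands are folded into this class).  Basis
#' band areas are normalised to 1 per class, so a mixture weighted by
#' structure fractions is area-faithful.
#'
#' @param center_jitter_sd Per-spectrum band-center jitter SD (cm^-1).
#' @param noise_sd Additive Gaussian noise SD (absorbance units, on spectra
#'   whose Amide I maximum is 1).
#' @param grid Wavenumber grid; default 1600-1700 cm^-1 at 2 cm^-1 spacing.
#' @return List of class `synthetic_model` with a `bands` data.frame
#'   (class, center, sigma, weight).
#' @export
synthetic_model <- function(center_jitter_sd = 1, noise_sd = 0.005,
                            grid = seq(1600, 1700, by = 2)) {
  bands <- data.frame(
    class = c("helix", "sheet", "sheet", "other"),
    center = c(1654, 1631, 1678, 1645),
    sigma = c(7, 6, 5, 12),
    weight = c(1, 0.8, 0.2, 1))   # per-class areas sum to 1
  stopifnot(all(bands$sigma > 0))
  structure(list(bands = bands, center_jitter_sd = center_jitter_sd,
                 noise_sd = noise_sd, grid = as.numeric(grid)),
            class = "synthetic_model")
}

#' Sample structure fractions uniformly on the simplex
#'
#' Uniform sampling on the 2-simplex via ordered uniform spacings: two
#' U(0,1) draws are sorted and the three gaps are the fractions.
#'
#' @param n Number of triples.
#' @param seed Integer seed.
#' @return List of n [structure_fractions()].
#' @export
sample_fractions <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      u <- sort(stats::runif(2))
      structure_fractions(u[1], u[2] - u[1], 1 - u[2])
    })
  })
}

synth_basis <- function(model, jitter = NULL) {
  b <- model$bands
  centers <- b$center + if (is.null(jitter)) 0 else jitter
  g <- model$grid
  comp <- vapply(seq_len(nrow(b)), function(i) {
    amp <- b$weight[i] / (b$sigma[i] * sqrt(2 * pi))   # unit-area scaling
    amp * exp(-(g - centers[i])^2 / (2 * b$sigma[i]^2))
  }, numeric(length(g)))
  vapply(c("helix", "sheet", "other"), function(cl)
    rowSums(comp[, b$class == cl, drop = FALSE]), numeric(length(g)))
}

#' Generate one synthetic spectrum
#'
#' Absorbance = helix*B_helix + sheet*B_sheet + other*B_other on the model
#' grid, with per-spectrum Gaussian jitter of each band center, additive
#' Gaussian noise, and final normalisation to 1 at the maximum.
#'
#' @param fractions A [structure_fractions()].
#' @param model A [synthetic_model()].
#' @param seed Integer seed for jitter and noise.
#' @param label Spectrum label.
#' @return An [ir_spectrum()].
#' @export
synth_spectrum <- function(fractions, model = synthetic_model(), seed = 1L,
                           label = "synthetic") {
  stopifnot(inherits(model, "synthetic_model"))
  f <- structure_fractions(fractions[["helix"]], fractions[["sheet"]],
                           fractions[["other"]])
  withr::with_seed(seed, {
    jitter <- stats::rnorm(nrow(model$bands), 0, model$center_jitter_sd)
    basis <- synth_basis(model, jitter)
    a <- as.numeric(basis %*% c(f[["helix"]], f[["sheet"]], f[["other"]]))
    a <- a + stats::rnorm(length(a), 0, model$noise_sd * max(a))
    s <- ir_spectrum(model$grid, a, label = label)
    normalize_amide1(s)$spectrum
  })
}

#' Generate a synthetic reference set
#'
#' n spectra with fractions drawn uniformly on the simplex, sharing the
#' model grid; deterministic under the seed.
#'
#' @param n Number of members (>= 2).
#' @param model A [synthetic_model()].
#' @param seed Integer seed.
#' @return A [reference_set()] whose `fractions` are the true generating
#'   fractions.
#' @export
make_reference_set <- function(n, model = synthetic_model(), seed = 1L) {
  stopifnot(n >= 2)
  fracs <- sample_fractions(n, seed = seed)
  spectra <- vapply(seq_len(n), function(i)
    synth_spectrum(fracs[[i]], model, seed = fold_seed(seed, i),
                   label = sprintf("S%d", i))$absorbance,
    numeric(length(model$grid)))
  reference_set(model$grid, spectra,
                do.call(rbind, lapply(fracs, unclass)),
                labels = sprintf("S%d", seq_len(n)))
}
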