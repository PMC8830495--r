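# Shared fixture builders; everything is generated in code.

gauss_spec <- function(centers, sigmas, amps, grid = seq(1600, 1700, 2),
                       label = "g") {
  y <- rep(0, length(grid))
  for (i in seq_along(centers))
    y <- y + amps[i] * exp(-(grid - centers[i])^2 / (2 * sigmas[i]^2))
  ir_spectrum(grid, y, label = label)
}

noiseless_model <- function(grid = seq(1600, 1700, by = 2)) {
  synthetic_model(center_jitter_sd = 0, noise_sd = 0, grid = grid)
}

# map with hand-set node spectra, for predict/assign oracle tests
manual_map <- function(node_spectra, grid, side, k_bmu = 3,
                       structures = NULL, placements = integer()) {
  j <- seq_len(side * side)
  structure(list(side = side, grid = grid, node_spectra = node_spectra,
                 coords = data.frame(node = j,
                                     row = (j - 1L) %/% side + 1L,
                                     col = (j - 1L) %% side + 1L),
                 node_structures = structures,
                 placements = placements,
                 config = som_config(map_dim = side, k_bmu = k_bmu),
                 qe_trace = numeric()),
            class = "som_map")
}

# interpolated position of the absorbance maximum (parabolic refinement)
peak_position <- function(s) {
  y <- s$absorbance; w <- s$wavenumbers; i <- which.max(y)
  if (i == 1 || i == length(y)) return(w[i])
  h <- w[2] - w[1]
  w[i] + h / 2 * (y[i - 1] - y[i + 1]) / (y[i - 1] - 2 * y[i] + y[i + 1])
}
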