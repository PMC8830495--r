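test_that("Savitzky-Golay second derivative is exact on polynomials", {
  grid <- seq(1600, 1700, 2)
  quad <- ir_spectrum(grid, 3e-4 * grid^2)
  d2 <- second_derivative(quad)
  core <- 5:47                      # away from filter edges
  expect_lt(max(abs(d2$absorbance[core] - 6e-4)), 1e-8)
  lin <- ir_spectrum(grid, 2 - 0.001 * grid)
  expect_lt(max(abs(second_derivative(lin)$absorbance[core])), 1e-10)
  expect_error(second_derivative(quad, window_pts = 8), "odd")
  uneven <- ir_spectrum(c(1600, 1601, 1603, 1610, 1620), rep(1, 5))
  expect_error(second_derivative(uneven), "uniform")
})

test_that("a Gaussian band's second derivative dips at its center", {
  s <- gauss_spec(1652, 7, 1)
  d2 <- second_derivative(s)
  expect_lt(abs(d2$wavenumbers[which.min(d2$absorbance)] - 1652), 2 + 1e-9)
})

test_that("band centers are picked from second-derivative minima", {
  s <- gauss_spec(c(1632, 1654), c(6, 6), c(1, 1))
  d2 <- second_derivative(s)
  centers <- pick_band_centers(d2)
  expect_length(centers, 2)
  expect_lt(max(abs(centers - c(1632, 1654))), 2 + 1e-9)
  flat <- ir_spectrum(seq(1600, 1700, 2), rep(0.3, 51))
  expect_equal(pick_band_centers(second_derivative(flat), 1e-12), numeric(0))
  single <- gauss_spec(1645, 8, 1)
  expect_length(pick_band_centers(second_derivative(single), 1e-6), 1)
})

test_that("planted Gaussians are recovered to high accuracy", {
  grid <- seq(1580, 1720, 2)
  tru <- data.frame(center = c(1631, 1645, 1654), sigma = c(6, 9, 5),
                    amp = c(0.7, 0.5, 0.6))
  s <- gauss_spec(tru$center, tru$sigma, tru$amp, grid = grid)
  fit <- fit_gaussians(s, centers = c(1633, 1643, 1656))
  expect_equal(nrow(fit$bands), 3)
  expect_lt(max(abs(fit$bands$center - tru$center)), 0.2)
  tru_area <- tru$amp * tru$sigma * sqrt(2 * pi)
  expect_lt(max(abs(fit$bands$area - tru_area) / tru_area), 0.01)
  expect_true(all(diff(fit$rss_trace) <= 1e-12))
})

test_that("an exact initial guess is a fixed point of the fit", {
  s <- gauss_spec(1650, 6, 0.8)
  fit <- fit_gaussians(s, centers = 1650, init_sigma = 6)
  expect_lt(fit$rss, 1e-16)
  expect_equal(fit$bands$center, 1650, tolerance = 1e-6)
  expect_equal(fit$bands$sigma, 6, tolerance = 1e-6)
  expect_equal(fit$bands$amplitude, 0.8, tolerance = 1e-6)
})

test_that("amplitudes are clamped at zero and flagged degenerate", {
  grid <- seq(1600, 1700, 2)
  s <- ir_spectrum(grid, exp(-(grid - 1650)^2 / 72) - 0.05)
  fit <- fit_gaussians(s, centers = c(1610, 1650))
  expect_true(all(fit$bands$amplitude >= 0))
  expect_true(any(fit$bands$degenerate) || all(fit$bands$amplitude > 0))
})

test_that("structure windows partition band areas correctly", {
  mk <- function(centers, areas) {
    sigma <- rep(5, length(centers))
    data.frame(center = centers, sigma = sigma,
               amplitude = areas / (sigma * sqrt(2 * pi)), area = areas,
               degenerate = FALSE)
  }
  f1 <- structure_from_bands(mk(1654, 1))
  expect_equal(unname(unclass(f1)), c(1, 0, 0))
  f2 <- structure_from_bands(mk(c(1631, 1654), c(2, 2)))
  expect_equal(unname(unclass(f2)), c(0.5, 0.5, 0))
  f3 <- structure_from_bands(mk(c(1631, 1645, 1654, 1678), rep(1, 4)))
  expect_equal(unname(unclass(f3)), c(0.25, 0.25, 0.5))
  expect_error(structure_from_bands(mk(1650, 0)), "zero total")
})

test_that("direct band-fitting recovers planted area fractions", {
  grid <- seq(1580, 1720, 2)
  tru <- data.frame(center = c(1631, 1645, 1654), sigma = c(6, 9, 5),
                    amp = c(0.7, 0.5, 0.6))
  s <- gauss_spec(tru$center, tru$sigma, tru$amp, grid = grid)
  fit <- fit_gaussians(s, centers = c(1633, 1643, 1656))
  fr <- structure_from_bands(fit)
  tru_area <- tru$amp * tru$sigma * sqrt(2 * pi)
  planted <- c(tru_area[3], tru_area[1], tru_area[2]) / sum(tru_area)
  expect_lt(max(abs(unclass(fr) - planted)), 0.01)
  expect_true(all(unclass(fr) >= 0))
  expect_lt(abs(sum(fr) - 1), 1e-9)
})

test_that("the second-derivative method classifies planted bands", {
  single <- gauss_spec(1654, 6, 1, grid = seq(1580, 1720, 2))
  r1 <- fit_second_derivative_method(single)
  expect_gt(r1$fractions[["helix"]], 0.98)
  # equal widths, equal areas -> equal fractions within 2%
  pair <- gauss_spec(c(1631, 1654), c(6, 6), c(1, 1), grid = seq(1580, 1720, 2))
  r2 <- fit_second_derivative_method(pair)
  expect_lt(abs(r2$fractions[["helix"]] - r2$fractions[["sheet"]]), 0.02)
  flat <- ir_spectrum(seq(1580, 1720, 2), rep(0.2, 71))
  expect_error(fit_second_derivative_method(flat), "no bands")
})

test_that("the full direct method runs end-to-end on a mixture", {
  grid <- seq(1590, 1710, 2)
  s <- gauss_spec(c(1631, 1654), c(6, 6), c(1, 0.8), grid = grid)
  res <- fit_direct_method(s)
  expect_gt(res$fractions[["sheet"]], res$fractions[["helix"]])
  expect_lt(abs(sum(res$fractions) - 1), 1e-9)
})
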