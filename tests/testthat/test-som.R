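test_that("training is deterministic under a fixed seed", {
  rs <- make_reference_set(6, seed = 2)
  cfg <- som_config(map_dim = 6, n_steps = 300, seed = 5)
  m1 <- som_train(rs, cfg)
  m2 <- som_train(rs, cfg)
  expect_identical(m1$node_spectra, m2$node_spectra)
  expect_identical(m1$placements, m2$placements)
  expect_identical(m1$node_structures, m2$node_structures)
  m3 <- som_train(rs, som_config(map_dim = 6, n_steps = 300, seed = 6))
  expect_false(identical(m1$node_spectra, m3$node_spectra))
})

test_that("two identical references act as a single attractor", {
  grid <- seq(1600, 1700, 2)
  x <- exp(-(grid - 1650)^2 / 128)
  rs <- reference_set(grid, cbind(x, x),
                      rbind(c(0.4, 0.3, 0.3), c(0.4, 0.3, 0.3)))
  map <- som_train(rs, som_config(map_dim = 5, n_steps = 500, seed = 1))
  # quantization-error checkpoints decrease monotonically to ~0
  expect_true(all(diff(map$qe_trace) <= 1e-12))
  d_final <- sqrt(min(colSums((map$node_spectra - x)^2)))
  expect_lt(d_final, 0.05)
  # all node structures equal the single fractions triple
  expect_lt(max(abs(map$node_structures[, "helix"] - 0.4)), 1e-9)
})

test_that("training preserves topology: clusters stay contiguous on the map", {
  grid <- seq(1600, 1700, 2)
  lowc <- vapply(1:4, function(i) exp(-(grid - 1630 - i / 4)^2 / 72),
                 numeric(length(grid)))
  highc <- vapply(1:4, function(i) exp(-(grid - 1670 - i / 4)^2 / 72),
                  numeric(length(grid)))
  fr <- matrix(rep(c(0.2, 0.4, 0.4), 8), ncol = 3, byrow = TRUE)
  rs <- reference_set(grid, cbind(lowc, highc), fr)
  map <- som_train(rs, som_config(map_dim = 8, n_steps = 2000, seed = 3))
  pos <- map$coords[map$placements, c("row", "col")]
  gd <- as.matrix(dist(pos))
  within <- c(gd[1:4, 1:4][upper.tri(diag(4))], gd[5:8, 5:8][upper.tri(diag(4))])
  between <- gd[1:4, 5:8]
  expect_lt(mean(within), mean(between))
})

test_that("find_bmus matches an exhaustive-search oracle", {
  grid <- seq(1600, 1638, 2)          # 20 points
  for (seed in 1:25) {
    set.seed(seed)
    side <- sample(3:6, 1)
    W <- matrix(stats::runif(length(grid) * side^2), length(grid))
    s <- ir_spectrum(grid, stats::runif(length(grid)))
    map <- manual_map(W, grid, side)
    k <- sample(1:(side^2), 1)
    got <- find_bmus(map, s, k)
    d <- sqrt(colSums((W - s$absorbance)^2))
    ord <- order(d, seq_along(d))[seq_len(k)]
    expect_identical(got$node, ord)
    expect_equal(got$distance, d[ord])
  }
  map <- manual_map(matrix(1, 20, 9), grid, 3)
  expect_error(find_bmus(map, ir_spectrum(grid, rep(1, 20)), 10), "exceeds")
})

test_that("BMU ranking with k = node count is a permutation", {
  grid <- seq(1600, 1700, 10)
  set.seed(9)
  W <- matrix(stats::runif(length(grid) * 16), length(grid))
  map <- manual_map(W, grid, 4)
  got <- find_bmus(map, ir_spectrum(grid, stats::runif(length(grid))), 16)
  expect_setequal(got$node, 1:16)
  expect_true(all(diff(got$distance) >= 0))
})

test_that("structure assignment agrees with a brute-force oracle", {
  rs <- make_reference_set(5, noiseless_model(), seed = 4)
  map <- som_train(rs, som_config(map_dim = 4, n_steps = 400, seed = 1),
                   assign = FALSE)
  p <- 2
  map <- assign_structures(map, rs, p = p)
  d <- sqrt(t(apply(map$node_spectra, 2, function(w)
    colSums((rs$spectra - w)^2))))
  placed_members <- split(seq_along(map$placements), map$placements)
  for (j in seq_len(ncol(map$node_spectra))) {
    key <- as.character(j)
    expected <- if (!is.null(placed_members[[key]])) {
      mem <- placed_members[[key]]
      rs$fractions[mem[which.min(d[j, mem])], ]
    } else {
      wts <- 1 / d[j, ]^p
      colSums(wts * rs$fractions) / sum(wts)
    }
    expected <- expected / sum(expected)
    expect_lt(max(abs(map$node_structures[j, ] - expected)), 1e-12)
  }
})

test_that("placement nodes carry their member's fractions exactly", {
  rs <- make_reference_set(6, seed = 8)
  map <- som_train(rs, som_config(map_dim = 5, n_steps = 800, seed = 2))
  for (i in seq_along(map$placements)) {
    node <- map$placements[i]
    others <- setdiff(seq_along(map$placements),
                      which(map$placements == node))
    if (length(others) == 5)   # node not shared
      expect_equal(unname(map$node_structures[node, ]),
                   unname(rs$fractions[i, ]))
  }
})

test_that("an equidistant node averages the two references symmetrically", {
  grid <- seq(1600, 1700, 25)
  r1 <- c(1, 0, 0, 0, 0); r2 <- c(0, 0, 0, 0, 1)
  rs <- reference_set(grid, cbind(r1, r2), rbind(c(1, 0, 0), c(0, 1, 0)))
  W <- cbind(r1, r2, c(0.5, 0, 0, 0, 0.5), rep(0.2, 5))
  map <- manual_map(W, grid, 2, placements = c(A = 1L, B = 2L))
  map <- assign_structures(map, rs, p = 1)
  expect_equal(unname(map$node_structures[3, ]), c(0.5, 0.5, 0))
})

test_that("prediction takes the zero-distance branch on exact matches", {
  grid <- seq(1600, 1700, 25)
  W <- matrix(stats::runif(20, 0.5, 1.5), 5, 4)
  st <- rbind(c(0.4, 0.3, 0.3), c(0.1, 0.8, 0.1),
              c(0.3, 0.3, 0.4), c(0.25, 0.5, 0.25))
  colnames(st) <- c("helix", "sheet", "other")
  map <- manual_map(W, grid, 2, structures = st)
  p <- predict(map, ir_spectrum(grid, W[, 1]), k = 3)
  expect_equal(unname(unclass(p$fractions)), c(0.4, 0.3, 0.3))
  expect_equal(p$nrmsd, 0)
  expect_equal(p$bmus$distance[1], 0)
})

test_that("two equidistant BMUs give the midpoint fractions", {
  grid <- seq(1600, 1700, 25)
  base <- rep(1, 5)
  W <- cbind(base + 0.1, base - 0.1, base + 5, base + 6)
  st <- rbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0), c(0, 1, 0))
  colnames(st) <- c("helix", "sheet", "other")
  map <- manual_map(W, grid, 2, structures = st)
  p <- predict(map, ir_spectrum(grid, base), k = 2)
  expect_equal(unname(unclass(p$fractions)), c(0.5, 0, 0.5))
})

test_that("prediction matches an independent weighted-average oracle", {
  grid <- seq(1600, 1700, 5)
  for (seed in 1:10) {
    set.seed(seed)
    W <- matrix(stats::runif(21 * 9), 21, 9)
    st <- t(apply(matrix(stats::runif(27), 9, 3), 1, function(r) r / sum(r)))
    colnames(st) <- c("helix", "sheet", "other")
    map <- manual_map(W, grid, 3, structures = st)
    s <- ir_spectrum(grid, stats::runif(21))
    p <- predict(map, s, k = 5)
    d <- sqrt(colSums((W - s$absorbance)^2))
    ord <- order(d, seq_along(d))[1:5]
    wts <- (1 / d[ord]) / sum(1 / d[ord])
    oracle_f <- colSums(wts * st[ord, ])
    oracle_recon <- as.numeric(W[, ord] %*% wts)
    expect_lt(max(abs(unclass(p$fractions) - oracle_f)), 1e-12)
    expect_lt(max(abs(p$reconstructed - oracle_recon)), 1e-12)
    expect_equal(p$nrmsd,
                 sqrt(sum((s$absorbance - oracle_recon)^2) / sum(s$absorbance^2)))
    # simplex conservation
    expect_true(all(unclass(p$fractions) >= 0))
    expect_lt(abs(sum(p$fractions) - 1), 1e-9)
  }
})

test_that("nrmsd satisfies its analytic identities", {
  x <- c(3, 4)
  expect_equal(nrmsd(x, x), 0)
  expect_equal(nrmsd(x, c(0, 0)), 1)
  expect_equal(nrmsd(x, c(3, 0)), 0.8)
  expect_error(nrmsd(c(0, 0), x), "zero norm")
  expect_error(nrmsd(1:3, 1:4), "equal length")
})

test_that("self-consistency: members that own their node predict exactly", {
  rs <- make_reference_set(8, noiseless_model(), seed = 6)
  map <- som_train(rs, som_config(map_dim = 6, n_steps = 1500, seed = 1))
  for (i in 1:8) {
    node <- map$placements[i]
    s <- refset_member(rs, i)
    d <- sqrt(colSums((map$node_spectra - s$absorbance)^2))
    if (which.min(d) == node && sum(map$placements == node) == 1) {
      p <- predict(map, s, k = 1)
      expect_equal(unname(unclass(p$fractions)), unname(rs$fractions[i, ]))
    }
  }
})

test_that("saved maps reload losslessly and refuse foreign grids", {
  rs <- make_reference_set(5, seed = 7)
  map <- som_train(rs, som_config(map_dim = 4, n_steps = 300, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  save_map(map, path)
  back <- load_map(path)
  expect_equal(back$node_spectra, unname(map$node_spectra))
  expect_equal(back$side, map$side)
  s <- refset_member(rs, 2)
  p1 <- predict(map, s)
  p2 <- predict(back, s)
  expect_equal(unclass(p1$fractions), unclass(p2$fractions),
               tolerance = 1e-12)
  expect_equal(p1$nrmsd, p2$nrmsd, tolerance = 1e-12)
  wrong <- ir_spectrum(seq(1500, 1600, 2), rep(1, 51))
  expect_error(predict(back, wrong), "grid")
})

test_that("non-finite reference spectra abort training", {
  grid <- seq(1600, 1700, 2)
  rs <- make_reference_set(3, seed = 1)
  rs$spectra[4, 2] <- NaN
  expect_error(som_train(rs, som_config(map_dim = 3, n_steps = 10)),
               "non-finite")
})
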