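# Self-organising map engine: train a square Kohonen map on reference
# spectra, assign node spectra/structures, and predict test-spectrum
# structure from the top-k best matching units (BMUs).

#' SOM training configuration
#'
#' @param map_dim Side length of the square map.  `NULL` picks a default from
#'   the reference-set size at training time: 40 for sets of ~50 members,
#'   20 for ~30, otherwise `ceiling(4*sqrt(N))` capped at 40.
#' @param n_steps Online training iterations (one reference spectrum
#'   presented per step).  20,000 is typical for leave-one-out folds and
#'   50,000 for maps trained on a full reference set.
#' @param alpha0,alpha_end Initial/final learning rate; exponential decay.
#' @param sigma0,sigma_end Initial/final Gaussian neighbourhood radius in map
#'   units; `sigma0 = NULL` means `map_dim / 2`.
#' @param seed Integer RNG seed controlling node initialisation and the
#'   presentation order; fixed seed implies a bit-identical trained map.
#' @param k_bmu Number of best-matching units averaged in prediction
#'   (3 or 5 in routine use).
#' @param weight_power Inverse-distance power p for structure assignment
#'   weights (w = 1/d^p).  The default 2 (Shepard inverse-square weighting)
#'   keeps the assignment local; p = 1 spreads weight so widely over the
#'   reference set that interpolated node structures shrink towards the
#'   global mean.
#' @return List of class `som_config`.
#' @export
som_config <- function(map_dim = NULL, n_steps = 20000,
                       alpha0 = 0.5, alpha_end = 0.01,
                       sigma0 = NULL, sigma_end = 0.5,
                       seed = 1L, k_bmu = 5L, weight_power = 2) {
  if (!is.null(map_dim) && map_dim < 2) stop("map_dim must be >= 2", call. = FALSE)
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (!(alpha_end > 0 && alpha_end <= alpha0 && alpha0 <= 1))
    stop("need 0 < alpha_end <= alpha0 <= 1", call. = FALSE)
  if (sigma_end <= 0) stop("sigma_end must be > 0", call. = FALSE)
  if (k_bmu < 1) stop("k_bmu must be >= 1", call. = FALSE)
  structure(list(map_dim = map_dim, n_steps = as.integer(n_steps),
                 alpha0 = alpha0, alpha_end = alpha_end,
                 sigma0 = sigma0, sigma_end = sigma_end,
                 seed = as.integer(seed), k_bmu = as.integer(k_bmu),
                 weight_power = weight_power),
            class = "som_config")
}

default_map_dim <- function(n) {
  if (n >= 45) return(40L)
  if (n >= 25 && n <= 35) return(20L)
  as.integer(min(40, ceiling(4 * sqrt(n))))
}

node_coords <- function(side) {
  j <- seq_len(side * side)
  data.frame(node = j, row = (j - 1L) %/% side + 1L,
             col = (j - 1L) %% side + 1L)
}

#' Train a self-organising map on a reference set
#'
#' Runs the classic online Kohonen algorithm: at each step a reference
#' spectrum is drawn (uniformly, seeded), its best matching node located by
#' Euclidean distance in spectral space, and every node pulled towards the
#' spectrum with a learning rate times a Gaussian neighbourhood factor in
#' map-grid distance.  Learning rate and neighbourhood radius decay
#' exponentially over the run.  Nodes are initialised elementwise-uniform
#' between the per-wavenumber minimum and maximum of the reference set.
#'
#' After training each reference member is placed on its nearest node
#' (ties broken by lowest row-major node index) and, when `assign = TRUE`,
#' secondary-structure vectors are attached to every node via
#' [assign_structures()].
#'
#' @param refset A [reference_set()].
#' @param config A [som_config()].
#' @param assign Also assign node structures (default TRUE).
#' @return Object of class `som_map`: `side`, `grid`, `node_spectra`
#'   (matrix, one column per node in row-major node order), `coords`,
#'   `node_structures` (nodes x 3, or NULL), `placements` (named integer
#'   vector, member label -> node), `config`, and `qe_trace`, the mean
#'   reference-to-BMU distance logged at checkpoints during training.
#' @export
som_train <- function(refset, config = som_config(), assign = TRUE) {
  stopifnot(inherits(refset, "reference_set"))
  if (any(!is.finite(refset$spectra)))
    stop("training error: non-finite reference spectrum", call. = FALSE)
  n <- ncol(refset$spectra)
  side <- if (is.null(config$map_dim)) default_map_dim(n) else
    as.integer(config$map_dim)
  sigma0 <- if (is.null(config$sigma0)) side / 2 else config$sigma0
  npts <- length(refset$grid)
  nn <- side * side
  rmin <- apply(refset$spectra, 1, min)
  rmax <- apply(refset$spectra, 1, max)
  state <- withr::with_seed(config$seed, {
    w0 <- rmin + matrix(stats::runif(npts * nn), npts, nn) * (rmax - rmin)
    ord <- sample.int(n, config$n_steps, replace = TRUE)
    list(w0 = w0, ord = ord)
  })
  trace_every <- max(1L, config$n_steps %/% 50L)
  w <- som_train_cpp(state$w0, refset$spectra, state$ord, side,
                     config$alpha0, config$alpha_end, sigma0, config$sigma_end,
                     trace_every)
  qe_trace <- attr(w, "qe_trace")
  attr(w, "qe_trace") <- NULL
  d2 <- cross_dist2_cpp(w, refset$spectra)   # nodes x members
  placements <- apply(d2, 2, which.min)      # ties: lowest row-major index
  names(placements) <- refset$labels
  map <- structure(list(side = side, grid = refset$grid, node_spectra = w,
                        coords = node_coords(side),
                        node_structures = NULL,
                        placements = placements,
                        config = config, qe_trace = qe_trace),
                   class = "som_map")
  if (assign) map <- assign_structures(map, refset, p = config$weight_power)
  map
}

#' @export
print.som_map <- function(x, ...) {
  cat(sprintf("<som_map %dx%d: %d-point grid, %d reference placements%s>\n",
              x$side, x$side, length(x$grid), length(x$placements),
              if (is.null(x$node_structures)) ", structures unassigned" else ""))
  invisible(x)
}

#' Assign secondary-structure vectors to map nodes
#'
#' Nodes holding a reference placement take that member's fractions exactly
#' (when several members share a node, the spectrally closest one).  Every
#' other node receives an inverse-distance-weighted average of all reference
#' members' fractions, with weights `1/d^p` on the Euclidean distance between
#' the node spectrum and each reference spectrum; a zero distance is treated
#' as an exact match and the member's fractions are copied.  The resulting
#' triple is renormalised to sum to 1, so every node structure lies on the
#' unit simplex.
#'
#' @param map A `som_map` from [som_train()].
#' @param refset The [reference_set()] the map was trained on.
#' @param p Inverse-distance weighting power.
#' @return The map with `node_structures` filled in.
#' @export
assign_structures <- function(map, refset, p = 2) {
  stopifnot(inherits(map, "som_map"), inherits(refset, "reference_set"))
  if (!grids_match(map$grid, refset$grid))
    stop("reference set grid does not match the map grid", call. = FALSE)
  d <- sqrt(cross_dist2_cpp(map$node_spectra, refset$spectra))  # nodes x N
  nn <- ncol(map$node_spectra)
  fr <- refset$fractions
  out <- matrix(NA_real_, nn, 3, dimnames = list(NULL, colnames(fr)))
  placed <- split(seq_along(map$placements), map$placements)
  for (j in seq_len(nn)) {
    key <- as.character(j)
    if (!is.null(placed[[key]])) {
      members <- placed[[key]]
      out[j, ] <- fr[members[which.min(d[j, members])], ]
    } else if (any(d[j, ] == 0)) {
      hits <- which(d[j, ] == 0)
      out[j, ] <- colMeans(fr[hits, , drop = FALSE])
    } else {
      w <- 1 / d[j, ]^p
      out[j, ] <- colSums(w * fr) / sum(w)
    }
    out[j, ] <- out[j, ] / sum(out[j, ])
  }
  map$node_structures <- out
  map
}

grids_match <- function(g1, g2, tol = 1e-8) {
  length(g1) == length(g2) && max(abs(g1 - g2)) <= tol
}

check_on_grid <- function(map, s) {
  if (!grids_match(map$grid, s$wavenumbers))
    stop(sprintf(
      "grid error: spectrum '%s' is not on the map's wavenumber grid", s$label),
      call. = FALSE)
}

#' Best matching units for a spectrum
#'
#' Ranks map nodes by Euclidean distance between their stored spectra and the
#' query spectrum and returns the top k.  Ties are broken by lowest row-major
#' node index.
#'
#' @param map A `som_map`.
#' @param s An [ir_spectrum()] on the map's grid.
#' @param k Number of BMUs.
#' @return data.frame with columns `node`, `row`, `col`, `distance`, sorted
#'   by non-decreasing distance.
#' @export
find_bmus <- function(map, s, k = map$config$k_bmu) {
  stopifnot(inherits(map, "som_map"), inherits(s, "ir_spectrum"))
  check_on_grid(map, s)
  nn <- ncol(map$node_spectra)
  if (k > nn) stop("k exceeds the number of map nodes", call. = FALSE)
  d <- sqrt(colSums((map$node_spectra - s$absorbance)^2))
  ord <- order(d, seq_along(d))[seq_len(k)]
  data.frame(node = ord, row = map$coords$row[ord], col = map$coords$col[ord],
             distance = d[ord])
}

#' Predict secondary structure for a test spectrum
#'
#' The test step: the k best matching units are found in spectral space and
#' the estimated fractions are their structure vectors averaged with
#' inverse-distance weights `1/d`.  If any BMU distance is zero the estimate
#' is the plain mean over all zero-distance nodes.  The same weights applied
#' to the BMU node spectra give a reconstructed spectrum, whose normalised
#' root-mean-square deviation ([nrmsd()]) from the input is the fit-quality
#' measure.
#'
#' @param object A `som_map` with assigned structures.
#' @param s An [ir_spectrum()], preprocessed (normalised) on the map's grid.
#' @param k Number of BMUs (defaults to the training config's `k_bmu`).
#' @param ... Unused.
#' @return Object of class `som_prediction`: `label`, `fractions`
#'   ([structure_fractions()]), `bmus` (as [find_bmus()], plus
#'   `grid_distance`, the map-grid Euclidean distance of each BMU from the
#'   first, kept for diagnostics), `reconstructed`, `nrmsd`.
#' @export
predict.som_map <- function(object, s, k = object$config$k_bmu, ...) {
  if (is.null(object$node_structures))
    stop("map has no node structures; run assign_structures()", call. = FALSE)
  bmus <- find_bmus(object, s, k)
  zero <- bmus$distance == 0
  w <- if (any(zero)) as.numeric(zero) else 1 / bmus$distance
  w <- w / sum(w)
  f <- colSums(w * object$node_structures[bmus$node, , drop = FALSE])
  f <- f / sum(f)
  recon <- as.numeric(object$node_spectra[, bmus$node, drop = FALSE] %*% w)
  bmus$grid_distance <- sqrt((bmus$row - bmus$row[1])^2 +
                             (bmus$col - bmus$col[1])^2)
  structure(list(label = s$label,
                 fractions = structure_fractions(f[["helix"]], f[["sheet"]],
                                                 f[["other"]]),
                 bmus = bmus,
                 reconstructed = recon,
                 nrmsd = nrmsd(s$absorbance, recon)),
            class = "som_prediction")
}

#' @export
print.som_prediction <- function(x, ...) {
  cat(sprintf("<som_prediction '%s': helix %.3f sheet %.3f other %.3f, NRMSD %.4f>\n",
              x$label, x$fractions[["helix"]], x$fractions[["sheet"]],
              x$fractions[["other"]], x$nrmsd))
  invisible(x)
}

#' Normalised root-mean-square deviation
#'
#' `sqrt(sum((obs - pred)^2) / sum(obs^2))`: 0 for a perfect reconstruction,
#' 1 when the prediction is identically zero.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
nrmsd <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  denom <- sum(observed^2)
  if (denom == 0) stop("observed vector has zero norm", call. = FALSE)
  sqrt(sum((observed - predicted)^2) / denom)
}

#' Save / load a trained map
#'
#' Serialises every field of a `som_map` to JSON at maximum decimal-text
#' precision (15+ significant digits), so save-then-load reproduces
#' predictions to better than 1e-12 relative.  A loaded map refuses to
#' predict spectra on a different wavenumber grid.
#'
#' @param map A `som_map`.
#' @param path Output path (JSON).
#' @return `path` invisibly; `load_map` returns the `som_map`.
#' @export
save_map <- function(map, path) {
  stopifnot(inherits(map, "som_map"))
  obj <- list(format = "amidesom-map", version = 1L,
              side = map$side, grid = map$grid,
              node_spectra = map$node_spectra,
              node_structures = map$node_structures,
              placements = as.list(map$placements),
              config = unclass(map$config),
              qe_trace = map$qe_trace)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_map
#' @export
load_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "amidesom-map"))
    stop(sprintf("%s is not a saved map", path), call. = FALSE)
  cfg <- obj$config
  config <- som_config(map_dim = cfg$map_dim, n_steps = cfg$n_steps,
                       alpha0 = cfg$alpha0, alpha_end = cfg$alpha_end,
                       sigma0 = cfg$sigma0, sigma_end = cfg$sigma_end,
                       seed = cfg$seed, k_bmu = cfg$k_bmu,
                       weight_power = cfg$weight_power)
  placements <- unlist(obj$placements)
  ns <- obj$node_structures
  if (!is.null(ns)) colnames(ns) <- c("helix", "sheet", "other")
  structure(list(side = obj$side, grid = obj$grid,
                 node_spectra = obj$node_spectra,
                 coords = node_coords(obj$side),
                 node_structures = ns,
                 placements = placements,
                 config = config, qe_trace = obj$qe_trace),
            class = "som_map")
}
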