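#' Infrared absorbance spectrum
#'
#' Constructs an `ir_spectrum`, the basic container used throughout the
#' package: absorbance values on a wavenumber grid in cm^-1.  Wavenumbers may
#' be supplied in either direction but are stored ascending.
#'
#' @param wavenumbers Numeric vector of wavenumbers (cm^-1), strictly
#'   monotonic, length >= 3.
#' @param absorbance Numeric vector of absorbance values, same length.
#' @param label Free-text identifier.
#' @return An object of class `ir_spectrum` with fields `wavenumbers`
#'   (ascending), `absorbance` and `label`.
#' @examples
#' s <- ir_spectrum(seq(1600, 1700, 2), dnorm(seq(1600, 1700, 2), 1654, 7))
#' range(s$wavenumbers)
#' @export
ir_spectrum <- function(wavenumbers, absorbance, label = "") {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance must have equal length", call. = FALSE)
  if (length(wavenumbers) < 3)
    stop("a spectrum needs at least 3 points", call. = FALSE)
  if (anyNA(wavenumbers) || anyNA(absorbance))
    stop("spectrum contains missing values", call. = FALSE)
  d <- diff(wavenumbers)
  if (all(d > 0)) {
    # already ascending
  } else if (all(d < 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  } else {
    stop("wavenumbers must be strictly monotonic", call. = FALSE)
  }
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 label = as.character(label)[1]),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum '%s': %d points, %.6g-%.6g cm^-1>\n",
              x$label, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Secondary-structure fractions
#'
#' A triple (helix, sheet, other) of per-residue secondary-structure
#' fractions.  Helix counts alpha-helix plus 3_10-helix, sheet is beta-sheet,
#' and "other" is everything else, so the three always sum to 1.  When
#' `other` is omitted it is computed as `1 - helix - sheet`.
#'
#' @param helix,sheet,other Fractions in \[0, 1\].
#' @param tol Tolerance on the unit-sum constraint.
#' @return Named numeric vector `c(helix=, sheet=, other=)` of class
#'   `structure_fractions`.
#' @examples
#' structure_fractions(0.4, 0.3)          # other = 0.3
#' @export
structure_fractions <- function(helix, sheet, other = NULL, tol = 1e-6) {
  helix <- as.numeric(helix); sheet <- as.numeric(sheet)
  if (is.null(other)) other <- 1 - helix - sheet
  other <- as.numeric(other)
  f <- c(helix = helix, sheet = sheet, other = other)
  if (anyNA(f)) stop("structure fractions contain NA", call. = FALSE)
  if (any(f < -tol) || any(f > 1 + tol))
    stop("structure fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(f) - 1) > tol)
    stop(sprintf("structure fractions must sum to 1 (got %.8f)", sum(f)),
         call. = FALSE)
  f <- pmin(pmax(f, 0), 1)
  class(f) <- "structure_fractions"
  f
}

#' @export
print.structure_fractions <- function(x, ...) {
  cat(sprintf("helix %.3f  sheet %.3f  other %.3f\n",
              x[["helix"]], x[["sheet"]], x[["other"]]))
  invisible(x)
}

#' Reference set of spectra with known structure
#'
#' Pairs N protein spectra sharing one wavenumber grid with their
#' secondary-structure fractions.  This is the training input for
#' [som_train()] and [loov()].
#'
#' @param grid Common ascending wavenumber vector (cm^-1).
#' @param spectra Numeric matrix, `length(grid)` rows by N columns, one
#'   member spectrum per column.
#' @param fractions Numeric matrix, N rows by 3 columns (helix, sheet,
#'   other), or a list of [structure_fractions()].
#' @param labels Character vector of N member labels.
#' @return Object of class `reference_set`.
#' @export
reference_set <- function(grid, spectra, fractions, labels = NULL) {
  grid <- as.numeric(grid)
  spectra <- as.matrix(spectra)
  if (is.list(fractions)) fractions <- do.call(rbind, fractions)
  fractions <- as.matrix(fractions)
  n <- ncol(spectra)
  if (n < 2) stop("a reference set needs at least 2 members", call. = FALSE)
  if (length(grid) < 3 || any(diff(grid) <= 0))
    stop("grid must be strictly ascending with >= 3 points", call. = FALSE)
  if (nrow(spectra) != length(grid))
    stop("spectra rows must match grid length", call. = FALSE)
  if (nrow(fractions) != n || ncol(fractions) != 3)
    stop("fractions must be an N x 3 matrix (helix, sheet, other)",
         call. = FALSE)
  if (any(!is.finite(spectra)))
    stop("reference spectra must be finite", call. = FALSE)
  if (is.null(labels)) labels <- sprintf("R%d", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("need one label per member", call. = FALSE)
  colnames(fractions) <- c("helix", "sheet", "other")
  for (j in seq_len(n)) {
    ok <- tryCatch({
      structure_fractions(fractions[j, 1], fractions[j, 2], fractions[j, 3])
      TRUE
    }, error = function(e) FALSE)
    if (!ok)
      stop(sprintf(
        "invalid structure fractions for member %d ('%s'): sum = %.6f",
        j, labels[j], sum(fractions[j, ])), call. = FALSE)
  }
  colnames(spectra) <- labels
  rownames(fractions) <- labels
  structure(list(grid = grid, spectra = spectra, fractions = fractions,
                 labels = labels),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set: %d members, %d-point grid %.6g-%.6g cm^-1>\n",
              ncol(x$spectra), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
length.reference_set <- function(x) ncol(x$spectra)

#' Extract one member of a reference set as a spectrum
#'
#' @param refset A [reference_set()].
#' @param i Member index or label.
#' @return An [ir_spectrum()].
#' @export
refset_member <- function(refset, i) {
  if (is.character(i)) i <- match(i, refset$labels)
  ir_spectrum(refset$grid, refset$spectra[, i], label = refset$labels[i])
}

#' Drop members from a reference set
#'
#' Used by the leave-one-out driver to form each fold's training set.
#'
#' @param refset A [reference_set()].
#' @param i Indices or labels to drop.
#' @return A smaller `reference_set`.
#' @export
refset_drop <- function(refset, i) {
  if (is.character(i)) i <- match(i, refset$labels)
  keep <- setdiff(seq_along(refset$labels), i)
  reference_set(refset$grid, refset$spectra[, keep, drop = FALSE],
                refset$fractions[keep, , drop = FALSE],
                refset$labels[keep])
}
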