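# File formats: comma-separated training/test files (columns of spectral
# data, structure rows below) and generic two-column spectra.

fmt_num <- function(x) trimws(formatC(x, digits = 9, format = "g"))

strict_numeric <- function(fields, path, what) {
  out <- suppressWarnings(as.numeric(fields))
  if (anyNA(out))
    stop(sprintf("%s: cannot parse %s value '%s' (dot decimal separator required)",
                 path, what, fields[which(is.na(out))[1]]), call. = FALSE)
  out
}

read_csv_rows <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  comments <- lines[startsWith(trimws(lines), "#")]
  data <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  list(rows = strsplit(data, ",", fixed = TRUE), comments = comments)
}

comment_value <- function(comments, key) {
  hit <- grep(sprintf("^#\\s*%s:", key), comments, value = TRUE)
  if (!length(hit)) return(NULL)
  trimws(sub(sprintf("^#\\s*%s:", key), "", hit[1]))
}

#' Read a training file (reference set)
#'
#' Parses the comma-separated training format: N vertical columns of spectral
#' data, one column per protein, with the corresponding structure rows placed
#' below the spectral block.  In this package's dialect the three structure
#' rows are tagged `helix`, `sheet`, `other` in their first field, and the
#' wavenumber grid is either embedded as the first column of the spectral
#' block (the default written by [write_training_file()]) or supplied via
#' `grid`.  Member labels are carried in a `# labels:` comment line.
#'
#' @param path Path to a comma-separated text file.
#' @param grid Optional wavenumber vector when the file does not embed one.
#' @return A [reference_set()].
#' @seealso [write_training_file()], [read_test_file()]
#' @export
read_training_file <- function(path, grid = NULL) {
  parsed <- read_csv_rows(path)
  rows <- parsed$rows
  if (length(rows) < 4)
    stop(sprintf("%s: too few rows for a training file", path), call. = FALSE)
  nr <- length(rows)
  tags <- vapply(rows[(nr - 2):nr], `[`, "", 1)
  if (!identical(tolower(trimws(tags)), c("helix", "sheet", "other")))
    stop(sprintf(
      "%s: last three rows must be structure rows tagged helix, sheet, other",
      path), call. = FALSE)
  struct_rows <- rows[(nr - 2):nr]
  spec_rows <- rows[seq_len(nr - 3)]
  n <- length(struct_rows[[1]]) - 1L
  if (n < 1) stop(sprintf("%s: no data columns", path), call. = FALSE)
  widths <- lengths(spec_rows)
  if (length(unique(widths)) != 1 ||
      length(unique(lengths(struct_rows))) != 1)
    stop(sprintf("%s: ragged columns", path), call. = FALSE)
  w <- widths[1]
  if (w == n + 1L) {
    grid_file <- strict_numeric(vapply(spec_rows, `[`, "", 1), path, "grid")
    vals <- lapply(spec_rows, function(r) strict_numeric(r[-1], path, "spectral"))
    grid <- grid_file
  } else if (w == n) {
    if (is.null(grid))
      stop(sprintf("%s: file has no embedded grid; supply `grid`", path),
           call. = FALSE)
    if (length(grid) != length(spec_rows))
      stop(sprintf("%s: %d spectral rows but supplied grid has %d points",
                   path, length(spec_rows), length(grid)), call. = FALSE)
    vals <- lapply(spec_rows, function(r) strict_numeric(r, path, "spectral"))
  } else {
    stop(sprintf("%s: ragged columns (spectral rows have %d fields, expected %d or %d)",
                 path, w, n, n + 1L), call. = FALSE)
  }
  spectra <- do.call(rbind, vals)
  fr <- do.call(cbind, lapply(struct_rows, function(r)
    strict_numeric(r[-1], path, "structure")))
  colnames(fr) <- c("helix", "sheet", "other")
  labels <- comment_value(parsed$comments, "labels")
  labels <- if (is.null(labels)) sprintf("R%d", seq_len(n)) else
    trimws(strsplit(labels, ",", fixed = TRUE)[[1]])
  for (j in seq_len(n)) {
    if (abs(sum(fr[j, ]) - 1) > 1e-6)
      stop(sprintf("%s: structure column %d ('%s') sums to %.6f, not 1",
                   path, j, labels[j], sum(fr[j, ])), call. = FALSE)
  }
  reference_set(grid, spectra, fr, labels)
}

#' Write a training file
#'
#' Writes a [reference_set()] in the comma-separated training format read by
#' [read_training_file()].  Numbers are written with 9 significant digits and
#' a dot decimal separator, so write-then-read round-trips to within 1e-9.
#'
#' @param refset A [reference_set()].
#' @param path Output path.
#' @param embed_grid Write the wavenumber grid as the first column of the
#'   spectral block (default TRUE).
#' @return `path`, invisibly.
#' @export
write_training_file <- function(refset, path, embed_grid = TRUE) {
  stopifnot(inherits(refset, "reference_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# amidesom training file",
               paste0("# labels: ", paste(refset$labels, collapse = ","))),
             con)
  sp <- refset$spectra
  for (i in seq_along(refset$grid)) {
    row <- fmt_num(sp[i, ])
    if (embed_grid) row <- c(fmt_num(refset$grid[i]), row)
    writeLines(paste(row, collapse = ","), con)
  }
  for (cls in c("helix", "sheet", "other"))
    writeLines(paste(c(cls, fmt_num(refset$fractions[, cls])), collapse = ","),
               con)
  invisible(path)
}

#' Read a test file (spectra without structure rows)
#'
#' Test files hold one or more comma-separated columns of spectral data with
#' no structure block; the single-column case is the leave-one-out layout.
#' The grid is taken from an embedded first column (when the file carries a
#' `# grid: embedded` marker, as written by [write_test_file()]) or from
#' `grid`.
#'
#' @param path Path to the file.
#' @param grid Wavenumber grid to attach when not embedded.
#' @return List of [ir_spectrum()] objects, one per column.
#' @export
read_test_file <- function(path, grid = NULL) {
  parsed <- read_csv_rows(path)
  rows <- parsed$rows
  if (length(rows) < 3)
    stop(sprintf("%s: too few rows", path), call. = FALSE)
  if (length(unique(lengths(rows))) != 1)
    stop(sprintf("%s: ragged columns", path), call. = FALSE)
  embedded <- identical(comment_value(parsed$comments, "grid"), "embedded")
  vals <- lapply(rows, function(r) strict_numeric(r, path, "spectral"))
  m <- do.call(rbind, vals)
  if (embedded) {
    grid <- m[, 1]
    m <- m[, -1, drop = FALSE]
  } else {
    if (is.null(grid))
      stop(sprintf("%s: file has no embedded grid; supply `grid`", path),
           call. = FALSE)
    if (nrow(m) != length(grid))
      stop(sprintf("%s: %d values per column but grid has %d points",
                   path, nrow(m), length(grid)), call. = FALSE)
  }
  labels <- comment_value(parsed$comments, "labels")
  labels <- if (is.null(labels)) sprintf("T%d", seq_len(ncol(m))) else
    trimws(strsplit(labels, ",", fixed = TRUE)[[1]])
  lapply(seq_len(ncol(m)), function(j)
    ir_spectrum(grid, m[, j], label = labels[j]))
}

#' Write spectra as a test file
#'
#' @param spectra A single [ir_spectrum()] or list of them on a common grid.
#' @param path Output path.
#' @param embed_grid Embed the grid as the first column.
#' @return `path`, invisibly.
#' @export
write_test_file <- function(spectra, path, embed_grid = TRUE) {
  if (inherits(spectra, "ir_spectrum")) spectra <- list(spectra)
  grid <- spectra[[1]]$wavenumbers
  for (s in spectra)
    if (!isTRUE(all.equal(s$wavenumbers, grid)))
      stop("all spectra must share one grid", call. = FALSE)
  labels <- vapply(spectra, function(s) s$label, "")
  m <- vapply(spectra, function(s) s$absorbance, numeric(length(grid)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# amidesom test file",
               if (embed_grid) "# grid: embedded",
               paste0("# labels: ", paste(labels, collapse = ","))), con)
  for (i in seq_along(grid)) {
    row <- fmt_num(m[i, ])
    if (embed_grid) row <- c(fmt_num(grid[i]), row)
    writeLines(paste(row, collapse = ","), con)
  }
  invisible(path)
}

#' Read a generic two-column spectrum
#'
#' Reads (wavenumber, absorbance) pairs from delimited text with optional
#' `#` comment lines; comma, tab and whitespace delimiters are accepted.
#'
#' @param path Path to the file.
#' @param label Label for the returned spectrum (default: file name).
#' @return An [ir_spectrum()].
#' @export
read_spectrum <- function(path, label = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  rows <- if (any(grepl(",", lines, fixed = TRUE)))
    strsplit(lines, ",", fixed = TRUE)
  else strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(rows) != 2))
    stop(sprintf("%s: expected two columns (wavenumber, absorbance)", path),
         call. = FALSE)
  m <- do.call(rbind, lapply(rows, function(r) strict_numeric(r, path, "")))
  if (is.null(label)) label <- basename(path)
  ir_spectrum(m[, 1], m[, 2], label = label)
}

#' Write a spectrum as two-column delimited text
#'
#' @param s An [ir_spectrum()].
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, delim = ",") {
  stopifnot(inherits(s, "ir_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", s$label), con)
  writeLines(paste(fmt_num(s$wavenumbers), fmt_num(s$absorbance), sep = delim),
             con)
  invisible(path)
}

#' Export predictions as CSV
#'
#' One row per prediction: label, the three estimated fractions, the spectral
#' NRMSD of the reconstruction, and the k best-matching nodes with their
#' spectral distances.
#'
#' @param predictions A single prediction from [predict.som_map()] or a list
#'   of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  if (inherits(predictions, "som_prediction")) predictions <- list(predictions)
  k <- nrow(predictions[[1]]$bmus)
  rows <- lapply(predictions, function(p) {
    data.frame(label = p$label,
               helix = p$fractions[["helix"]],
               sheet = p$fractions[["sheet"]],
               other = p$fractions[["other"]],
               nrmsd = p$nrmsd,
               rbind(stats::setNames(p$bmus$node, sprintf("bmu%d", seq_len(k)))),
               rbind(stats::setNames(p$bmus$distance, sprintf("d%d", seq_len(k)))),
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
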