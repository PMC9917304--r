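#' Amplitude tables
#'
#' Long-format table of mean response intensities: one row per
#' bee x stimulus, in \eqn{\Delta F/F} percent, averaged over the two
#' presentations. The inclusion rule of the imaging protocol is enforced as a
#' completeness check: every bee must have a value for every stimulus of the
#' panel (animals with missing presentations are excluded upstream).
#'
#' @param x data frame with columns `bee`, `stimulus`, `amplitude` and
#'   optionally `structure`.
#' @param panel optional [odor_panel()]; stimulus names are validated
#'   against it and the completeness check uses the full panel.
#' @return An object of class `amplitude_table` (a data frame).
#' @export
amplitude_table <- function(x, panel = NULL) {
  req <- c("bee", "stimulus", "amplitude")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("amplitude table lacks columns: ",
                         paste(miss, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(x$structure)) x$structure <- NA_character_
  x <- x[, c("bee", "structure", "stimulus", "amplitude")]
  if (!is.numeric(x$amplitude)) stop("amplitude must be numeric")
  if (anyDuplicated(x[, c("bee", "stimulus")]))
    stop("duplicate bee x stimulus cells")
  stimuli <- unique(x$stimulus)
  if (!is.null(panel)) {
    unknown <- setdiff(stimuli, panel$name)
    if (length(unknown))
      stop("unknown stimulus name(s): ", paste(unknown, collapse = ", "))
    stimuli <- panel$name
  }
  bees <- unique(x$bee)
  full <- expand.grid(bee = bees, stimulus = stimuli, stringsAsFactors = FALSE)
  have <- paste(x$bee, x$stimulus, sep = "\r")
  want <- paste(full$bee, full$stimulus, sep = "\r")
  missing_cells <- full[!(want %in% have), , drop = FALSE]
  if (nrow(missing_cells))
    stop("incomplete block design; missing bee x stimulus pairs: ",
         paste(missing_cells$bee, missing_cells$stimulus, sep = ":",
               collapse = ", "))
  class(x) <- c("amplitude_table", "data.frame")
  x
}

#' Read and write amplitude tables
#'
#' The canonical on-disk format is long CSV with columns
#' `bee, structure, stimulus, amplitude`. XLSX files (e.g. supplementary data
#' tables) can be imported by supplying an explicit `layout` mapping, since
#' spreadsheet layouts vary: `layout = list(format = "long", sheet = 1,
#' columns = c(bee = "Bee", stimulus = "Odorant", amplitude = "Amplitude"))`
#' or `layout = list(format = "wide", sheet = 1, bee_column = 1)` for tables
#' with bees as rows and odorants as columns.
#'
#' @param path CSV or XLSX file path.
#' @param layout layout mapping, required for XLSX input.
#' @param panel optional [odor_panel()] for name validation.
#' @param structure optional structure label to attach to every row.
#' @return An [amplitude_table()].
#' @export
read_amplitude_table <- function(path, layout = NULL, panel = NULL,
                                 structure = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (is.null(layout))
      stop("XLSX import requires an explicit `layout` mapping")
    sheet <- layout$sheet %||% 1
    raw <- as.data.frame(readxl::read_excel(path, sheet = sheet))
    fmt <- match.arg(layout$format %||% "long", c("long", "wide"))
    if (fmt == "long") {
      cols <- layout$columns
      if (is.null(cols) || !all(c("bee", "stimulus", "amplitude") %in% names(cols)))
        stop("long layout needs `columns` naming bee, stimulus and amplitude")
      tab <- data.frame(bee = as.character(raw[[cols[["bee"]]]]),
                        stimulus = as.character(raw[[cols[["stimulus"]]]]),
                        amplitude = as.numeric(raw[[cols[["amplitude"]]]]),
                        stringsAsFactors = FALSE)
    } else {
      bee_col <- layout$bee_column %||% 1
      odors <- setdiff(names(raw), names(raw)[bee_col])
      tab <- data.frame(
        bee = rep(as.character(raw[[bee_col]]), times = length(odors)),
        stimulus = rep(odors, each = nrow(raw)),
        amplitude = as.numeric(unlist(raw[odors], use.names = FALSE)),
        stringsAsFactors = FALSE)
    }
  } else {
    tab <- read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(structure)) tab$structure <- structure
  amplitude_table(tab, panel = panel)
}

#' @rdname read_amplitude_table
#' @param table an [amplitude_table()].
#' @export
write_amplitude_table <- function(table, path) {
  stopifnot(inherits(table, "amplitude_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Labeled distance matrices
#'
#' Symmetric nonnegative matrices of inter-odorant Euclidean distances with a
#' zero diagonal. Slightly asymmetric input (e.g. rounded on export) is
#' symmetrized by averaging when the largest asymmetry is within `tol`;
#' larger asymmetries are rejected.
#'
#' @param values square numeric matrix.
#' @param labels stimulus names (defaults to `rownames(values)`).
#' @param provenance one of `"per-bee"`, `"cross-bee-mean"`, `"behavioral"`,
#'   `"latent"`.
#' @param tol maximum tolerated absolute asymmetry.
#' @return An object of class `dist_matrix`.
#' @export
dist_matrix <- function(values, labels = rownames(values),
                        provenance = "per-bee", tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(labels)) stop("distance matrix needs stimulus labels")
  if (length(labels) != nrow(values))
    stop("label count does not match matrix dimension")
  if (anyDuplicated(labels)) stop("duplicate stimulus labels")
  asym <- max(abs(values - t(values)))
  if (asym > tol)
    stop("asymmetry ", format(asym), " exceeds tolerance ", format(tol))
  values <- (values + t(values)) / 2
  if (max(abs(diag(values))) > tol) stop("diagonal must be zero")
  diag(values) <- 0
  if (min(values) < -tol) stop("distances must be nonnegative")
  values[values < 0] <- 0
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, provenance = provenance),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  n <- length(x$labels)
  cat("Distance matrix (", x$provenance, "): ", n, " stimuli, ",
      n * (n - 1) / 2, " pairs\n", sep = "")
  print(round(x$values, 3), ...)
  invisible(x)
}

#' @rdname dist_matrix
#' @param path CSV file path (square, labeled, first column = row names).
#' @export
read_distance_matrix <- function(path, provenance = "per-bee", tol = 1e-8) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m))
    stop("non-square distance matrix in ", path, " (", nrow(m), "x", ncol(m), ")")
  dist_matrix(m, labels = rownames(m), provenance = provenance, tol = tol)
}

#' @rdname dist_matrix
#' @param dm a `dist_matrix`.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "dist_matrix"))
  write.csv(dm$values, path, row.names = TRUE)
  invisible(path)
}

upper_values <- function(dm) dm$values[upper.tri(dm$values)]
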