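#' Fluorescence movies and region masks
#'
#' A movie is a `height x width x n_frames` array of nonnegative integer
#' fluorescence counts (12-bit range) plus acquisition metadata. The standard
#' acquisition protocol records 100 frames at 5 Hz with the odor given at the
#' 15th frame for 1 s (5 frames); [ca_movie()] warns when `n_frames` deviates
#' from 100 but does not fail, so trimmed recordings remain usable.
#'
#' @param pixels numeric array `height x width x n_frames`, values in
#'   0..4095.
#' @param frame_rate acquisition rate in Hz.
#' @param stimulus_onset_frame 1-based frame index of odor onset.
#' @param stimulus_duration_frames stimulus duration in frames.
#' @param structure_label one of `"AL"`, `"LH"`, `"MB"`, `"whole_brain"`.
#' @param bee_id,stimulus_id,presentation_index identifiers (presentation is
#'   1 or 2, or `NA` when averaged).
#' @return An object of class `ca_movie`.
#' @export
ca_movie <- function(pixels, frame_rate = 5, stimulus_onset_frame = 15,
                     stimulus_duration_frames = 5,
                     structure_label = "AL", bee_id = NA_character_,
                     stimulus_id = NA_character_, presentation_index = NA_integer_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("pixels must be a height x width x n_frames array")
  if (anyNA(pixels) || min(pixels) < 0)
    stop("movie intensities must be nonnegative and non-missing")
  if (max(pixels) > 4095)
    stop("raw movie intensities exceed the 12-bit range (4095)")
  n_frames <- dim(pixels)[3]
  if (n_frames != 100L)
    warning("movie has ", n_frames, " frames; the standard protocol records 100")
  if (stimulus_onset_frame + stimulus_duration_frames > n_frames)
    stop("stimulus extends beyond the last frame")
  structure_label <- match.arg(structure_label,
                               c("AL", "LH", "MB", "whole_brain"))
  structure(list(pixels = pixels, frame_rate = frame_rate,
                 stimulus_onset_frame = stimulus_onset_frame,
                 stimulus_duration_frames = stimulus_duration_frames,
                 structure_label = structure_label, bee_id = bee_id,
                 stimulus_id = stimulus_id,
                 presentation_index = presentation_index),
            class = "ca_movie")
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$pixels)
  cat("Calcium movie: ", d[1], "x", d[2], " px, ", d[3], " frames @ ",
      x$frame_rate, " Hz [", x$structure_label, "]\n", sep = "")
  cat("  stimulus: frame ", x$stimulus_onset_frame, " for ",
      x$stimulus_duration_frames, " frames; bee=", x$bee_id, " stimulus=",
      x$stimulus_id, " presentation=", x$presentation_index, "\n", sep = "")
  invisible(x)
}

#' @export
dim.ca_movie <- function(x) dim(x$pixels)

movie_metadata <- function(movie) {
  movie[c("frame_rate", "stimulus_onset_frame", "stimulus_duration_frames",
          "structure_label", "bee_id", "stimulus_id", "presentation_index")]
}

#' Read and write movies as multi-page TIFF stacks
#'
#' Movies are stored as 16-bit multi-page TIFF files (one page per frame,
#' values 0..4095) with a JSON metadata sidecar at `<path>.json` carrying the
#' acquisition fields. The pair is an exact inverse: `read_movie(write_movie())`
#' reproduces every pixel and metadata field.
#'
#' @param path TIFF file path.
#' @param metadata optional named list overriding sidecar metadata fields
#'   (any of `frame_rate`, `stimulus_onset_frame`, `stimulus_duration_frames`,
#'   `structure_label`, `bee_id`, `stimulus_id`, `presentation_index`).
#' @return [read_movie()] returns a [ca_movie()]; [write_movie()] returns
#'   `path` invisibly.
#' @export
read_movie <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("movie file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path, " (",
                                             conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent page shapes in ", path)
  arr <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  if (min(arr) < 0) stop("negative intensities in ", path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  meta[names(metadata)] <- metadata
  ca_movie(arr,
           frame_rate = meta$frame_rate %||% 5,
           stimulus_onset_frame = meta$stimulus_onset_frame %||% 15,
           stimulus_duration_frames = meta$stimulus_duration_frames %||% 5,
           structure_label = meta$structure_label %||% "AL",
           bee_id = meta$bee_id %||% NA_character_,
           stimulus_id = meta$stimulus_id %||% NA_character_,
           presentation_index = meta$presentation_index %||% NA_integer_)
}

#' @rdname read_movie
#' @param movie a [ca_movie()].
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie$pixels)
  # 16-bit storage: k/65535 rounds back to k exactly on read
  pages <- lapply(seq_len(d[3]), function(k)
    matrix(movie$pixels[, , k], d[1], d[2]) / 65535)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                 error = function(e) stop("cannot write TIFF at ", path, " (",
                                          conditionMessage(e), ")"))
  meta <- movie_metadata(movie)
  meta <- meta[!vapply(meta, function(v) length(v) == 1L && is.na(v), TRUE)]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Region masks
#'
#' Boolean inclusion masks delimiting the imaged structure. Masks are stored
#' as single-channel 8-bit PNG files with 0 = excluded and 255 = included;
#' any intermediate gray value is rejected.
#'
#' @param include logical matrix (`TRUE` = pixel belongs to the structure).
#' @param label structure name.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(include, label = "AL") {
  if (!is.matrix(include) || !is.logical(include))
    stop("mask must be a logical matrix")
  if (anyNA(include)) stop("mask may not contain missing values")
  if (!any(include)) stop("mask must include at least one pixel")
  structure(list(include = include, label = label), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("Mask [", x$label, "]: ", nrow(x$include), "x", ncol(x$include),
      " px, ", sum(x$include), " included\n", sep = "")
  invisible(x)
}

#' @rdname roi_mask
#' @param path PNG file path.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L) stop("mask PNG must be single-channel")
    img <- img[, , 1]
  }
  vals <- round(img * 255)
  if (max(abs(img * 255 - vals)) > 1e-6 || !all(vals %in% c(0, 255))) {
    n_bad <- sum(!(vals %in% c(0, 255)) | abs(img * 255 - vals) > 1e-6)
    stop("mask PNG contains ", n_bad, " pixel(s) that are neither 0 nor 255")
  }
  lab <- sub("\\.png$", "", basename(path))
  roi_mask(vals == 255, label = lab)
}

#' @rdname roi_mask
#' @param mask a `roi_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  png::writePNG(ifelse(mask$include, 1, 0), path)
  invisible(path)
}

mask_conformable <- function(mask, dims) {
  if (!identical(dim(mask$include), dims[1:2]))
    stop("mask shape ", nrow(mask$include), "x", ncol(mask$include),
         " does not match image ", dims[1], "x", dims[2])
  invisible(TRUE)
}
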