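#' Relative fluorescence change (delta F / F)
#'
#' Converts a raw movie to \eqn{\Delta F/F = (F - F_0)/F_0} in percent, where
#' \eqn{F_0} is each pixel's mean over the baseline frames — by default the
#' 3 frames just before odor onset (frames 9-11 for onset at frame 15).
#'
#' @param movie a [ca_movie()].
#' @param baseline_frames 1-based inclusive frame range used as \eqn{F_0}.
#' @return An object of class `dff_movie`: list with `values`
#'   (height x width x n_frames array, in %), `baseline_frames`,
#'   `processing_flags`, and the movie metadata.
#' @examples
#' m <- ca_movie(array(100L, c(4, 4, 100)))
#' d <- compute_dff(m)
#' range(d$values)  # 0 0
#' @export
compute_dff <- function(movie, baseline_frames = c(9, 11)) {
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie$pixels)
  bl <- frame_range(baseline_frames, d[3], "baseline range")
  if (max(bl) >= movie$stimulus_onset_frame)
    stop("baseline frames must end before stimulus onset (frame ",
         movie$stimulus_onset_frame, ")")
  mat <- matrix(movie$pixels, d[1] * d[2], d[3])
  f0 <- rowMeans(mat[, bl, drop = FALSE])
  n_bad <- sum(f0 <= 0)
  if (n_bad > 0)
    stop("degenerate baseline: ", n_bad, " pixel(s) with F0 <= 0")
  vals <- array(100 * (mat - f0) / f0, d)
  structure(c(list(values = vals, baseline_frames = range(bl),
                   processing_flags = character(0)),
              movie_metadata(movie)),
            class = "dff_movie")
}

#' @export
print.dff_movie <- function(x, ...) {
  d <- dim(x$values)
  cat("dF/F movie: ", d[1], "x", d[2], " px, ", d[3], " frames [",
      x$structure_label, "]; baseline frames ", x$baseline_frames[1], "-",
      x$baseline_frames[2], "\n  flags: ",
      if (length(x$processing_flags)) paste(x$processing_flags, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Illumination and bleaching correction
#'
#' Removes frame-wide multiplicative artefacts (lamp fluctuations,
#' photobleaching) by subtracting the median pixel value of each frame from
#' every pixel of that frame. The median is taken over the full frame, not
#' the mask, since the correction precedes masking. After correction every
#' frame has median exactly 0; the operation is idempotent, and applying it
#' twice raises a warning because it indicates pipeline misuse.
#'
#' @param dff a `dff_movie` from [compute_dff()].
#' @return The corrected `dff_movie` with flag `illumination_corrected`.
#' @export
correct_illumination <- function(dff) {
  stopifnot(inherits(dff, "dff_movie"))
  if ("illumination_corrected" %in% dff$processing_flags)
    warning("illumination correction already applied; applying again is a no-op")
  d <- dim(dff$values)
  mat <- matrix(dff$values, d[1] * d[2], d[3])
  meds <- apply(mat, 2L, median)
  dff$values <- array(sweep(mat, 2L, meds, `-`), d)
  dff$processing_flags <- union(dff$processing_flags, "illumination_corrected")
  dff
}

# reflection-boundary 1D Gaussian convolution matrix (half-sample reflection:
# ... c b a | a b c ... ), memoised per (n, window, sigma)
conv_cache <- new.env(parent = emptyenv())
gauss_conv_matrix <- function(n, window, sigma) {
  key <- paste(n, window, signif(sigma, 12), sep = "_")
  if (!is.null(conv_cache[[key]])) return(conv_cache[[key]])
  half <- (window - 1L) / 2L
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g <- g / sum(g)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (o in -half:half) {
    j <- i + o
    while (j < 1L || j > n) {
      if (j < 1L) j <- 1L - j
      if (j > n) j <- 2L * n + 1L - j
    }
    M[i, j] <- M[i, j] + g[o + half + 1L]
  }
  conv_cache[[key]] <- M
  M
}

#' Gaussian spatial filtering
#'
#' Convolves each frame with a normalised, truncated 2-D Gaussian kernel of
#' odd window size — 7x7 for antennal lobe recordings, 3x3 for lateral horn
#' and mushroom body (the default when `window` is `NULL`). The Gaussian
#' sigma is `(window - 1)/4`, so the window spans +/- 2 sigma; boundaries are
#' handled by half-sample reflection, which preserves the frame mean on
#' interior-dominated images. `window = 1` is the identity.
#'
#' @param dff a `dff_movie`.
#' @param window odd window size; `NULL` picks 7 for AL and 3 otherwise.
#' @param sigma Gaussian sigma in pixels (default `(window - 1)/4`).
#' @return The filtered `dff_movie` with flag `filtered`.
#' @export
spatial_filter <- function(dff, window = NULL, sigma = NULL) {
  stopifnot(inherits(dff, "dff_movie"))
  if (is.null(window))
    window <- if (identical(dff$structure_label, "AL")) 7L else 3L
  if (window %% 2 == 0 || window < 1)
    stop("filter window must be an odd positive integer")
  window <- as.integer(window)
  if (window == 1L) {
    dff$processing_flags <- union(dff$processing_flags, "filtered")
    return(dff)
  }
  if (is.null(sigma)) sigma <- (window - 1) / 4
  d <- dim(dff$values)
  Mr <- gauss_conv_matrix(d[1], window, sigma)
  Mc <- gauss_conv_matrix(d[2], window, sigma)
  x <- matrix(dff$values, d[1], d[2] * d[3])
  x <- Mr %*% x                                  # along rows
  x <- array(x, d)
  x <- aperm(x, c(2, 1, 3))
  x <- Mc %*% matrix(x, d[2], d[1] * d[3])       # along columns
  dff$values <- aperm(array(x, c(d[2], d[1], d[3])), c(2, 1, 3))
  dff$processing_flags <- union(dff$processing_flags, "filtered")
  dff
}

#' Biphasic response-amplitude map
#'
#' Reduces a \eqn{\Delta F/F} movie to one amplitude per pixel: the mean over
#' the positive window (default frames 19-21, the end of the odor pulse)
#' minus the mean over the negative window (default frames 49-51, the
#' undershoot). This difference captures the full swing of the biphasic
#' signal. Pixels outside the mask are set to `NA` and excluded from every
#' downstream reduction.
#'
#' @param dff a `dff_movie`.
#' @param positive_frames,negative_frames 1-based inclusive frame ranges.
#' @param mask a [roi_mask()] matching the movie shape.
#' @return An object of class `response_map` with elements `amplitude`
#'   (matrix, `NA` outside the mask), `mask` and the recording identifiers.
#' @export
amplitude_map <- function(dff, positive_frames = c(19, 21),
                          negative_frames = c(49, 51), mask) {
  stopifnot(inherits(dff, "dff_movie"), inherits(mask, "roi_mask"))
  d <- dim(dff$values)
  mask_conformable(mask, d)
  pos <- frame_range(positive_frames, d[3], "positive window")
  neg <- frame_range(negative_frames, d[3], "negative window")
  if (length(intersect(pos, neg)))
    stop("positive and negative windows overlap")
  if (min(pos) <= dff$stimulus_onset_frame)
    stop("positive window must start after stimulus onset")
  mat <- matrix(dff$values, d[1] * d[2], d[3])
  amp <- rowMeans(mat[, pos, drop = FALSE]) -
         rowMeans(mat[, neg, drop = FALSE])
  amp <- matrix(amp, d[1], d[2])
  amp[!mask$include] <- NA_real_
  structure(list(amplitude = amp, mask = mask, bee_id = dff$bee_id,
                 stimulus_id = dff$stimulus_id,
                 presentation_index = dff$presentation_index),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat("Response map: ", nrow(x$amplitude), "x", ncol(x$amplitude), " px, ",
      sum(x$mask$include), " in-mask; bee=", x$bee_id, " stimulus=",
      x$stimulus_id, " presentation=",
      x$presentation_index %||% NA, "\n", sep = "")
  cat("  in-mask mean ", round(response_intensity(x), 3), "% dF/F\n", sep = "")
  invisible(x)
}

#' @export
plot.response_map <- function(x, ...) {
  z <- t(x$amplitude[rev(seq_len(nrow(x$amplitude))), ])
  graphics::image(z, axes = FALSE, asp = nrow(x$amplitude) / ncol(x$amplitude),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  invisible(x)
}

#' Mean in-mask response intensity
#'
#' Arithmetic mean of the amplitude over all valid (in-mask) pixels: the
#' scalar response intensity of a recording, in \eqn{\Delta F/F} percent.
#'
#' @param map a `response_map`.
#' @return A scalar.
#' @export
response_intensity <- function(map) {
  stopifnot(inherits(map, "response_map"))
  v <- map$amplitude[map$mask$include]
  if (!length(v)) stop("empty mask")
  mean(v)
}

#' Regional time course
#'
#' Per-frame mean \eqn{\Delta F/F} over a region: either a [roi_mask()] or a
#' rectangle `c(row1, row2, col1, col2)` (1-based, inclusive).
#'
#' @param dff a `dff_movie`.
#' @param region a `roi_mask` or a length-4 integer rectangle.
#' @return An object of class `time_course`: list with `dff` (one value per
#'   frame), `region`, `frame_rate` and identifiers.
#' @export
region_time_course <- function(dff, region) {
  stopifnot(inherits(dff, "dff_movie"))
  d <- dim(dff$values)
  if (inherits(region, "roi_mask")) {
    mask_conformable(region, d)
    sel <- which(region$include)
  } else if (is.numeric(region) && length(region) == 4L) {
    if (region[1] < 1 || region[2] > d[1] || region[3] < 1 || region[4] > d[2]
        || region[1] > region[2] || region[3] > region[4])
      stop("rectangle outside the image")
    m <- matrix(FALSE, d[1], d[2])
    m[region[1]:region[2], region[3]:region[4]] <- TRUE
    sel <- which(m)
  } else stop("region must be a roi_mask or c(row1, row2, col1, col2)")
  if (!length(sel)) stop("empty region")
  mat <- matrix(dff$values, d[1] * d[2], d[3])
  structure(list(dff = colMeans(mat[sel, , drop = FALSE]), region = region,
                 frame_rate = dff$frame_rate, bee_id = dff$bee_id,
                 stimulus_id = dff$stimulus_id),
            class = "time_course")
}

#' @export
plot.time_course <- function(x, ...) {
  t <- seq_along(x$dff) / x$frame_rate
  graphics::plot(t, x$dff, type = "l", xlab = "time (s)",
                 ylab = expression(Delta * F / F ~ "(%)"), ...)
  invisible(x)
}

#' Average response maps over presentations
#'
#' Pixel-wise mean of the maps of one bee and one stimulus across its
#' (typically 2) presentations; the presentation index is cleared.
#'
#' @param maps list of `response_map`s with identical shape and mask.
#' @return A `response_map`.
#' @export
average_presentations <- function(maps) {
  if (!length(maps)) stop("no maps to average")
  lapply(maps, function(m) stopifnot(inherits(m, "response_map")))
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!identical(dim(m$amplitude), dim(ref$amplitude)) ||
        !identical(m$mask$include, ref$mask$include))
      stop("maps have mismatched shapes or masks")
  }
  amp <- Reduce(`+`, lapply(maps, `[[`, "amplitude")) / length(maps)
  structure(list(amplitude = amp, mask = ref$mask, bee_id = ref$bee_id,
                 stimulus_id = ref$stimulus_id, presentation_index = NULL),
            class = "response_map")
}

#' Full movie-to-map processing pipeline
#'
#' Applies the processing stages in their fixed order:
#' [compute_dff()], then [correct_illumination()], then [spatial_filter()],
#' then [amplitude_map()]; also returns the whole-mask time course of the
#' filtered \eqn{\Delta F/F} movie. Stage errors are propagated with the
#' stage name prepended.
#'
#' @param movie a [ca_movie()].
#' @param mask a [roi_mask()].
#' @param config optional list overriding `baseline_frames`, `window`,
#'   `sigma`, `positive_frames`, `negative_frames`.
#' @return A list with elements `map` (a `response_map`) and `time_course`.
#' @export
process_recording <- function(movie, mask, config = list()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  dff <- stage("compute_dff",
               compute_dff(movie, config$baseline_frames %||% c(9, 11)))
  dff <- stage("correct_illumination", correct_illumination(dff))
  dff <- stage("spatial_filter",
               spatial_filter(dff, window = config$window,
                              sigma = config$sigma))
  map <- stage("amplitude_map",
               amplitude_map(dff, config$positive_frames %||% c(19, 21),
                             config$negative_frames %||% c(49, 51), mask))
  tc <- stage("region_time_course", region_time_course(dff, mask))
  list(map = map, time_course = tc)
}
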