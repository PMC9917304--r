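#' Simulated imaging geometry
#'
#' Layout of the simulated field of view. In `"AL"` mode the structure is an
#' ellipse tiled with compact Gaussian blobs standing in for glomeruli,
#' arranged on a hexagonal lattice; in `"LH"`/`"MB"` mode a handful of broad
#' bumps produce the smooth, low-spatial-frequency fields typical of those
#' neuropils at this magnification. The default of 23 blobs is an arbitrary
#' but plausible glomerular count for a wide-field antennal lobe view.
#'
#' Each blob carries fixed chemical tuning: a preferred carbon chain length
#' (laid out as a gradient across the field), a preferred oxygen moiety
#' (C=O vs C-OH) and a preferred subtype within the moiety. Odor-specific
#' activity patterns are deterministic smooth functions of these latent
#' coordinates, so pattern distances mirror chemical distances.
#'
#' @param structure `"AL"`, `"LH"` or `"MB"`.
#' @param height,width frame size in pixels.
#' @param n_blobs number of blobs (default 23 for AL, 6 otherwise).
#' @param blob_radius Gaussian radius of a blob in pixels.
#' @param margin margin between blob centers and the frame border.
#' @return An object of class `blob_geometry` with blob positions, tuning,
#'   and the elliptical [roi_mask()] of the structure.
#' @export
blob_geometry <- function(structure = c("AL", "LH", "MB"), height = 48,
                          width = 64, n_blobs = NULL, blob_radius = NULL,
                          margin = NULL) {
  structure_label <- match.arg(structure)
  if (is.null(n_blobs)) n_blobs <- if (structure_label == "AL") 23L else 6L
  if (is.null(blob_radius)) blob_radius <- if (structure_label == "AL") 2 else 8
  if (is.null(margin)) margin <- round(min(height, width) / 4)
  if (n_blobs < 2) stop("at least 2 blobs are required")
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  a <- width / 2 - margin; b <- height / 2 - margin  # blob-center ellipse
  if (a <= 1 || b <= 1) stop("frame too small for the requested margin")
  # hexagonal lattice, then keep the n_blobs sites closest to the center
  s <- sqrt(pi * a * b / (n_blobs * sqrt(3) / 2))
  for (iter in 1:20) {
    xs <- seq(cx - a, cx + a, by = s)
    ys <- seq(cy - b, cy + b, by = s * sqrt(3) / 2)
    pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
      off <- if (i %% 2 == 0) s / 2 else 0
      cbind(row = ys[i], col = xs + off)
    }))
    inside <- ((pts[, "col"] - cx) / a)^2 + ((pts[, "row"] - cy) / b)^2 <= 1
    pts <- pts[inside, , drop = FALSE]
    if (nrow(pts) >= n_blobs) break
    s <- s * 0.93
  }
  if (nrow(pts) < n_blobs) stop("could not place ", n_blobs, " blobs")
  d2 <- ((pts[, "col"] - cx) / a)^2 + ((pts[, "row"] - cy) / b)^2
  pts <- pts[order(d2)[seq_len(n_blobs)], , drop = FALSE]
  pts <- pts[order(pts[, "col"], pts[, "row"]), , drop = FALSE]
  # chemotopic tuning: chain-length gradient along x, alternating moiety
  # and subtype preferences
  tuning <- data.frame(
    chain = seq(6, 9, length.out = n_blobs),
    moiety = rep_len(c(-1, 1), n_blobs),
    subtype = rep_len(c(-1, -1, 1, 1), n_blobs))
  ma <- width / 2 - 2; mb <- height / 2 - 2                 # mask ellipse
  col_idx <- matrix(rep(seq_len(width), each = height), height, width)
  row_idx <- matrix(rep(seq_len(height), times = width), height, width)
  include <- ((col_idx - cx) / ma)^2 + ((row_idx - cy) / mb)^2 <= 1
  structure(list(structure_label = structure_label, height = height,
                 width = width, positions = pts, tuning = tuning,
                 blob_radius = blob_radius,
                 mask = roi_mask(include, label = structure_label)),
            class = "blob_geometry")
}

#' @export
print.blob_geometry <- function(x, ...) {
  cat("Geometry [", x$structure_label, "]: ", x$height, "x", x$width,
      " px, ", nrow(x$positions), " blobs (radius ", x$blob_radius, ")\n",
      sep = "")
  invisible(x)
}

default_tuning <- function() {
  c(sigma_chain = 1.0, sigma_moiety = 2.0, sigma_subtype = 2.5)
}

blob_weights <- function(odor, geometry, tuning = default_tuning(),
                         jitter_sd = 0) {
  tu <- geometry$tuning
  w <- exp(-0.5 * ((odor$chain_length - tu$chain) / tuning[["sigma_chain"]])^2 -
           0.5 * ((odor$moiety - tu$moiety) / tuning[["sigma_moiety"]])^2 -
           0.5 * ((odor$subtype - tu$subtype) / tuning[["sigma_subtype"]])^2)
  if (jitter_sd > 0) w <- w * exp(rnorm(length(w), 0, jitter_sd))
  w
}

#' Odor-specific spatial activity pattern
#'
#' Builds the nonnegative, unit-Euclidean-norm activity pattern of one odor:
#' a weighted sum of the geometry's Gaussian blobs (truncated at three radii),
#' zero outside the structure mask, and normalised so the sum of squared
#' in-mask weights equals 1. Blob weights are a deterministic smooth function
#' of the odor's chemical coordinates (chain length, functional group), so
#' two odors with identical coordinates and no jitter yield identical
#' patterns, and C6 vs C9 patterns lie farther apart than C6 vs C7.
#' Multiplicative log-normal jitter on the blob weights models bee-to-bee
#' (or presentation-to-presentation) variability.
#'
#' Control stimuli (`is_control = TRUE`) receive a flat in-mask pattern; they
#' are simulated with amplitude ~0, so their pattern never matters.
#'
#' @param odor one stimulus: a single row of an [odor_panel()] (or a list
#'   with `functional_group`, `chain_length`, `is_control`).
#' @param geometry a [blob_geometry()]; defaults to the structure's default.
#' @param structure structure label used when `geometry` is `NULL`.
#' @param jitter_sd standard deviation of the log-normal blob-weight jitter.
#' @param seed optional seed for the jitter draw.
#' @param tuning named vector of tuning widths (`sigma_chain`,
#'   `sigma_moiety`, `sigma_subtype`).
#' @return A `height x width` matrix with unit Euclidean norm inside the
#'   mask, with the geometry attached as attribute `"geometry"`.
#' @export
spatial_pattern <- function(odor, geometry = NULL, structure = "AL",
                            jitter_sd = 0, seed = NULL,
                            tuning = default_tuning()) {
  if (inherits(odor, "odor_panel")) {
    if (nrow(odor) != 1L) stop("pass a single stimulus (one panel row)")
    odor <- as.list(as.data.frame(odor))
  }
  if (is.null(geometry)) geometry <- blob_geometry(structure)
  if (geometry$structure_label == "AL" && nrow(geometry$positions) < 2)
    stop("AL geometry requires at least 2 blobs")
  if (!is.null(seed)) set.seed(seed)
  h <- geometry$height; w <- geometry$width
  inc <- geometry$mask$include
  if (isTRUE(odor$is_control)) {
    field <- matrix(0, h, w)
    field[inc] <- 1
  } else {
    if (is.null(odor$chain_length) || is.na(odor$chain_length))
      stop("non-control odor needs a chain length (6-9)")
    lat <- list(chain_length = odor$chain_length,
                moiety = if (odor$functional_group %in% c("aldehyde", "ketone"))
                           1 else -1,
                subtype = if (odor$functional_group %in%
                              c("primary_alcohol", "aldehyde")) -1 else 1)
    wts <- blob_weights(lat, geometry, tuning, jitter_sd)
    field <- pattern_from_weights(wts, geometry)
  }
  field <- normalize_pattern(field, geometry)
  attr(field, "odor") <- odor$name %||% NA_character_
  field
}

# unnormalised field: weighted sum of truncated Gaussian blobs, zero outside
# the structure mask
pattern_from_weights <- function(wts, geometry) {
  h <- geometry$height; w <- geometry$width
  field <- matrix(0, h, w)
  r <- geometry$blob_radius
  half <- ceiling(3 * r)
  prof <- outer((-half:half)^2, (-half:half)^2, "+")
  prof <- exp(-prof / (2 * r^2)) * (sqrt(prof) <= 3 * r)
  for (bidx in seq_len(nrow(geometry$positions))) {
    r0 <- round(geometry$positions[bidx, "row"])
    c0 <- round(geometry$positions[bidx, "col"])
    rr <- max(1, r0 - half):min(h, r0 + half)
    cc <- max(1, c0 - half):min(w, c0 + half)
    field[rr, cc] <- field[rr, cc] +
      wts[bidx] * prof[rr - r0 + half + 1, cc - c0 + half + 1]
  }
  field[!geometry$mask$include] <- 0
  field
}

normalize_pattern <- function(field, geometry) {
  nrm <- sqrt(sum(field[geometry$mask$include]^2))
  if (nrm == 0) stop("degenerate pattern: no in-mask activity")
  field <- field / nrm
  attr(field, "geometry") <- geometry
  field
}

# pairwise Euclidean distances between zero-jitter unit-norm patterns of the
# non-control panel stimuli: the generator's latent odor space
latent_distance_matrix <- function(panel, geometry = NULL,
                                   tuning = default_tuning()) {
  if (is.null(geometry)) geometry <- blob_geometry("AL")
  odors <- panel[!panel$is_control, , drop = FALSE]
  pats <- lapply(seq_len(nrow(odors)), function(i)
    spatial_pattern(odors[i, ], geometry = geometry, tuning = tuning))
  n <- length(pats)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- sqrt(sum((pats[[i]] - pats[[j]])^2))
  dist_matrix(m, labels = odors$name, provenance = "latent")
}
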