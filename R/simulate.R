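#' Simulate one fluorescence movie
#'
#' Forward model of a recording. Each pixel follows
#' \deqn{F(x,y,t) = B(x,y)\,(1-\beta)^{t-1}\,
#'   \bigl(1 + \tfrac{A}{100}\,P(x,y)\,k(t)\bigr)\,(1 + \eta_t) +
#'   \varepsilon_{x,y,t}}
#' with baseline map \eqn{B}, per-frame bleach fraction \eqn{\beta},
#' amplitude \eqn{A} (\eqn{\Delta F/F} %), spatial pattern \eqn{P}, biphasic
#' kernel \eqn{k}, frame-level illumination jitter \eqn{\eta_t \sim N(0,
#' \sigma_i^2)} and pixel noise \eqn{\varepsilon \sim N(0, \sigma_p^2)}
#' (counts). The result is clipped to the 12-bit range and quantised to
#' integers, emulating the camera. The model is multiplicative so that in the
#' noiseless, bleach-free limit the \eqn{\Delta F/F} pipeline recovers
#' \eqn{A\,P(x,y)\,k(t)} exactly (up to quantisation).
#'
#' @param pattern spatial pattern matrix (nonnegative).
#' @param amplitude response amplitude \eqn{A} in \eqn{\Delta F/F} percent,
#'   scaled so that `amplitude` is the peak local \eqn{\Delta F/F} when
#'   `max(pattern) == 1`.
#' @param kernel a [biphasic_kernel()].
#' @param baseline mean fluorescence level: a scalar or a
#'   `height x width` matrix of counts (strictly positive).
#' @param bleach_rate per-frame bleached fraction \eqn{\beta}.
#' @param illumination_sd SD of the frame-level multiplicative jitter.
#' @param pixel_noise_sd SD of additive pixel noise, in counts.
#' @param seed optional seed.
#' @param structure_label,bee_id,stimulus_id,presentation_index metadata
#'   passed to [ca_movie()].
#' @return A [ca_movie()].
#' @export
simulate_movie <- function(pattern, amplitude, kernel = biphasic_kernel(),
                           baseline = 1000, bleach_rate = 0,
                           illumination_sd = 0, pixel_noise_sd = 0,
                           seed = NULL, structure_label = "AL",
                           bee_id = NA_character_, stimulus_id = NA_character_,
                           presentation_index = NA_integer_) {
  stopifnot(is.matrix(pattern), inherits(kernel, "biphasic_kernel"))
  if (!is.null(seed)) set.seed(seed)
  h <- nrow(pattern); w <- ncol(pattern); f <- kernel$n_frames
  if (is.matrix(baseline)) {
    if (!identical(dim(baseline), dim(pattern)))
      stop("baseline map shape does not match pattern")
  } else baseline <- matrix(baseline, h, w)
  if (min(baseline) <= 0) stop("baseline must be strictly positive")
  resp <- 1 + (amplitude / 100) * outer(as.vector(pattern), kernel$values)
  if (min(resp) < 0)
    stop("amplitude drives pre-clip fluorescence negative ",
         "(min response factor ", format(min(resp)), ")")
  gain <- (1 - bleach_rate)^(seq_len(f) - 1)
  if (illumination_sd > 0) gain <- gain * (1 + rnorm(f, 0, illumination_sd))
  m <- as.vector(baseline) * resp
  m <- sweep(m, 2L, gain, `*`)
  if (pixel_noise_sd > 0) m <- m + rnorm(length(m), 0, pixel_noise_sd)
  m <- round(pmin(pmax(m, 0), 4095))
  arr <- array(m, c(h, w, f))
  storage.mode(arr) <- "integer"
  ca_movie(arr, frame_rate = 5, stimulus_onset_frame = kernel$onset_frame,
           stimulus_duration_frames = 5, structure_label = structure_label,
           bee_id = bee_id, stimulus_id = stimulus_id,
           presentation_index = presentation_index)
}

default_amplitude_model <- function() c(intercept = 6, slope = 2)

# expected pipeline readout factor per unit amplitude: window-mean of
# kernel x deterministic bleach gain (relative to the baseline frames)
effective_contrast <- function(kernel, bleach_rate = 0,
                               baseline_frames = c(9, 11),
                               positive_frames = c(19, 21),
                               negative_frames = c(49, 51)) {
  f <- kernel$n_frames
  gain <- (1 - bleach_rate)^(seq_len(f) - 1)
  gain <- gain / mean(gain[frame_range(baseline_frames, f)])
  pos <- frame_range(positive_frames, f)
  neg <- frame_range(negative_frames, f)
  mean(gain[pos] * kernel$values[pos]) - mean(gain[neg] * kernel$values[neg])
}

# core cohort loop: draws bee-level and presentation-level pattern jitter,
# computes ground truth, and hands every simulated movie to `sink`
cohort_core <- function(panel, n_bees, structure, geometry, amplitude_model,
                        kernel, bee_jitter_sd, presentation_jitter_sd,
                        baseline, bleach_rate, illumination_sd, pixel_noise_sd,
                        seed, tuning, sink, store_patterns = FALSE) {
  if (n_bees < 2) stop("n_bees must be >= 2 (paired statistics downstream)")
  if (is.null(geometry)) geometry <- blob_geometry(structure)
  set.seed(seed)
  contrast <- effective_contrast(kernel, bleach_rate)
  inc <- geometry$mask$include
  odors <- odor_latent(panel)
  amp_true <- ifelse(panel$is_control, 0,
                     amplitude_model[["intercept"]] +
                     amplitude_model[["slope"]] * log10(panel$vapor_pressure))
  if (any(amp_true < 0))
    stop("amplitude model gives negative amplitudes; adjust intercept/slope")
  base_w <- lapply(seq_len(nrow(panel)), function(i) {
    if (panel$is_control[i]) return(NULL)
    blob_weights(list(chain_length = odors$chain[i], moiety = odors$moiety[i],
                      subtype = odors$subtype[i]),
                 geometry, tuning, jitter_sd = 0)
  })
  n_blobs <- nrow(geometry$positions)
  gt <- list(); patterns <- list()
  bees <- sprintf("bee%02d", seq_len(n_bees))
  for (bi in seq_len(n_bees)) {
    bee_fac <- exp(rnorm(n_blobs, 0, bee_jitter_sd))
    for (si in seq_len(nrow(panel))) {
      stim <- panel$name[si]
      for (pres in 1:2) {
        if (panel$is_control[si]) {
          field <- matrix(0, geometry$height, geometry$width)
          field[inc] <- 1
          pat <- normalize_pattern(field, geometry)
        } else {
          pres_fac <- exp(rnorm(n_blobs, 0, presentation_jitter_sd))
          pat <- normalize_pattern(
            pattern_from_weights(base_w[[si]] * bee_fac * pres_fac, geometry),
            geometry)
        }
        # mean-normalised injection: the amplitude parameter is the expected
        # mask-mean dF/F readout, the unit in which response intensities are
        # reported
        pat_inj <- pat / mean(pat[inc])
        A <- amp_true[si]
        expected <- A * contrast
        movie <- simulate_movie(pat_inj, A, kernel = kernel,
                                baseline = baseline,
                                bleach_rate = bleach_rate,
                                illumination_sd = illumination_sd,
                                pixel_noise_sd = pixel_noise_sd,
                                structure_label = geometry$structure_label,
                                bee_id = bees[bi], stimulus_id = stim,
                                presentation_index = pres)
        info <- data.frame(bee = bees[bi], stimulus = stim,
                           presentation = pres,
                           functional_group = panel$functional_group[si],
                           chain_length = panel$chain_length[si],
                           vapor_pressure = panel$vapor_pressure[si],
                           is_control = panel$is_control[si],
                           amplitude_true = A,
                           expected_intensity = expected,
                           stringsAsFactors = FALSE)
        gt[[length(gt) + 1L]] <- info
        if (store_patterns)
          patterns[[paste(bees[bi], stim, pres, sep = "|")]] <- pat
        sink(movie, info)
      }
    }
  }
  out <- list(ground_truth = do.call(rbind, gt), geometry = geometry,
              kernel = kernel, panel = panel,
              params = list(n_bees = n_bees, seed = seed,
                            amplitude_model = amplitude_model,
                            bee_jitter_sd = bee_jitter_sd,
                            presentation_jitter_sd = presentation_jitter_sd,
                            baseline = if (is.matrix(baseline)) "map" else baseline,
                            bleach_rate = bleach_rate,
                            illumination_sd = illumination_sd,
                            pixel_noise_sd = pixel_noise_sd))
  if (store_patterns) out$patterns <- patterns
  out
}

#' Generate a synthetic imaging cohort
#'
#' Simulates a full experiment: `n_bees` bees, every panel stimulus presented
#' twice, with odor-specific spatial patterns (bee-level and
#' presentation-level blob-weight jitter), response amplitudes coupled to the
#' logarithm of vapor pressure
#' (\eqn{A = a + b\,\log_{10} VP}; controls get \eqn{A = 0}), multiplicative
#' photobleaching, frame-level illumination jitter and pixel noise. All
#' randomness is driven by `seed`; identical seeds give identical cohorts.
#'
#' With `out_dir = NULL` the movies are returned in memory (fine for a few
#' bees; a 10-bee cohort is ~0.5 GB). With `out_dir` set, each movie is
#' written as a 16-bit multi-page TIFF with a JSON sidecar, together with
#' `mask.png`, `ground_truth.csv`, `index.csv` and `params.json`, and only
#' the manifest is returned. For generate-and-process workflows that never
#' need raw movies, use [simulate_cohort_maps()].
#'
#' @param panel an [odor_panel()] (default: the 16 aliphatic odorants + air).
#' @param n_bees number of bees (>= 2).
#' @param structure structure label for the default geometry.
#' @param geometry optional [blob_geometry()].
#' @param amplitude_model named vector `c(intercept=, slope=)` of the
#'   amplitude vs `log10(vapor pressure)` relation, in \eqn{\Delta F/F} %.
#' @param kernel a [biphasic_kernel()].
#' @param bee_jitter_sd,presentation_jitter_sd SD of the log-normal
#'   blob-weight jitter across bees / presentations.
#' @param baseline,bleach_rate,illumination_sd,pixel_noise_sd forwarded to
#'   [simulate_movie()].
#' @param seed integer seed driving all randomness.
#' @param tuning tuning widths, see [spatial_pattern()].
#' @param out_dir optional output directory.
#' @return A list with `ground_truth` (data frame), `geometry`, `kernel`,
#'   `panel`, `params`, and either `movies` (list of [ca_movie()]) or
#'   `dir` + `index` when writing to disk.
#' @export
generate_cohort <- function(panel = aliphatic_panel(), n_bees = 10,
                            structure = "AL", geometry = NULL,
                            amplitude_model = default_amplitude_model(),
                            kernel = biphasic_kernel(),
                            bee_jitter_sd = 0.3,
                            presentation_jitter_sd = 0.05,
                            baseline = 1000, bleach_rate = 0.001,
                            illumination_sd = 0.005, pixel_noise_sd = 3,
                            seed = 1, tuning = default_tuning(),
                            out_dir = NULL) {
  if (is.null(out_dir)) {
    movies <- list()
    collect <- function(movie, info)
      movies[[length(movies) + 1L]] <<- movie
    out <- cohort_core(panel, n_bees, structure, geometry, amplitude_model,
                       kernel, bee_jitter_sd, presentation_jitter_sd,
                       baseline, bleach_rate, illumination_sd, pixel_noise_sd,
                       seed, tuning, collect)
    out$movies <- movies
    return(out)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  index <- list()
  writer <- function(movie, info) {
    fn <- sprintf("%s_%s_p%d.tif", info$bee,
                  gsub("[^A-Za-z0-9]+", "-", info$stimulus),
                  info$presentation)
    write_movie(movie, file.path(out_dir, fn))
    info$file <- fn
    index[[length(index) + 1L]] <<- info
  }
  out <- cohort_core(panel, n_bees, structure, geometry, amplitude_model,
                     kernel, bee_jitter_sd, presentation_jitter_sd,
                     baseline, bleach_rate, illumination_sd, pixel_noise_sd,
                     seed, tuning, writer)
  out$index <- do.call(rbind, index)
  out$dir <- out_dir
  write_mask(out$geometry$mask, file.path(out_dir, "mask.png"))
  write.csv(out$ground_truth, file.path(out_dir, "ground_truth.csv"),
            row.names = FALSE)
  write.csv(out$index, file.path(out_dir, "index.csv"), row.names = FALSE)
  jsonlite::write_json(out$params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Simulate a cohort and process it on the fly
#'
#' Streams [generate_cohort()] through [process_recording()]: each movie is
#' processed to a biphasic response map as soon as it is simulated and then
#' discarded, so arbitrarily large cohorts fit in memory. This is the main
#' entry point for parameter-recovery and structure-recovery experiments.
#'
#' @inheritParams generate_cohort
#' @param config processing configuration passed to [process_recording()].
#' @return A list with `maps` (per-presentation [amplitude_map()] results,
#'   one per row of `ground_truth`), `ground_truth`, `amplitude_table`
#'   (presentation-averaged measured intensities as an [amplitude_table()]),
#'   `geometry`, `kernel`, `panel`, `params`.
#' @export
simulate_cohort_maps <- function(panel = aliphatic_panel(), n_bees = 10,
                                 structure = "AL", geometry = NULL,
                                 amplitude_model = default_amplitude_model(),
                                 kernel = biphasic_kernel(),
                                 bee_jitter_sd = 0.3,
                                 presentation_jitter_sd = 0.05,
                                 baseline = 1000, bleach_rate = 0.001,
                                 illumination_sd = 0.005, pixel_noise_sd = 3,
                                 seed = 1, tuning = default_tuning(),
                                 config = list()) {
  maps <- list()
  if (is.null(geometry)) geometry <- blob_geometry(structure)
  process <- function(movie, info) {
    res <- process_recording(movie, geometry$mask, config)
    maps[[length(maps) + 1L]] <<- res$map
  }
  out <- cohort_core(panel, n_bees, structure, geometry, amplitude_model,
                     kernel, bee_jitter_sd, presentation_jitter_sd,
                     baseline, bleach_rate, illumination_sd, pixel_noise_sd,
                     seed, tuning, process)
  out$maps <- maps
  gt <- out$ground_truth
  gt$measured_intensity <- vapply(maps, response_intensity, numeric(1))
  out$ground_truth <- gt
  mean_int <- tapply(gt$measured_intensity,
                     list(gt$bee, gt$stimulus), mean)
  long <- expand.grid(bee = rownames(mean_int), stimulus = colnames(mean_int),
                      stringsAsFactors = FALSE)
  long$amplitude <- as.vector(mean_int)
  long$structure <- geometry$structure_label
  out$amplitude_table <- amplitude_table(long, panel = out$panel)
  out
}

#' Synthetic behavioral distance matrix
#'
#' Stand-in for inter-odorant distances measured behaviorally (e.g. by
#' generalisation in appetitive conditioning). At `distortion = 0` it equals
#' the generator's latent pattern distance matrix exactly (Mantel r = 1
#' against neural distances from the same latent space); increasing
#' `distortion` adds a seeded symmetric perturbation scaled to the spread of
#' the latent distances, degrading the expected Mantel correlation
#' monotonically.
#'
#' @param panel an [odor_panel()]; controls are dropped.
#' @param distortion nonnegative distortion level.
#' @param seed seed for the perturbation.
#' @param geometry optional [blob_geometry()].
#' @param tuning tuning widths, see [spatial_pattern()].
#' @return A `dist_matrix` with provenance `"behavioral"`.
#' @export
generate_behavior_matrix <- function(panel = aliphatic_panel(),
                                     distortion = 0, seed = 1,
                                     geometry = NULL,
                                     tuning = default_tuning()) {
  if (distortion < 0) stop("distortion must be nonnegative")
  lat <- latent_distance_matrix(panel, geometry, tuning)
  v <- lat$values
  if (distortion > 0) {
    set.seed(seed)
    n <- nrow(v)
    e <- matrix(rnorm(n * n), n, n)
    e <- (e + t(e)) / 2
    diag(e) <- 0
    v <- v + distortion * sd(upper_values(lat)) * e
    v[v < 0] <- 0
    diag(v) <- 0
  }
  dist_matrix(v, labels = lat$labels, provenance = "behavioral")
}
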