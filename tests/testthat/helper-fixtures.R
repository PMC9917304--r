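# shared fixture builders; everything is generated in code at test time

# small movie with an arbitrary frame count (suppresses the 100-frame
# protocol warning, which is itself tested once in test-core-io)
tiny_movie <- function(arr, onset = 2, dur = 1, ...) {
  suppressWarnings(ca_movie(arr, stimulus_onset_frame = onset,
                            stimulus_duration_frames = dur, ...))
}

full_mask <- function(h, w, label = "AL") roi_mask(matrix(TRUE, h, w), label)

make_map <- function(amplitude, mask = NULL, bee = "b1", stim = "s1",
                     pres = 1L) {
  if (is.null(mask)) mask <- full_mask(nrow(amplitude), ncol(amplitude))
  amp <- amplitude
  amp[!mask$include] <- NA_real_
  structure(list(amplitude = amp, mask = mask, bee_id = bee,
                 stimulus_id = stim, presentation_index = pres),
            class = "response_map")
}

rand_map <- function(h, w, mask = NULL, ...) {
  make_map(matrix(rnorm(h * w), h, w), mask = mask, ...)
}

# random symmetric distance matrix from points in a Euclidean space
rand_dist <- function(n, dim = 5, labels = paste0("o", seq_len(n))) {
  pts <- matrix(rnorm(n * dim), n, dim)
  dist_matrix(as.matrix(dist(pts)), labels = labels)
}

# write a wide-format XLSX (bees as rows, odorants as columns) through the
# system python's openpyxl; used for the dual-format import check
write_wide_xlsx <- function(wide_df, path) {
  csv <- tempfile(fileext = ".csv")
  write.csv(wide_df, csv, row.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import csv, sys",
    "from openpyxl import Workbook",
    "wb = Workbook(); ws = wb.active",
    "with open(sys.argv[1]) as fh:",
    "    for row in csv.reader(fh):",
    "        ws.append([float(x) if x.replace('.','',1).replace('-','',1).isdigit() else x for x in row])",
    "wb.save(sys.argv[2])"), script)
  status <- system2("python", c(script, csv, path), stdout = FALSE,
                    stderr = FALSE)
  stopifnot(status == 0L)
  invisible(path)
}

# two-presentation toy cohort of 1x2-pixel maps with hand-checkable values
toy_presentation_maps <- function(values) {
  # values: named list bee -> stim -> list(p1 = c(a, b), p2 = c(a, b))
  maps <- list()
  for (bee in names(values)) for (stim in names(values[[bee]]))
    for (p in 1:2) {
      v <- values[[bee]][[stim]][[p]]
      maps[[length(maps) + 1L]] <- make_map(matrix(v, 1, 2), bee = bee,
                                            stim = stim, pres = p)
    }
  maps
}
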