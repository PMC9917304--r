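#' Biphasic GCaMP6f response kernel
#'
#' Piecewise-exponential template of the biphasic calcium signal seen in
#' wide-field honey bee recordings: a fast fluorescence rise during the odor
#' pulse, a brief peak, then a slow decay into a long-lasting undershoot
#' below baseline that recovers exponentially. The kernel is a unitless
#' per-frame weight vector with the positive peak normalised to +1; the
#' response of a pixel is `amplitude x pattern(x, y) x kernel(frame)`.
#'
#' With default parameters the positive lobe peaks inside frames 19-21 and
#' the trough sits inside frames 49-51, matching the measurement windows of
#' the amplitude extraction (see [amplitude_map()]).
#'
#' @param n_frames number of frames (default 100).
#' @param onset_frame 1-based stimulus onset frame (default 15).
#' @param rise_tau rise time constant in frames.
#' @param peak_frame frame at which the positive lobe reaches 1.
#' @param plateau_frames frames held at the peak value.
#' @param trough_frame frame at which the undershoot is deepest.
#' @param undershoot_depth trough value as a (nonpositive) fraction of the
#'   peak, e.g. -0.4.
#' @param fall_tau time constant of the decay from peak to trough.
#' @param recovery_tau time constant of the recovery after the trough.
#' @return An object of class `biphasic_kernel` with element `values`
#'   (length `n_frames`).
#' @examples
#' k <- biphasic_kernel()
#' which.max(k$values)  # 20
#' which.min(k$values)  # 50
#' @export
biphasic_kernel <- function(n_frames = 100, onset_frame = 15, rise_tau = 2,
                            peak_frame = 20, plateau_frames = 1,
                            trough_frame = 50, undershoot_depth = -0.4,
                            fall_tau = 12, recovery_tau = 40) {
  if (undershoot_depth > 0)
    stop("undershoot_depth must be <= 0 (a fraction of the peak)")
  if (peak_frame <= onset_frame)
    stop("peak_frame must come after onset_frame")
  peak_end <- peak_frame + plateau_frames - 1
  if (trough_frame <= peak_end)
    stop("trough_frame must come after the peak plateau")
  if (trough_frame > n_frames) stop("trough_frame beyond the last frame")
  t <- seq_len(n_frames)
  v <- numeric(n_frames)
  rise <- t >= onset_frame & t <= peak_frame
  v[rise] <- (1 - exp(-(t[rise] - onset_frame) / rise_tau)) /
             (1 - exp(-(peak_frame - onset_frame) / rise_tau))
  v[t > peak_frame & t <= peak_end] <- 1
  fall <- t > peak_end & t <= trough_frame
  v[fall] <- 1 - (1 - undershoot_depth) *
    (1 - exp(-(t[fall] - peak_end) / fall_tau)) /
    (1 - exp(-(trough_frame - peak_end) / fall_tau))
  rec <- t > trough_frame
  v[rec] <- undershoot_depth * exp(-(t[rec] - trough_frame) / recovery_tau)
  # the extraction windows presume the peak shortly after stimulus offset
  if (which.max(v) < onset_frame || which.max(v) > onset_frame + 10)
    stop("kernel peak at frame ", which.max(v),
         " falls outside frames ", onset_frame, "-", onset_frame + 10)
  structure(list(values = v, n_frames = n_frames, onset_frame = onset_frame,
                 rise_frames = peak_frame - onset_frame,
                 peak_plateau_frames = plateau_frames,
                 undershoot_onset_frame = peak_end + 1,
                 trough_frame = trough_frame,
                 undershoot_depth = undershoot_depth,
                 rise_tau = rise_tau, fall_tau = fall_tau,
                 recovery_tau = recovery_tau),
            class = "biphasic_kernel")
}

#' @export
print.biphasic_kernel <- function(x, ...) {
  cat("Biphasic kernel: ", x$n_frames, " frames, onset ", x$onset_frame,
      ", peak ", which.max(x$values), ", trough ", which.min(x$values),
      " (depth ", x$undershoot_depth, ")\n", sep = "")
  invisible(x)
}

#' Kernel contrast of the amplitude-extraction windows
#'
#' Mean kernel weight over the positive window minus the mean over the
#' negative window; the factor linking an injected amplitude to the value the
#' biphasic amplitude map reads out at the pattern peak.
#'
#' @param kernel a [biphasic_kernel()].
#' @param positive_frames,negative_frames 1-based inclusive frame ranges.
#' @return A scalar.
#' @export
kernel_contrast <- function(kernel, positive_frames = c(19, 21),
                            negative_frames = c(49, 51)) {
  stopifnot(inherits(kernel, "biphasic_kernel"))
  pos <- frame_range(positive_frames, kernel$n_frames, "positive window")
  neg <- frame_range(negative_frames, kernel$n_frames, "negative window")
  mean(kernel$values[pos]) - mean(kernel$values[neg])
}
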