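# Cutting a recording into baselines and the six working-memory load
# segments, the >0.5 Hz high-pass, and edge trimming for phase features.

#' Zero-phase high-pass filter
#'
#' Fourth-order Butterworth high-pass applied as its zero-phase
#' (forward-backward) response to every channel: the reflection-padded
#' spectrum is multiplied by the squared magnitude response |H(w)|^2, which
#' removes DC exactly and attenuates slow drifts below the cutoff without
#' any phase distortion.
#'
#' @param recording an [EEGRecording-class].
#' @param cutoff high-pass edge in Hz (default 0.5).
#' @return the filtered [EEGRecording-class].
#' @export
highpass <- function(recording, cutoff = 0.5) {
  fs <- samplingRate(recording)
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bt <- signal::butter(4, cutoff / (fs / 2), type = "high")
  x <- eegData(recording)
  # pad well past the filter's settling time at the cutoff
  npad <- min(round(4 * fs / cutoff), ncol(x) - 1L)
  fp <- .fftPad(t(x), npad)
  w <- 2 * pi * (seq_len(fp$n) - 1) / fp$n
  ew <- exp(-1i * outer(w, 0:4))
  gain <- Mod((ew %*% bt$b) / (ew %*% bt$a)) ^ 2
  y <- Re(stats::mvfft(fp$X * as.vector(gain), inverse = TRUE) / fp$n)
  y <- y[(fp$padL + 1):(fp$padL + fp$norig), , drop = FALSE]
  initialize(recording, data = t(y))
}

#' Cut a recording at its event boundaries
#'
#' Splits the recording into the pre-task baseline, the six load segments
#' (staircase order) and the post-task baseline using the attached event
#' table. Intervals are half-open `[onset, onset + duration)`.
#'
#' @param recording an [EEGRecording-class] whose events contain
#'   `baseline_pre`, `load_1` .. `load_6` and `baseline_post` exactly once
#'   each.
#' @return a [SegmentedRun-class].
#' @export
segmentAcquisition <- function(recording) {
  ev <- eventTable(recording)
  need <- .requiredEventLabels()
  missing <- setdiff(need, ev$label)
  dup <- unique(ev$label[duplicated(ev$label)])
  dup <- intersect(dup, need)
  if (length(missing) || length(dup))
    stop("bad event table; missing: [",
         paste(missing, collapse = ", "), "] duplicated: [",
         paste(dup, collapse = ", "), "]")
  x <- eegData(recording)
  cut <- function(lab) {
    row <- ev[ev$label == lab, ][1, ]
    x[, (row$onset + 1):(row$onset + row$duration), drop = FALSE]
  }
  new("SegmentedRun",
      baselinePre = cut("baseline_pre"),
      baselinePost = cut("baseline_post"),
      loadSegments = lapply(paste0("load_", 1:6), cut),
      fs = samplingRate(recording),
      modality = modalityTag(recording),
      participant = participantId(recording))
}

#' Trim segment edges
#'
#' Removes `round(trim_s * fs)` samples from each end of a segment, the
#' guard against filter/Hilbert edge artifacts applied before phase-based
#' features (200 ms by default).
#'
#' @param segment channels x samples matrix (or samples x k matrix of phase
#'   series; trimming acts on the longer time dimension only when `margin`
#'   says so).
#' @param fs sampling rate (Hz).
#' @param trim_s seconds to drop at each end (default 0.2).
#' @param margin 2 to trim columns (channels x samples layout, default),
#'   1 to trim rows.
#' @return the trimmed matrix (or vector).
#' @export
trimEdges <- function(segment, fs, trim_s = 0.2, margin = 2) {
  k <- round(trim_s * fs)
  vec <- !is.matrix(segment)
  if (vec) segment <- matrix(segment, nrow = 1)
  n <- if (margin == 2) ncol(segment) else nrow(segment)
  if (n <= 2 * k)
    stop("segment too short to trim ", k, " samples from each end")
  idx <- (k + 1):(n - k)
  out <- if (margin == 2) segment[, idx, drop = FALSE]
         else segment[idx, , drop = FALSE]
  if (vec) out[1, ] else out
}
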