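# Per-segment Welch power spectra, decibel baseline normalization and
# band averaging into the five conventional frequency bands.

#' Frequency band tables
#'
#' Two tables are used in the pipeline. `powerBands()` is shared by the
#' power-spectra and phase-connectivity features: theta 4-7, alpha 8-12,
#' beta 13-25, low gamma 26-45, high gamma 55-70 Hz. `cfcBands()` is the
#' cross-frequency table: theta 4-7 and alpha 8-13 Hz as modulating bands,
#' beta 14-30 and low gamma 31-45 Hz as modulated bands. The alpha/beta
#' edges genuinely differ between the two recipes and both tables are kept
#' as stated rather than reconciled.
#'
#' @return data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
powerBands <- function() {
  data.frame(name = c("theta", "alpha", "beta", "lowgamma", "highgamma"),
             lo = c(4, 8, 13, 26, 55),
             hi = c(7, 12, 25, 45, 70))
}

#' @rdname powerBands
#' @export
cfcBands <- function() {
  data.frame(name = c("theta", "alpha", "beta", "lowgamma"),
             lo = c(4, 8, 14, 31),
             hi = c(7, 13, 30, 45))
}

.checkBandTable <- function(bands) {
  stopifnot(all(c("name", "lo", "hi") %in% names(bands)))
  if (any(bands$lo >= bands$hi)) stop("band edges must satisfy lo < hi")
  o <- order(bands$lo)
  if (any(bands$hi[o][-nrow(bands)] > bands$lo[o][-1]))
    stop("bands within a table must not overlap")
  invisible(bands)
}

#' Welch power spectral density
#'
#' Per-channel PSD with 2-second Hann windows at 50% overlap, one-sided,
#' scaled as a density so that the integral over frequency approximates the
#' signal variance.
#'
#' @param segment channels x samples matrix (or a single numeric vector).
#' @param fs sampling rate (Hz).
#' @param windowSec window length in seconds (default 2).
#' @return list with `freq` (Hz) and `psd` (channels x frequency matrix).
#' @export
computePsd <- function(segment, fs, windowSec = 2) {
  if (!is.matrix(segment)) segment <- matrix(segment, nrow = 1)
  L <- round(windowSec * fs)
  if (ncol(segment) < L)
    stop("segment shorter than ", windowSec, " s; cannot estimate the PSD")
  step <- L %/% 2
  starts <- seq(1, ncol(segment) - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  U <- sum(w ^ 2)
  nf <- L %/% 2 + 1
  acc <- matrix(0, nrow(segment), nf)
  for (s in starts) {
    seg <- segment[, s:(s + L - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    X <- stats::mvfft(t(seg) * w)
    acc <- acc + t(Mod(X[seq_len(nf), , drop = FALSE]) ^ 2)
  }
  psd <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  psd <- sweep(psd, 2, dbl, `*`)
  rownames(psd) <- rownames(segment)
  list(freq = (0:(nf - 1)) * fs / L, psd = psd)
}

#' Decibel normalization against baseline
#'
#' `10 * log10(task / baseline)` bin-wise.
#'
#' @param psdTask,psdBaseline matrices (or vectors) on the same frequency
#'   grid; the baseline must be strictly positive everywhere.
#' @return matrix (or vector) of dB values.
#' @export
dbNormalize <- function(psdTask, psdBaseline) {
  if (any(psdBaseline <= 0))
    stop("baseline PSD must be strictly positive at every bin")
  10 * log10(psdTask / psdBaseline)
}

#' Average a dB spectrum into bands
#'
#' Mean of the dB values over the bins with `lo <= f <= hi` (inclusive band
#' edges, bins assigned by center frequency), per band in table order.
#'
#' @param dbSpectrum channels x frequency matrix (or vector) of dB values.
#' @param freq frequency grid (Hz).
#' @param bands band table as from [powerBands()].
#' @return channels x bands matrix (or named vector) of band means.
#' @export
bandAverage <- function(dbSpectrum, freq, bands = powerBands()) {
  .checkBandTable(bands)
  vec <- !is.matrix(dbSpectrum)
  if (vec) dbSpectrum <- matrix(dbSpectrum, nrow = 1)
  stopifnot(ncol(dbSpectrum) == length(freq))
  out <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- freq >= bands$lo[i] & freq <= bands$hi[i]
    if (!any(sel))
      stop("band ", bands$name[i], " covers no frequency bins")
    rowMeans(dbSpectrum[, sel, drop = FALSE])
  }, numeric(nrow(dbSpectrum)))
  out <- matrix(out, nrow = nrow(dbSpectrum),
                dimnames = list(rownames(dbSpectrum), bands$name))
  if (vec) out[1, ] else out
}

# Baseline PSD of a segmented run: mean of the pre- and post-task PSDs.
.baselinePsd <- function(segRun, windowSec = 2) {
  fs <- samplingRate(segRun)
  pre <- computePsd(baselinePre(segRun), fs, windowSec)
  post <- computePsd(baselinePost(segRun), fs, windowSec)
  list(freq = pre$freq, psd = (pre$psd + post$psd) / 2)
}

# Normalized band power per load segment: 6 x channels x bands array.
.runBandPower <- function(segRun, bands = powerBands(), windowSec = 2) {
  fs <- samplingRate(segRun)
  base <- .baselinePsd(segRun, windowSec)
  segs <- loadSegments(segRun)
  out <- array(NA_real_,
               c(6, nrow(base$psd), nrow(bands)),
               dimnames = list(NULL, rownames(base$psd), bands$name))
  for (k in 1:6) {
    p <- computePsd(segs[[k]], fs, windowSec)
    out[k, , ] <- bandAverage(dbNormalize(p$psd, base$psd), p$freq, bands)
  }
  out
}

#' Assemble the per-participant normalized power tensor
#'
#' Builds the task x load x channel x band tensor of baseline-normalized
#' band power (2 x 6 x 64 x 5 with the default montage and band table).
#' The baseline spectrum is the mean of the pre- and post-task baseline
#' PSDs of the same recording.
#'
#' @param visualRun,audiovisualRun [SegmentedRun-class] objects for the two
#'   tasks of one participant.
#' @param bands band table (default [powerBands()]).
#' @return 4-d array task(2) x load(6) x channel x band.
#' @export
assemblePowerTensor <- function(visualRun, audiovisualRun,
                                bands = powerBands()) {
  if (is.null(visualRun) || is.null(audiovisualRun))
    stop("both the visual and audiovisual segmented runs are required")
  v <- .runBandPower(visualRun, bands)
  a <- .runBandPower(audiovisualRun, bands)
  out <- array(NA_real_, c(2, dim(v)),
               dimnames = c(list(c("visual", "audiovisual")),
                            dimnames(v)))
  out[1, , , ] <- v
  out[2, , , ] <- a
  out
}
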