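# Phase-of-power cross-frequency coupling: the synchronization index between
# the phase of a low-frequency oscillation and the phase of the slow
# fluctuation of a high-frequency band's power envelope.

#' Narrowband power envelope
#'
#' Band-pass filters the signal around `fCenter` (3 Hz width, zero-phase
#' least-squares FIR) and returns the power time series
#' `p(t) = Re(z(t))^2 + Im(z(t))^2` of the analytic signal.
#'
#' @param x numeric vector.
#' @param fCenter center frequency (Hz).
#' @param fs sampling rate (Hz).
#' @param width filter width (Hz, default 3).
#' @return non-negative numeric vector, same length as `x`.
#' @export
powerEnvelope <- function(x, fCenter, fs, width = 3) {
  lo <- fCenter - width / 2
  hi <- fCenter + width / 2
  if (lo <= 0 || hi >= fs / 2)
    stop("envelope band ", lo, "-", hi, " Hz outside (0, Nyquist)")
  z <- bandAnalytic(x, lo, hi, fs)
  Mod(z) ^ 2
}

#' The two phase series entering the cross-frequency SI
#'
#' (a) the Hilbert phase of the signal band-passed at the modulating (low)
#' frequency, and (b) the Hilbert phase of the high-frequency power envelope
#' after that envelope is itself band-passed at the low frequency. Exposed
#' so the SI arithmetic can be checked directly against the underlying
#' phase sequences.
#'
#' @param x numeric vector.
#' @param fLow modulating center frequency (Hz).
#' @param fHigh modulated center frequency (Hz).
#' @param fs sampling rate (Hz).
#' @param lowWidth,highWidth filter widths (Hz, default 3).
#' @return list with `phiLow` and `phiUpper` phase series.
#' @export
cfcPhases <- function(x, fLow, fHigh, fs, lowWidth = 3, highWidth = 3) {
  if (!(fLow < fHigh)) stop("fLow must be below fHigh")
  lo <- c(fLow - lowWidth / 2, fLow + lowWidth / 2)
  if (lo[1] <= 0) stop("low band reaches 0 Hz")
  phiLow <- Arg(bandAnalytic(x, lo[1], lo[2], fs))
  p <- powerEnvelope(x, fHigh, fs, highWidth)
  pf <- bandAnalytic(p - mean(p), lo[1], lo[2], fs)
  list(phiLow = phiLow, phiUpper = Arg(pf))
}

#' Cross-frequency coupling synchronization index
#'
#' SI between the low-frequency phase and the phase of the low-frequency
#' fluctuation of the high-frequency power envelope, for one channel and one
#' (fLow, fHigh) grid point. The first and last `trim_s` seconds are
#' discarded before the SI.
#'
#' @inheritParams cfcPhases
#' @param trim_s edge trim in seconds (default 0.2).
#' @return a value in \[0, 1\].
#' @export
cfcSI <- function(x, fLow, fHigh, fs, lowWidth = 3, highWidth = 3,
                  trim_s = 0.2) {
  ph <- cfcPhases(x, fLow, fHigh, fs, lowWidth, highWidth)
  k <- round(trim_s * fs)
  n <- length(ph$phiLow)
  if (n <= 2 * k) stop("segment too short for the edge trim")
  idx <- (k + 1):(n - k)
  phaseSI(ph$phiLow[idx], ph$phiUpper[idx])
}

#' Frequency grids of the four band pairs
#'
#' Modulating centers 5-13 Hz in 2-Hz steps and modulated centers 15-45 Hz
#' in 3-Hz steps (3-Hz filter widths); a grid point belongs to a pair when
#' its centers fall inside the pair's bands from [cfcBands()].
#'
#' @param pair one of `"theta-beta"`, `"theta-lowgamma"`, `"alpha-beta"`,
#'   `"alpha-lowgamma"`.
#' @param lowStep,highStep grid steps in Hz (defaults 2 and 3).
#' @return list with `low` and `high` center-frequency vectors.
#' @export
cfcGrid <- function(pair, lowStep = 2, highStep = 3) {
  parts <- strsplit(pair, "-", fixed = TRUE)[[1]]
  bands <- cfcBands()
  if (length(parts) != 2 || !all(parts %in% bands$name))
    stop("unknown band pair label: ", pair)
  lowBand <- bands[bands$name == parts[1], ]
  highBand <- bands[bands$name == parts[2], ]
  lows <- seq(5, 13, by = lowStep)
  highs <- seq(15, 45, by = highStep)
  list(low = lows[lows >= lowBand$lo & lows <= lowBand$hi],
       high = highs[highs >= highBand$lo & highs <= highBand$hi])
}

#' Labels of the four modulating-modulated band pairs
#' @return character vector of length four.
#' @export
cfcPairLabels <- function() {
  c("theta-beta", "theta-lowgamma", "alpha-beta", "alpha-lowgamma")
}

# Vectorized per-segment CFC for all channels: mean SI over the pair's
# (low, high) grid. segment is channels x samples; returns a named
# per-channel vector.
.segmentCfc <- function(segment, pair, fs, trim_s = 0.2,
                        lowStep = 2, highStep = 3) {
  grid <- cfcGrid(pair, lowStep, highStep)
  x <- t(segment)
  k <- round(trim_s * fs)
  n <- nrow(x)
  if (n <= 2 * k) stop("segment too short for the edge trim")
  idx <- (k + 1):(n - k)
  acc <- numeric(ncol(x))
  cnt <- 0L
  # all filters of the grid; the raw signal (and each power envelope) is
  # padded and Fourier-transformed once and reused across grid points
  bLow <- lapply(grid$low, function(fl)
    designFirLS(fl - 1.5, fl + 1.5, fs))
  names(bLow) <- as.character(grid$low)
  bHigh <- lapply(grid$high, function(fh)
    designFirLS(fh - 1.5, fh + 1.5, fs))
  names(bHigh) <- as.character(grid$high)
  maxTaps <- max(lengths(c(bLow, bHigh)))
  if (n <= maxTaps %/% 2 + 1)
    stop("segment too short for the filter order (", maxTaps - 1, ")")
  fp <- .fftPad(x, maxTaps)
  lowUnit <- lapply(bLow, function(b) {
    z <- .applyBand(fp, b)[idx, , drop = FALSE]
    z / Mod(z)
  })
  maxLowTaps <- max(lengths(bLow))
  for (fh in as.character(grid$high)) {
    zh <- .applyBand(fp, bHigh[[fh]])
    p <- Re(zh) ^ 2 + Im(zh) ^ 2
    p <- sweep(p, 2, colMeans(p))
    fpp <- .fftPad(p, maxLowTaps)
    for (fl in as.character(grid$low)) {
      pz <- .applyBand(fpp, bLow[[fl]])[idx, , drop = FALSE]
      # SI = |mean(exp(i (phiLow - phiUpper)))|^2 via unit phasors
      u <- lowUnit[[fl]] * Conj(pz / Mod(pz))
      m <- colMeans(u)
      acc <- acc + Re(m) ^ 2 + Im(m) ^ 2
      cnt <- cnt + 1L
    }
  }
  out <- acc / cnt
  names(out) <- rownames(segment)
  out
}

#' Per-channel CFC features for one band pair
#'
#' For each load segment of a run, the mean cross-frequency SI per channel
#' over the (modulating, modulated) frequency grid of the labeled pair.
#'
#' @param segRun a [SegmentedRun-class].
#' @param pair band-pair label, see [cfcPairLabels()].
#' @param trim_s edge trim in seconds (default 0.2).
#' @param lowStep,highStep grid steps (Hz).
#' @return 6 x channels matrix (rows = load segments).
#' @export
bandPairCfc <- function(segRun, pair, trim_s = 0.2, lowStep = 2,
                        highStep = 3) {
  fs <- samplingRate(segRun)
  segs <- loadSegments(segRun)
  out <- t(vapply(segs, function(s)
    .segmentCfc(s, pair, fs, trim_s, lowStep, highStep),
    numeric(nrow(segs[[1]]))))
  rownames(out) <- paste0("load_", 1:6)
  out
}
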