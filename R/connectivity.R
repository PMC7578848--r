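# Inter-site phase synchronization: band-pass + Hilbert phase per channel,
# synchronization index per non-neighbor channel pair, reduction to
# per-channel features and ROI-pair summaries.

#' Zero-phase least-squares FIR band-pass
#'
#' Designs a linear-phase least-squares FIR for the band and applies it
#' forward and backward (two-way), so the output has zero phase lag and the
#' squared magnitude response of the design.
#'
#' @param x numeric vector or samples x channels matrix.
#' @param fLo,fHi pass-band edges (Hz).
#' @param fs sampling rate (Hz).
#' @param order even FIR order; default is three cycles of `fLo`
#'   (`3 * floor(fs / fLo)`).
#' @return filtered series, same shape as `x`.
#' @export
firBandpass <- function(x, fLo, fHi, fs, order = NULL) {
  bandAnalytic(x, fLo, fHi, fs, order = order, analytic = FALSE)
}

#' Instantaneous phase of a band-limited signal
#'
#' Phase of the analytic (Hilbert) signal, wrapped to (-pi, pi].
#'
#' @param x numeric vector (band-limited).
#' @return numeric vector of phase values in radians.
#' @export
instantaneousPhase <- function(x) {
  Arg(analyticSignal(x))
}

#' Synchronization index of two phase series
#'
#' The squared modulus of the mean complex phasor of the phase difference:
#' `SI = |mean(exp(1i * (phi2 - phi1)))|^2`. 0 means no phase relation,
#' 1 perfect phase locking. The unsquared mean resultant length is available
#' with `squared = FALSE`; both variants order coupling strengths
#' identically.
#'
#' @param phi1,phi2 phase series in radians, equal length.
#' @param squared return the squared resultant (default) or the plain
#'   resultant length.
#' @return a value in \[0, 1\].
#' @export
phaseSI <- function(phi1, phi2, squared = TRUE) {
  if (length(phi1) != length(phi2))
    stop("phase series must have equal length")
  if (!length(phi1)) stop("empty phase series")
  r <- Mod(mean(exp(1i * (phi2 - phi1))))
  if (squared) r ^ 2 else r
}

# Phase matrix (samples x channels) of a segment in one band: zero-phase
# band-pass, Hilbert phase, then edge trim.
.segmentPhases <- function(segment, fLo, fHi, fs, trim_s = 0.2,
                           order = NULL) {
  z <- bandAnalytic(t(segment), fLo, fHi, fs, order = order)
  phi <- Arg(z)
  trimEdges(phi, fs, trim_s, margin = 1)
}

# SI matrix (channels x channels) from a phase matrix via three real
# cross-products; entry (i, j) is |mean exp(i(phi_j - phi_i))|^2.
.siMatrix <- function(phi, squared = TRUE) {
  n <- nrow(phi)
  C <- cos(phi)
  S <- sin(phi)
  re <- (crossprod(C) + crossprod(S)) / n
  cs <- crossprod(C, S) / n
  im <- cs - t(cs)
  r2 <- re ^ 2 + im ^ 2
  if (squared) r2 else sqrt(r2)
}

#' Pairwise phase connectivity of a segmented run
#'
#' For every load segment (and both baselines) computes the synchronization
#' index between all non-neighbor channel pairs in one band: zero-phase FIR
#' band-pass, Hilbert phase, 200 ms edge trim, squared mean resultant of the
#' phase difference. Neighbor pairs and the diagonal are `NA`.
#'
#' @param segRun a [SegmentedRun-class].
#' @param fLo,fHi band edges (Hz). For the theta band the worked recipe
#'   filters to 4-8 Hz.
#' @param adjacency logical channels x channels neighbor matrix as from
#'   [buildAdjacency()].
#' @param trim_s edge trim in seconds (default 0.2).
#' @param includeBaselines also compute the baseline segments.
#' @return named list of channels x channels SI matrices: `load_1` ..
#'   `load_6` (plus `baseline_pre`, `baseline_post`).
#' @export
pairwiseConnectivity <- function(segRun, fLo, fHi, adjacency,
                                 trim_s = 0.2, includeBaselines = FALSE) {
  fs <- samplingRate(segRun)
  segs <- loadSegments(segRun)
  names(segs) <- paste0("load_", 1:6)
  if (includeBaselines)
    segs <- c(segs, list(baseline_pre = baselinePre(segRun),
                         baseline_post = baselinePost(segRun)))
  lapply(segs, function(seg) {
    phi <- .segmentPhases(seg, fLo, fHi, fs, trim_s)
    si <- .siMatrix(phi)
    dimnames(si) <- list(rownames(seg), rownames(seg))
    si[adjacency] <- NA
    diag(si) <- NA
    si
  })
}

#' Non-neighbor pair values from an SI matrix
#'
#' @param siMatrix channels x channels SI matrix with neighbors masked NA.
#' @return data.frame with `ch1`, `ch2`, `si` for each unordered
#'   non-neighbor pair.
#' @export
pairValues <- function(siMatrix) {
  idx <- which(upper.tri(siMatrix) & !is.na(siMatrix), arr.ind = TRUE)
  data.frame(ch1 = rownames(siMatrix)[idx[, 1]],
             ch2 = colnames(siMatrix)[idx[, 2]],
             si = siMatrix[idx])
}

#' Per-channel connectivity features
#'
#' Reduces the pair SI matrix to one value per channel: the mean SI over all
#' of the channel's non-neighbor partners.
#'
#' @param siMatrix channels x channels SI matrix with neighbors masked NA.
#' @return named numeric vector, one value per channel.
#' @export
channelConnectivityFeatures <- function(siMatrix) {
  rowMeans(siMatrix, na.rm = TRUE)
}

#' ROI-pair connectivity summary
#'
#' Mean SI over non-neighbor pairs whose channels fall into the two named
#' regions of interest (the pair Fp1-Fp2, for instance, contributes to
#' left_frontal-right_frontal). All 10 unordered ROI combinations are
#' reported, within-ROI pairs included.
#'
#' @param siMatrix channels x channels SI matrix with neighbors masked NA.
#' @param roiMap named list of channel sets (default [defaultRoiMap()]).
#' @return named numeric vector of ROI-pair means.
#' @export
roiSummary <- function(siMatrix, roiMap = defaultRoiMap()) {
  chs <- rownames(siMatrix)
  bad <- setdiff(unlist(roiMap), chs)
  if (length(bad))
    stop("ROI channels not in the matrix: ", paste(bad, collapse = ", "))
  rois <- names(roiMap)
  out <- c()
  for (i in seq_along(rois)) {
    for (j in i:length(rois)) {
      a <- roiMap[[i]]
      b <- roiMap[[j]]
      block <- siMatrix[a, b, drop = FALSE]
      if (i == j) block[lower.tri(block, diag = TRUE)] <- NA
      out[paste(rois[i], rois[j], sep = "-")] <- mean(block, na.rm = TRUE)
    }
  }
  out
}

# Per-segment 64-feature rows for one band of one segmented run:
# 6 x channels matrix.
.connectivityRows <- function(segRun, fLo, fHi, adjacency, trim_s = 0.2) {
  si <- pairwiseConnectivity(segRun, fLo, fHi, adjacency, trim_s)
  t(vapply(si, channelConnectivityFeatures,
           numeric(nrow(adjacency))))
}

# Band edges used for connectivity filtering: the worked theta recipe uses
# 4-8 Hz; other bands filter at their table edges.
connectivityFilterBand <- function(bandName, bands = powerBands()) {
  row <- bands[bands$name == bandName, ]
  if (!nrow(row)) stop("unknown band: ", bandName)
  if (bandName == "theta") c(4, 8) else c(row$lo, row$hi)
}
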