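# Synthetic EEG cohorts with the study's design: 18 participants x 2 tasks,
# a 1-min baseline before and after six staircase acquisition segments of
# 21-37 s, 64 channels at 256 Hz. Three effect families can be planted with
# known magnitudes: modality-specific band-power offsets, load-dependent
# fronto-parietal phase coupling, and modality-dependent phase-of-power
# cross-frequency coupling. Parameter recovery on these cohorts is the
# pipeline's acceptance surface.

#' Cohort configuration
#'
#' Builds and validates the parameter set of the synthetic-cohort generator.
#' Defaults emulate the study design: 18 participants, two tasks each,
#' 256 Hz, six load segments drawn uniformly from 21-37 s (rounded to whole
#' seconds), and 60 s baselines before and after.
#'
#' @param nParticipants number of participants (default 18).
#' @param fs sampling rate in Hz (default 256; must be at least 128 so the
#'   70 Hz band edge is resolvable).
#' @param segmentRange range (s) the six segment durations are drawn from.
#' @param baselineDuration baseline length in seconds (pre and post).
#' @param modalityPowerEffect 2 x 5 matrix (rows `visual`, `audiovisual`;
#'   columns the [powerBands()] names) of planted dB offsets of task band
#'   power over baseline. The modality difference of a column is what
#'   modality decoding from power features can recover.
#' @param loadCouplingEffect 2 x 6 matrix (rows `theta`, `alpha`; columns
#'   load segments 1-6) of von Mises concentrations of the planted
#'   fronto-parietal phase coupling. The concentrations are identical in
#'   both tasks and the planted amplitude tracks the task's total in-band
#'   background (including the modality power offset), so the coupling SI
#'   carries load information only.
#' @param cfcEffect named list mapping a band-pair label (see
#'   [cfcPairLabels()]) to `c(visual = , audiovisual = )` modulation depths
#'   in \[0, 1\].
#' @param couplingSnr,cfcSnr amplitude of planted oscillators relative to
#'   the background RMS in their band.
#' @param noiseSd background noise standard deviation (microvolts).
#' @param seed master seed; every recording derives its own stream from it.
#' @return a validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nParticipants = 18,
                         fs = 256,
                         segmentRange = c(21, 37),
                         baselineDuration = 60,
                         modalityPowerEffect = defaultPowerEffect(),
                         loadCouplingEffect = defaultCouplingEffect(),
                         cfcEffect = defaultCfcEffect(),
                         couplingSnr = 1.5,
                         cfcSnr = 1.5,
                         noiseSd = 10,
                         seed = 1L) {
  cfg <- list(nParticipants = as.integer(nParticipants), fs = fs,
              segmentRange = segmentRange,
              baselineDuration = baselineDuration,
              modalityPowerEffect = modalityPowerEffect,
              loadCouplingEffect = loadCouplingEffect,
              cfcEffect = cfcEffect, couplingSnr = couplingSnr,
              cfcSnr = cfcSnr, noiseSd = noiseSd, seed = seed)
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

#' @rdname cohortConfig
#' @export
defaultPowerEffect <- function() {
  m <- rbind(visual = c(3, 2, 1, 0.5, 0.5),
             audiovisual = c(5, 2, 2.5, 0.5, 2))
  colnames(m) <- powerBands()$name
  m
}

#' @rdname cohortConfig
#' @export
defaultCouplingEffect <- function() {
  m <- rbind(theta = c(2.5, 2.0, 1.5, 1.0, 0.6, 0.3),
             alpha = c(2.0, 1.6, 1.2, 0.8, 0.5, 0.25))
  colnames(m) <- paste0("load_", 1:6)
  m
}

#' @rdname cohortConfig
#' @export
defaultCfcEffect <- function() {
  list("theta-beta" = c(visual = 0.2, audiovisual = 0.6))
}

#' @rdname cohortConfig
#' @param config a `CohortConfig`.
#' @export
validateCohortConfig <- function(config) {
  fail <- function(field, why) stop("invalid CohortConfig field '", field,
                                    "': ", why, call. = FALSE)
  if (is.na(config$nParticipants) || config$nParticipants < 1)
    fail("nParticipants", "must be >= 1")
  if (config$fs < 128) fail("fs", "must be >= 128 Hz to resolve 70 Hz")
  if (length(config$segmentRange) != 2 ||
      config$segmentRange[1] > config$segmentRange[2] ||
      config$segmentRange[1] <= 1)
    fail("segmentRange", "must be an increasing pair above 1 s")
  mp <- config$modalityPowerEffect
  if (!is.matrix(mp) || nrow(mp) != 2 ||
      !all(rownames(mp) == c("visual", "audiovisual")))
    fail("modalityPowerEffect", "needs rows visual, audiovisual")
  if (any(mp < 0)) fail("modalityPowerEffect", "offsets must be >= 0 dB")
  lc <- config$loadCouplingEffect
  if (!is.matrix(lc) || ncol(lc) != 6 || any(lc < 0))
    fail("loadCouplingEffect",
         "needs one non-negative concentration per load segment")
  for (pair in names(config$cfcEffect)) {
    d <- config$cfcEffect[[pair]]
    if (!pair %in% cfcPairLabels()) fail("cfcEffect", paste("unknown pair", pair))
    if (!all(c("visual", "audiovisual") %in% names(d)))
      fail("cfcEffect", "each pair needs visual and audiovisual depths")
    if (any(d < 0 | d > 1)) fail("cfcEffect", "depths must lie in [0, 1]")
  }
  if (config$noiseSd <= 0) fail("noiseSd", "must be positive")
  if (config$baselineDuration < 5)
    fail("baselineDuration", "must be at least 5 s")
  invisible(config)
}

#' Plant phase coupling between two channels
#'
#' Adds a band-limited oscillation to both series whose phase difference
#' follows a von Mises distribution with the given concentration (sampled at
#' half-second knots and interpolated). Concentration 0 gives independent
#' phases, `Inf` a constant lag.
#'
#' @param chA,chB numeric vectors of equal length.
#' @param band pass band `c(lo, hi)` in Hz.
#' @param concentration von Mises concentration (>= 0; may be `Inf`).
#' @param fs sampling rate (Hz).
#' @param amplitude oscillation amplitude (microvolts).
#' @param mu mean phase lag (radians).
#' @param seed optional seed for this planting.
#' @return list with `a`, `b` (the augmented series) and `lag` (the planted
#'   per-sample phase-difference sequence, the oracle for the measured SI).
#' @export
plantPhaseCoupling <- function(chA, chB, band, concentration, fs,
                               amplitude = 1, mu = 0, seed = NULL) {
  if (length(chA) != length(chB))
    stop("channel series must have equal length")
  if (concentration < 0) stop("concentration must be >= 0")
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must lie inside (0, Nyquist)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(chA)
  phi <- Arg(.synthAnalyticBand(n, 1L, fs, band[1], band[2])[, 1])
  nknots <- max(2L, ceiling(n / fs / 0.5) + 1L)
  lag <- .interpAngles(rVonMises(nknots, mu, concentration), n)
  list(a = chA + amplitude * cos(phi),
       b = chB + amplitude * cos(phi + lag),
       lag = lag)
}

#' Plant phase-of-power cross-frequency coupling
#'
#' Adds a low-frequency oscillation and a narrowband carrier at the high
#' frequency whose amplitude is `(1 + depth * cos(phi_low))`-modulated by
#' that same low-frequency phase.
#'
#' @param x numeric vector.
#' @param fLow,fHigh modulating and carrier center frequencies (Hz),
#'   `fLow < fHigh < fs/2`.
#' @param depth modulation depth in \[0, 1\].
#' @param fs sampling rate (Hz).
#' @param amplitudeLow,amplitudeHigh component amplitudes (microvolts).
#' @param seed optional seed.
#' @return list with `x` (augmented series, same length), `phiLow` (the
#'   planted low-frequency phase) and `envelope` (the planted carrier
#'   amplitude), the oracles for the measured coupling.
#' @export
plantCfc <- function(x, fLow, fHigh, depth, fs, amplitudeLow = 1,
                     amplitudeHigh = 1, seed = NULL) {
  if (depth < 0 || depth > 1) stop("depth must lie in [0, 1]")
  if (!(fLow < fHigh && fHigh < fs / 2 && fLow > 1.5))
    stop("need 1.5 < fLow < fHigh < Nyquist")
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  phiL <- Arg(.synthAnalyticBand(n, 1L, fs, fLow - 1.5, fLow + 1.5)[, 1])
  phiH <- Arg(.synthAnalyticBand(n, 1L, fs, fHigh - 1, fHigh + 1)[, 1])
  env <- amplitudeHigh * (1 + depth * cos(phiL))
  list(x = x + amplitudeLow * cos(phiL) + env * cos(phiH),
       phiLow = phiL, envelope = env)
}

# ---- cohort generation -------------------------------------------------

# Draw the six whole-second segment durations for one participant.
.segmentDurations <- function(config, pidx) {
  set.seed(.deriveSeed(config$seed, pidx, 99L))
  round(stats::runif(6, config$segmentRange[1], config$segmentRange[2]))
}

#' Generate one synthetic recording
#'
#' @param config a [cohortConfig()].
#' @param participant participant index (1-based).
#' @param modality `"visual"` or `"audiovisual"`.
#' @return list with `recording` (an [EEGRecording-class]) and `truth`
#'   (data.frame of planted effect magnitudes per segment).
#' @export
generateRecording <- function(config, participant,
                              modality = c("visual", "audiovisual")) {
  validateCohortConfig(config)
  modality <- match.arg(modality)
  fs <- config$fs
  chans <- standardChannelNames()
  nch <- length(chans)
  roi <- defaultRoiMap()
  chIdx <- function(set) match(set, chans)

  durs <- .segmentDurations(config, participant)
  midx <- match(modality, c("visual", "audiovisual"))
  set.seed(.deriveSeed(config$seed, participant, midx))

  spanDur <- c(config$baselineDuration, durs, config$baselineDuration)
  spanLab <- .requiredEventLabels()
  bands <- powerBands()
  cfcB <- cfcBands()
  truth <- list()
  spans <- vector("list", length(spanDur))

  for (s in seq_along(spanDur)) {
    n <- round(spanDur[s] * fs)
    gBg <- .backgroundGain(n, fs, config$noiseSd)
    x <- t(.synthNoise(n, nch, gBg))  # channels x samples
    isLoad <- s >= 2 && s <= 7
    seg <- s - 1L
    if (isLoad) {
      # --- band-power offsets: extra band-limited noise scaled so the
      # task/baseline PSD ratio equals the requested dB in expectation
      offs <- config$modalityPowerEffect[modality, ]
      if (any(offs > 0)) {
        fgrid <- (seq_len(n) - 1) / n * fs
        ffold <- pmin(fgrid, fs - fgrid)
        boost <- numeric(n)
        for (b in seq_len(nrow(bands))) {
          o <- offs[bands$name[b]]
          if (is.na(o) || o <= 0) next
          sel <- ffold >= bands$lo[b] & ffold <= bands$hi[b]
          boost[sel] <- sqrt(10 ^ (o / 10) - 1)
          truth[[length(truth) + 1]] <- data.frame(
            participant = participant, modality = modality, segment = seg,
            effect = "power_db", band = bands$name[b], value = o)
        }
        x <- x + t(.synthNoise(n, nch, gBg * boost))
      }
      # per-channel variance the CFC plantings add inside each power band
      # (their low carriers live in the low band of the pair)
      cfcLowVar <- stats::setNames(numeric(nrow(bands)), bands$name)
      for (pair in names(config$cfcEffect)) {
        if (all(config$cfcEffect[[pair]] == 0)) next
        parts <- strsplit(pair, "-", fixed = TRUE)[[1]]
        lowB <- cfcB[cfcB$name == parts[1], ]
        aL <- config$cfcSnr *
          sqrt(2 * backgroundBandPower(n, fs, config$noiseSd,
                                       lowB$lo, lowB$hi))
        ov <- pmax(0, pmin(bands$hi, lowB$hi) - pmax(bands$lo, lowB$lo))
        cfcLowVar <- cfcLowVar + aL ^ 2 / 2 * ov / (lowB$hi - lowB$lo)
      }
      # --- load-dependent fronto-parietal phase coupling
      lc <- config$loadCouplingEffect
      for (b in rownames(lc)) {
        if (all(lc[b, ] == 0)) next
        kappa <- lc[b, seg]
        edges <- bands[bands$name == b, ]
        # amplitude tracks the total non-coupling in-band variance of this
        # task -- background times the modality power offset, plus any CFC
        # carrier in the band -- so the coupling signal-to-noise ratio
        # (hence the SI) is the same in both tasks and only the load
        # profile of the concentrations is recoverable
        offFac <- 1
        if (b %in% colnames(config$modalityPowerEffect))
          offFac <- 10 ^ (config$modalityPowerEffect[modality, b] / 10)
        bandVar <- offFac *
          backgroundBandPower(n, fs, config$noiseSd, edges$lo, edges$hi) +
          cfcLowVar[b]
        amp <- config$couplingSnr * sqrt(2 * bandVar)
        hemis <- list(c("left_frontal", "left_parieto_occipital"),
                      c("right_frontal", "right_parieto_occipital"))
        nknots <- max(2L, ceiling(n / fs / 0.5) + 1L)
        for (h in hemis) {
          phi <- Arg(.synthAnalyticBand(n, 1L, fs, edges$lo, edges$hi)[, 1])
          for (ch in chIdx(roi[[h[1]]])) {
            lag <- .interpAngles(rVonMises(nknots, 0, kappa), n)
            x[ch, ] <- x[ch, ] + amp * cos(phi + lag)
          }
          for (ch in chIdx(roi[[h[2]]])) {
            lag <- .interpAngles(rVonMises(nknots, pi / 3, kappa), n)
            x[ch, ] <- x[ch, ] + amp * cos(phi + lag)
          }
        }
        truth[[length(truth) + 1]] <- data.frame(
          participant = participant, modality = modality, segment = seg,
          effect = "coupling_kappa", band = b, value = kappa)
      }
      # --- modality-dependent cross-frequency coupling, planted per channel
      # with independent phases; carrier power is normalized across depths
      # so only the coupling (not band power) separates the modalities
      for (pair in names(config$cfcEffect)) {
        d <- config$cfcEffect[[pair]][modality]
        if (all(config$cfcEffect[[pair]] == 0)) next
        parts <- strsplit(pair, "-", fixed = TRUE)[[1]]
        lowB <- cfcB[cfcB$name == parts[1], ]
        highB <- cfcB[cfcB$name == parts[2], ]
        fcHigh <- mean(c(highB$lo, highB$hi))
        ampL <- config$cfcSnr *
          sqrt(2 * backgroundBandPower(n, fs, config$noiseSd,
                                       lowB$lo, lowB$hi))
        ampH <- config$cfcSnr *
          sqrt(2 * backgroundBandPower(n, fs, config$noiseSd,
                                       highB$lo, highB$hi))
        zl <- .synthAnalyticBand(n, nch, fs, lowB$lo, lowB$hi)
        zh <- .synthAnalyticBand(n, nch, fs, fcHigh - 1.5, fcHigh + 1.5)
        cphl <- cos(Arg(zl))
        mod <- (1 + d * cphl) / sqrt(1 + d ^ 2 / 2)
        x <- x + t(ampL * cphl + ampH * mod * cos(Arg(zh)))
        truth[[length(truth) + 1]] <- data.frame(
          participant = participant, modality = modality, segment = seg,
          effect = "cfc_depth", band = pair, value = unname(d))
      }
    }
    spans[[s]] <- x
  }

  onsets <- cumsum(c(0, vapply(spans, ncol, integer(1))))
  events <- data.frame(onset = onsets[seq_along(spans)],
                       duration = vapply(spans, ncol, integer(1)),
                       label = spanLab)
  rec <- EEGRecording(do.call(cbind, spans), fs = fs, channelNames = chans,
                      events = events, modality = modality,
                      participant = sprintf("P%02d", participant))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(participant = integer(), modality = character(),
               segment = integer(), effect = character(),
               band = character(), value = numeric())
  list(recording = rec, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' One visual and one audiovisual recording per participant, with the ground
#' truth of every planted effect. For large cohorts consider streaming via
#' [computeCohortFeatures()] instead of materializing all recordings.
#'
#' @param config a [cohortConfig()].
#' @return list with `recordings` (per participant, a list with `visual` and
#'   `audiovisual` [EEGRecording-class]s) and `truth` (data.frame).
#' @export
generateCohort <- function(config = cohortConfig()) {
  validateCohortConfig(config)
  truths <- list()
  recordings <- vector("list", config$nParticipants)
  for (p in seq_len(config$nParticipants)) {
    v <- generateRecording(config, p, "visual")
    a <- generateRecording(config, p, "audiovisual")
    recordings[[p]] <- list(visual = v$recording,
                            audiovisual = a$recording)
    truths[[p]] <- rbind(v$truth, a$truth)
  }
  names(recordings) <- sprintf("P%02d", seq_len(config$nParticipants))
  list(recordings = recordings, truth = do.call(rbind, truths))
}

#' Write a synthetic cohort to disk
#'
#' One EDF plus event sidecar per participant x task, and the ground truth
#' as a tab-separated table.
#'
#' @param config a [cohortConfig()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(config, dir) {
  validateCohortConfig(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truths <- list()
  for (p in seq_len(config$nParticipants)) {
    for (m in c("visual", "audiovisual")) {
      g <- generateRecording(config, p, m)
      base <- file.path(dir, sprintf("P%02d_%s", p, m))
      writeRecording(g$recording, paste0(base, ".edf"),
                     paste0(base, ".events.tsv"))
      truths[[length(truths) + 1]] <- g$truth
    }
  }
  utils::write.table(do.call(rbind, truths),
                     file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
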