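# EDF (16-bit) writing and EDF/BDF (24-bit) reading, with a plain-text
# event sidecar (onset_s, duration_s, label). The environment ships no EDF
# reader for R, so the fixed-layout format is handled directly here.

.padField <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write recording events as a tab-separated sidecar
#'
#' @param recording an [EEGRecording-class].
#' @param path output file.
#' @export
writeEventSidecar <- function(recording, path) {
  ev <- eventTable(recording)
  fs <- samplingRate(recording)
  out <- data.frame(onset_s = ev$onset / fs,
                    duration_s = ev$duration / fs,
                    label = ev$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an event sidecar
#'
#' @param path tab-separated file with columns onset_s, duration_s, label.
#' @param fs sampling rate used to convert seconds to samples.
#' @return data.frame with `onset`, `duration` (samples) and `label`.
#' @export
readEventSidecar <- function(path, fs) {
  if (!file.exists(path)) stop("event file not found: ", path)
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "label")
  if (!all(need %in% names(ev)))
    stop("event sidecar must have columns onset_s, duration_s, label")
  data.frame(onset = as.integer(round(ev$onset_s * fs)),
             duration = as.integer(round(ev$duration_s * fs)),
             label = ev$label)
}

# required event labels for a segmentable acquisition run
.requiredEventLabels <- function() {
  c("baseline_pre", paste0("load_", 1:6), "baseline_post")
}

#' Write a recording to EDF
#'
#' 16-bit EDF with one-second data records. The participant and modality
#' tags are stored in the patient-identification header field. If the
#' recording length is not a whole number of seconds the final record is
#' zero-padded (the event sidecar preserves the true extent).
#'
#' @param recording an [EEGRecording-class].
#' @param path output `.edf` file.
#' @param eventPath optional sidecar path; defaults to `path` with an
#'   `.events.tsv` extension.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, path,
                           eventPath = sub("\\.edf$", ".events.tsv", path)) {
  x <- eegData(recording)
  fs <- samplingRate(recording)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writing requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nch <- nrow(x)
  ns <- ncol(x)
  nrec <- as.integer(ceiling(ns / fs))
  if (nrec * fs > ns)
    x <- cbind(x, matrix(0, nch, nrec * fs - ns))
  pmin <- floor(min(x, -1))
  pmax <- ceiling(max(x, 1))
  dmin <- -32768L
  dmax <- 32767L
  dig <- round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(.padField(s, w), con, nchars = w,
                                 eos = NULL)
  wr("0", 8)
  wr(sprintf("pid=%s modality=%s", participantId(recording),
             modalityTag(recording)), 80)
  wr("eegwmdecode synthetic/export", 80)
  wr("01.01.20", 8)
  wr("00.00.00", 8)
  wr(256 + 256 * nch, 8)
  wr("", 44)
  wr(nrec, 8)
  wr("1", 8)
  wr(nch, 4)
  for (ch in channelNames(recording)) wr(ch, 16)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(pmin, 8)
  for (i in seq_len(nch)) wr(pmax, 8)
  for (i in seq_len(nch)) wr(dmin, 8)
  for (i in seq_len(nch)) wr(dmax, 8)
  for (i in seq_len(nch)) wr("HP:0.0Hz", 80)
  for (i in seq_len(nch)) wr(fs, 8)
  for (i in seq_len(nch)) wr("", 32)
  # data records: per record, all samples of channel 1, then channel 2, ...
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.vector(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  writeEventSidecar(recording, eventPath)
  invisible(path)
}

.readEdfHeader <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- readBin(con, "raw", 8)
  isBdf <- version[1] == as.raw(255)
  verstr <- trimws(rawToChar(if (isBdf) version[-1] else version))
  if ((isBdf && verstr != "BIOSEMI") || (!isBdf && verstr != "0"))
    stop("not an EDF/BDF file")
  patient <- rd(80)
  recid <- rd(80)
  rd(8); rd(8)
  hdrBytes <- as.integer(rd(8))
  reserved <- rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), character(1))
  vapply(seq_len(nch), function(i) rd(80), character(1))
  vapply(seq_len(nch), function(i) rd(8), character(1))
  pmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  vapply(seq_len(nch), function(i) rd(80), character(1))
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), character(1)))
  readBin(con, "raw", 32 * nch)
  list(isBdf = isBdf, version = verstr, patient = patient, recid = recid,
       nrec = nrec, recdur = recdur, nch = nch, labels = labels,
       pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax, spr = spr)
}

# read n 24-bit little-endian signed integers from raw bytes
.int24 <- function(raw) {
  m <- matrix(as.integer(raw), nrow = 3)
  v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
  ifelse(v >= 8388608, v - 16777216, v)
}

#' Read an EDF or BDF recording
#'
#' @param path `.edf` (16-bit) or `.bdf` (24-bit) file.
#' @param eventPath optional event sidecar; when given, events are attached
#'   and the data are truncated to the span the events cover (dropping any
#'   zero padding from whole-second records). All `load_1`..`load_6` and
#'   both baseline labels must be present.
#' @param requireEvents if `TRUE` (default when `eventPath` is given),
#'   missing segment labels raise an error naming them.
#' @return An [EEGRecording-class] with data in microvolts.
#' @export
readRecording <- function(path, eventPath = NULL,
                          requireEvents = !is.null(eventPath)) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .readEdfHeader(con)
  if (!hdr$isBdf && hdr$version != "0")
    stop("not an EDF/BDF file: ", path)
  fs <- hdr$spr[1] / hdr$recdur
  if (any(hdr$spr != hdr$spr[1]))
    stop("channels with heterogeneous sampling rates are not supported")
  bytes <- if (hdr$isBdf) 3L else 2L
  nch <- hdr$nch
  out <- matrix(0, nch, hdr$nrec * hdr$spr[1])
  for (r in seq_len(hdr$nrec)) {
    if (hdr$isBdf) {
      raw <- readBin(con, "raw", bytes * nch * hdr$spr[1])
      vals <- .int24(raw)
    } else {
      vals <- readBin(con, "integer", nch * hdr$spr[1], size = 2,
                      endian = "little")
    }
    rec <- matrix(vals, nrow = hdr$spr[1])
    out[, ((r - 1) * hdr$spr[1] + 1):(r * hdr$spr[1])] <- t(rec)
  }
  scale <- (hdr$pmax - hdr$pmin) / (hdr$dmax - hdr$dmin)
  out <- out * scale + (hdr$pmin - hdr$dmin * scale)
  rownames(out) <- hdr$labels

  participant <- sub(".*pid=(\\S+).*", "\\1", hdr$patient)
  modality <- if (grepl("modality=", hdr$patient))
    sub(".*modality=(\\S+).*", "\\1", hdr$patient) else ""
  if (participant == hdr$patient) participant <- ""

  ev <- data.frame(onset = integer(), duration = integer(),
                   label = character())
  if (!is.null(eventPath)) {
    ev <- readEventSidecar(eventPath, fs)
    if (requireEvents) {
      missing <- setdiff(.requiredEventLabels(), ev$label)
      if (length(missing))
        stop("event file is missing label(s): ",
             paste(missing, collapse = ", "))
    }
    span <- max(ev$onset + ev$duration)
    if (span <= ncol(out)) out <- out[, seq_len(span), drop = FALSE]
  }
  EEGRecording(out, fs = fs, channelNames = hdr$labels, events = ev,
               modality = modality, participant = participant)
}
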