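test_that("EDF write/read roundtrip preserves data within quantization", {
  g <- smallRecording()
  rec <- g$recording
  d <- tempfile("io")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  p <- file.path(d, "r.edf")
  writeRecording(rec, p)
  r2 <- readRecording(p, file.path(d, "r.events.tsv"))
  expect_equal(samplingRate(r2), samplingRate(rec))
  expect_equal(channelNames(r2), channelNames(rec))
  expect_equal(modalityTag(r2), modalityTag(rec))
  expect_equal(participantId(r2), participantId(rec))
  # events restore the true extent (zero padding of the last record is cut)
  expect_equal(dim(eegData(r2)), dim(eegData(rec)))
  err <- max(abs(eegData(r2) - eegData(rec)))
  quant <- diff(range(eegData(rec))) / 65535
  expect_lt(err, 2 * quant)
  expect_equal(eventTable(r2), eventTable(rec))
})

test_that("event sidecar roundtrips onsets, durations and labels", {
  g <- smallRecording()
  rec <- g$recording
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p), add = TRUE)
  writeEventSidecar(rec, p)
  ev <- readEventSidecar(p, samplingRate(rec))
  expect_equal(ev, eventTable(rec))
  expect_error(readEventSidecar(tempfile(), 256), "not found")
  bad <- tempfile(fileext = ".tsv")
  write.table(data.frame(a = 1), bad, sep = "\t", row.names = FALSE)
  on.exit(unlink(bad), add = TRUE)
  expect_error(readEventSidecar(bad, 256), "onset_s")
})

test_that("readRecording names the missing event labels", {
  g <- smallRecording()
  rec <- g$recording
  d <- tempfile("io2")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  p <- file.path(d, "r.edf")
  writeRecording(rec, p)
  ev <- eventTable(rec)
  fs <- samplingRate(rec)
  partial <- data.frame(onset_s = ev$onset / fs,
                        duration_s = ev$duration / fs,
                        label = ev$label)
  partial <- partial[!partial$label %in% c("load_3", "baseline_post"), ]
  pe <- file.path(d, "partial.tsv")
  write.table(partial, pe, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readRecording(p, pe), "load_3")
  expect_error(readRecording(p, pe), "baseline_post")
  # without requireEvents the partial table is attached as-is
  r3 <- readRecording(p, pe, requireEvents = FALSE)
  expect_equal(nrow(eventTable(r3)), nrow(partial))
})

test_that("readRecording rejects files that are not EDF/BDF", {
  p <- tempfile(fileext = ".edf")
  writeBin(as.raw(rep(7, 2000)), p)
  on.exit(unlink(p), add = TRUE)
  expect_error(readRecording(p), "not an EDF/BDF")
  expect_error(readRecording(tempfile()), "not found")
})

test_that("24-bit BDF files are read correctly", {
  # hand-build a minimal single-record BDF: 2 channels, 4 samples/record
  p <- tempfile(fileext = ".bdf")
  on.exit(unlink(p), add = TRUE)
  con <- file(p, "wb")
  pad <- function(s, w) writeChar(formatC(substr(s, 1, w), width = w,
                                          flag = "-"),
                                  con, nchars = w, eos = NULL)
  writeBin(as.raw(255), con)
  pad("BIOSEMI", 7)
  pad("pid=P77 modality=visual", 80)
  pad("test", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(as.character(256 + 256 * 2), 8)
  pad("24BIT", 44)
  pad("1", 8)   # one record
  pad("1", 8)   # of one second
  pad("2", 4)   # two channels
  pad("chA", 16); pad("chB", 16)
  pad("", 80); pad("", 80)
  pad("uV", 8); pad("uV", 8)
  pad("-1000", 8); pad("-1000", 8)
  pad("1000", 8); pad("1000", 8)
  pad("-8388608", 8); pad("-8388608", 8)
  pad("8388607", 8); pad("8388607", 8)
  pad("", 80); pad("", 80)
  pad("4", 8); pad("4", 8)
  pad("", 32); pad("", 32)
  int24 <- function(v) {
    v <- ifelse(v < 0, v + 16777216, v)
    as.raw(c(v %% 256, (v %/% 256) %% 256, v %/% 65536))
  }
  digital <- c(0L, 8388607L, -8388608L, 4194304L,   # chA
               -1L, 1L, 100L, -100L)                # chB
  for (v in digital) writeBin(int24(v), con)
  close(con)

  r <- readRecording(p)
  x <- eegData(r)
  expect_equal(dim(x), c(2, 4))
  expect_equal(participantId(r), "P77")
  expect_equal(modalityTag(r), "visual")
  scale <- 2000 / (8388607 + 8388608)
  expect_equal(x["chA", ], digital[1:4] * scale + (-1000 + 8388608 * scale),
               tolerance = 1e-9, ignore_attr = TRUE)
})
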