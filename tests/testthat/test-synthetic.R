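test_that("cohortConfig validates its fields with named errors", {
  expect_error(cohortConfig(nParticipants = 0), "nParticipants")
  expect_error(cohortConfig(fs = 64), "fs")
  expect_error(cohortConfig(segmentRange = c(9, 6)), "segmentRange")
  expect_error(cohortConfig(noiseSd = 0), "noiseSd")
  expect_error(cohortConfig(modalityPowerEffect = matrix(1, 3, 5)),
               "modalityPowerEffect")
  expect_error(
    cohortConfig(cfcEffect = list("theta-beta" = c(visual = 2,
                                                   audiovisual = 0.5))),
    "cfcEffect")
  expect_error(cohortConfig(cfcEffect = list("nope" = c(visual = 0.1,
                                                        audiovisual = 0.2))),
               "cfcEffect")
})

test_that("generateRecording is deterministic given the seed", {
  cfg <- smallConfig()
  a <- generateRecording(cfg, 1, "visual")
  b <- generateRecording(cfg, 1, "visual")
  expect_identical(eegData(a$recording), eegData(b$recording))
  expect_identical(a$truth, b$truth)
  # different participant or modality gives a different realization
  c1 <- generateRecording(cfg, 2, "visual")
  expect_false(identical(eegData(a$recording), eegData(c1$recording)))
  c2 <- generateRecording(cfg, 1, "audiovisual")
  expect_false(identical(eegData(a$recording), eegData(c2$recording)))
})

test_that("generated recordings have the configured structure", {
  g <- smallRecording()
  rec <- g$recording
  cfg <- smallConfig()
  expect_s4_class(rec, "EEGRecording")
  expect_equal(nrow(eegData(rec)), 64)
  expect_equal(samplingRate(rec), 256)
  ev <- eventTable(rec)
  expect_equal(ev$label,
               c("baseline_pre", paste0("load_", 1:6), "baseline_post"))
  durs <- ev$duration / samplingRate(rec)
  expect_equal(durs[1], cfg$baselineDuration)
  expect_equal(durs[8], cfg$baselineDuration)
  # load segments: whole seconds within the configured range
  expect_true(all(durs[2:7] >= cfg$segmentRange[1] &
                  durs[2:7] <= cfg$segmentRange[2]))
  expect_equal(durs, round(durs))
  # events tile the recording exactly
  expect_equal(ev$onset, cumsum(c(0, ev$duration[-8])))
  expect_equal(sum(ev$duration), ncol(eegData(rec)))
})

test_that("background noise has the configured overall scale", {
  g <- smallRecording()
  sds <- apply(eegData(g$recording), 1, sd)
  # planted effects add variance, so channel SDs sit at or above noiseSd
  expect_true(all(sds > 0.8 * smallConfig()$noiseSd))
  expect_true(all(sds < 3 * smallConfig()$noiseSd))
})

test_that("the truth table lists every planted effect", {
  g <- smallRecording()
  tr <- g$truth
  expect_setequal(unique(tr$effect),
                  c("power_db", "coupling_kappa", "cfc_depth"))
  expect_equal(sort(unique(tr$segment)), 1:6)
  # visual defaults: theta power 3 dB, theta-beta depth 0.2
  expect_equal(unique(tr$value[tr$effect == "power_db" &
                               tr$band == "theta"]), 3)
  expect_equal(unique(tr$value[tr$effect == "cfc_depth"]), 0.2)
  kap <- tr$value[tr$effect == "coupling_kappa" & tr$band == "theta"]
  expect_equal(kap[order(tr$segment[tr$effect == "coupling_kappa" &
                                    tr$band == "theta"])],
               unname(defaultCouplingEffect()["theta", ]))
})

test_that("plantPhaseCoupling produces the requested phase-lag law", {
  fs <- 256
  n <- 20 * fs
  zero <- numeric(n)
  # infinite concentration: constant lag, so the planted pair phase-locks
  pl <- plantPhaseCoupling(zero, zero, c(8, 12), Inf, fs, amplitude = 1,
                           mu = pi / 4, seed = 3)
  expect_equal(unique(round(pl$lag, 10)), pi / 4)
  phiA <- instantaneousPhase(pl$a)
  phiB <- instantaneousPhase(pl$b)
  keep <- 500:(n - 500)
  expect_gt(phaseSI(phiA[keep], phiB[keep]), 0.98)
  # the SI of the planted lag sequence matches the von Mises oracle
  set.seed(5)
  kappa <- 2
  pl2 <- plantPhaseCoupling(zero, zero, c(8, 12), kappa, fs, seed = 9)
  siLag <- Mod(mean(exp(1i * pl2$lag))) ^ 2
  oracle <- (besselI(kappa, 1) / besselI(kappa, 0)) ^ 2
  expect_equal(siLag, oracle, tolerance = 0.15)
  expect_error(plantPhaseCoupling(zero, zero, c(8, 12), -1, fs),
               "concentration")
  expect_error(plantPhaseCoupling(zero, numeric(10), c(8, 12), 1, fs),
               "equal length")
})

test_that("plantCfc modulates the carrier by the low-frequency phase", {
  fs <- 256
  n <- 30 * fs
  pc <- plantCfc(numeric(n), 6, 22, depth = 1, fs, seed = 2)
  expect_length(pc$x, n)
  # envelope law: amplitudeHigh * (1 + depth * cos(phiLow))
  expect_equal(pc$envelope, 1 + cos(pc$phiLow), tolerance = 1e-12)
  # measured coupling on the clean planted signal is strong once the
  # envelope filter is wide enough to pass the fHigh +- fLow sidebands
  expect_gt(cfcSI(pc$x, 6, 22, fs, highWidth = 16), 0.8)
  # depth 0: constant envelope, coupling near the 1/n null level
  pc0 <- plantCfc(numeric(n), 6, 22, depth = 0, fs, seed = 2)
  expect_equal(sd(pc0$envelope), 0)
  # at the study's 3 Hz width the depth-1 SI still clearly dominates
  expect_gt(cfcSI(pc$x, 6, 22, fs), 5 * cfcSI(pc0$x, 6, 22, fs))
  expect_error(plantCfc(numeric(n), 6, 22, depth = 2, fs), "depth")
})

test_that("generateCohort and writeCohort cover every participant x task", {
  cfg <- smallConfig()
  co <- generateCohort(cfg)
  expect_length(co$recordings, 2)
  expect_named(co$recordings[[1]], c("visual", "audiovisual"))
  d <- tempfile("cohort")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  writeCohort(cfg, d)
  files <- list.files(d)
  expect_setequal(
    files,
    c(sprintf("P%02d_%s.edf", rep(1:2, each = 2),
              c("visual", "audiovisual")),
      sprintf("P%02d_%s.events.tsv", rep(1:2, each = 2),
              c("visual", "audiovisual")),
      "ground_truth.tsv"))
  tr <- read.delim(file.path(d, "ground_truth.tsv"))
  expect_setequal(unique(tr$participant), 1:2)
  expect_setequal(unique(tr$modality), c("visual", "audiovisual"))
})
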