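test_that("phaseSI is 1 for identical series and for constant lags", {
  phi <- 2 * pi * 6 / 256 * seq_len(2560)
  phi <- atan2(sin(phi), cos(phi))
  expect_identical(phaseSI(phi, phi), 1)
  expect_equal(phaseSI(phi, phi + 0.7), 1, tolerance = 1e-12)
  expect_equal(phaseSI(phi, phi, squared = FALSE), 1, tolerance = 1e-12)
})

test_that("phaseSI stays in [0, 1] and matches the 1/n null level", {
  set.seed(21)
  n <- 2000
  sis <- replicate(500, phaseSI(runif(n, -pi, pi), runif(n, -pi, pi)))
  expect_true(all(sis >= 0 & sis <= 1))
  # E[SI] = 1/n for independent uniform phases
  expect_equal(mean(sis), 1 / n, tolerance = 0.15)
  expect_error(phaseSI(1:3, 1:4), "equal length")
  expect_error(phaseSI(numeric(), numeric()), "empty")
})

test_that("squared and unsquared SI order couplings identically", {
  set.seed(8)
  n <- 4000
  base <- runif(n, -pi, pi)
  kappas <- c(0.2, 0.5, 1, 2, 4)
  s2 <- u <- numeric(length(kappas))
  for (i in seq_along(kappas)) {
    lag <- eegwmdecode:::rVonMises(n, 0, kappas[i])
    s2[i] <- phaseSI(base, base + lag)
    u[i] <- phaseSI(base, base + lag, squared = FALSE)
  }
  expect_equal(order(s2), order(u))
  expect_equal(s2, u ^ 2, tolerance = 1e-12)
})

test_that(".siMatrix equals the brute-force pairwise SI", {
  set.seed(3)
  phi <- matrix(runif(400 * 5, -pi, pi), 400, 5)
  m <- eegwmdecode:::.siMatrix(phi)
  for (i in 1:5) for (j in 1:5)
    expect_equal(m[i, j], phaseSI(phi[, i], phi[, j]), tolerance = 1e-12)
  mu <- eegwmdecode:::.siMatrix(phi, squared = FALSE)
  expect_equal(mu, sqrt(m), tolerance = 1e-12)
})

test_that("pairwiseConnectivity masks neighbors and recovers coupling", {
  adj <- cachedAdjacency()
  run <- smallSegRun()
  si <- pairwiseConnectivity(run, 4, 8, adj)
  expect_named(si, paste0("load_", 1:6))
  m <- si$load_1
  expect_equal(dim(m), c(64, 64))
  expect_true(all(is.na(diag(m))))
  expect_true(all(is.na(m[adj])))
  offs <- m[!adj & !diag(64)]
  expect_true(all(offs >= 0 & offs <= 1))
  # planted fronto-parietal theta coupling: the left_frontal x
  # left_parieto_occipital block must exceed the overall background
  roi <- defaultRoiMap()
  lf <- roi$left_frontal
  lp <- roi$left_parieto_occipital
  coupled <- mean(m[lf, lp], na.rm = TRUE)
  expect_gt(coupled, 3 * mean(offs, na.rm = TRUE) / 2)
  # ... and the coupling weakens monotonically in load on average
  prof <- vapply(si, function(s) mean(s[lf, lp], na.rm = TRUE), numeric(1))
  expect_lt(prof[6], prof[1])
  si2 <- pairwiseConnectivity(run, 4, 8, adj, includeBaselines = TRUE)
  expect_named(si2, c(paste0("load_", 1:6), "baseline_pre",
                      "baseline_post"))
})

test_that("channel features respond only to their own couplings", {
  # all pair SIs equal c -> every channel feature is c
  m <- matrix(0.25, 6, 6)
  diag(m) <- NA
  expect_equal(unname(channelConnectivityFeatures(m)), rep(0.25, 6))
  # strengthening pair (1, 2) raises features of 1 and 2 only
  m2 <- m
  m2[1, 2] <- m2[2, 1] <- 0.9
  f0 <- channelConnectivityFeatures(m)
  f1 <- channelConnectivityFeatures(m2)
  expect_true(all(f1[1:2] > f0[1:2]))
  expect_equal(f1[3:6], f0[3:6])
})

test_that("roiSummary averages the right blocks", {
  chans <- standardChannelNames()
  m <- matrix(NA_real_, 64, 64, dimnames = list(chans, chans))
  # only the Fp1-Fp2 pair carries a value: it is a left-right frontal pair
  m["Fp1", "Fp2"] <- m["Fp2", "Fp1"] <- 0.5
  s <- roiSummary(m)
  expect_length(s, 10)
  expect_equal(unname(s["left_frontal-right_frontal"]), 0.5)
  expect_true(all(is.nan(s[names(s) != "left_frontal-right_frontal"])))
  expect_error(roiSummary(m[1:10, 1:10]), "not in the matrix")
})

test_that("pairValues lists each unordered non-neighbor pair once", {
  m <- matrix(c(NA, 0.1, 0.2,
                0.1, NA, NA,
                0.2, NA, NA), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  pv <- pairValues(m)
  expect_equal(nrow(pv), 2)
  expect_setequal(pv$si, c(0.1, 0.2))
  expect_false(any(duplicated(paste(pv$ch1, pv$ch2))))
})

test_that("theta connectivity filters at the 4-8 Hz worked recipe", {
  expect_equal(eegwmdecode:::connectivityFilterBand("theta"), c(4, 8))
  expect_equal(eegwmdecode:::connectivityFilterBand("alpha"), c(8, 12))
  expect_error(eegwmdecode:::connectivityFilterBand("nope"), "unknown band")
})
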