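test_that("oneWayAnova matches stats::aov on random data", {
  set.seed(14)
  groups <- list(a = rnorm(40, 0.5, 0.1), b = rnorm(40, 0.52, 0.1),
                 c = rnorm(40, 0.6, 0.1))
  got <- oneWayAnova(groups)
  y <- unlist(groups)
  g <- factor(rep(names(groups), each = 40))
  ref <- summary(stats::aov(y ~ g))[[1]]
  expect_equal(got$SS, ref[["Sum Sq"]], tolerance = 1e-10)
  expect_equal(got$df, ref[["Df"]])
  expect_equal(got$F[1], ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(got$p[1], ref[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(got$partialEtaSq[1],
               got$SS[1] / (got$SS[1] + got$SS[2]))
  expect_error(oneWayAnova(list(a = 1:3)), "two groups")
  expect_error(oneWayAnova(list(a = 1:3, b = 2)), "at least two values")
})

test_that("twoWayAnova matches stats::aov term by term", {
  set.seed(15)
  n <- 50
  bands <- rep(c("theta", "alpha"), each = 2 * n)
  cond <- rep(rep(c("actual", "chance"), each = n), 2)
  vals <- rnorm(4 * n, ifelse(cond == "actual", 0.8, 0.5), 0.05) +
    ifelse(bands == "theta", 0.02, 0)
  got <- twoWayAnova(vals, bands, cond)
  ref <- summary(stats::aov(vals ~ factor(bands) * factor(cond)))[[1]]
  expect_equal(got$term, c("band", "condition", "band:condition", "error"))
  expect_equal(got$SS, ref[["Sum Sq"]], tolerance = 1e-10)
  expect_equal(got$df, ref[["Df"]])
  expect_equal(got$F[1:3], ref[["F value"]][1:3], tolerance = 1e-10)
  ssErr <- got$SS[4]
  expect_equal(got$partialEtaSq[1:3], got$SS[1:3] / (got$SS[1:3] + ssErr))
  expect_error(twoWayAnova(vals[1:10], bands[1:10],
                           rep("actual", 10)), "incomplete")
})

test_that("observedPower follows the noncentral-F convention", {
  # lambda = F * df_effect; checked against direct pf arithmetic
  f <- 3.2
  expect_equal(observedPower(f, 4, 995),
               pf(qf(0.95, 4, 995), 4, 995, ncp = f * 4,
                  lower.tail = FALSE))
  # enormous F: power saturates at 1; F = 0: power equals at most alpha
  expect_equal(observedPower(760, 4, 995), 1, tolerance = 1e-6)
  expect_lt(observedPower(1e-8, 4, 995), 0.06)
  # monotone in F
  p <- vapply(c(0.5, 1, 2, 4, 8), observedPower, numeric(1),
              dfEff = 3, dfErr = 100)
  expect_true(all(diff(p) > 0))
  expect_error(observedPower(1, 0, 10), "degrees of freedom")
})

test_that("renderTables writes the accuracy and ANOVA reports", {
  set.seed(16)
  mk <- function(mu) new("AccuracyDistribution",
                         accuracies = pmin(pmax(rnorm(20, mu, 0.03), 0), 1),
                         cvAccuracies = rep(NA_real_, 20),
                         confusions = array(0L, c(2, 2, 20)),
                         condition = "actual", scheme = "modality",
                         seeds = 1:20)
  results <- list(power = list(
    theta = list(modality = list(actual = mk(0.9), chance = mk(0.5))),
    alpha = list(modality = list(actual = mk(0.7), chance = mk(0.5)))))
  d <- tempfile("report")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  paths <- renderTables(results, d)
  expect_true(all(file.exists(file.path(d, c("accuracy_power.tsv",
                                             "anova_power.tsv")))))
  acc <- read.delim(file.path(d, "accuracy_power.tsv"))
  expect_equal(nrow(acc), 2)
  expect_true(all(c("band", "scheme", "mean", "sd", "chance_mean")
                  %in% names(acc)))
  an <- read.delim(file.path(d, "anova_power.tsv"))
  expect_true(all(c("one_way_bands", "two_way_band_condition")
                  %in% an$analysis))
  # the two-way condition effect dominates by construction
  tw <- an[an$analysis == "two_way_band_condition", ]
  expect_gt(tw$F[tw$term == "condition"], tw$F[tw$term == "band"])
})
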