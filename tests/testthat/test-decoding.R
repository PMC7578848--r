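metaGrid <- function(nPerCell = 3) {
  expand.grid(participant = sprintf("P%02d", seq_len(nPerCell)),
              modality = c("visual", "audiovisual"),
              segment = 1:6, stringsAsFactors = FALSE)
}

test_that("makeTargets maps (modality, segment) to the three schemes", {
  meta <- metaGrid(1)
  four <- makeTargets(meta, "four_class")
  expect_equal(levels(four), c("1", "2", "3", "4"))
  expect_equal(as.integer(as.character(four)),
               ifelse(meta$modality == "visual",
                      ifelse(meta$segment <= 3, 1L, 2L),
                      ifelse(meta$segment <= 3, 3L, 4L)))
  modal <- makeTargets(meta, "modality")
  expect_equal(as.character(modal), meta$modality)
  load <- makeTargets(meta, "load")
  expect_equal(as.character(load),
               ifelse(meta$segment <= 3, "low", "high"))
  expect_error(makeTargets(data.frame(modality = "visual", segment = 7),
                           "load"), "1..6")
  expect_error(makeTargets(data.frame(modality = "audio", segment = 1),
                           "load"), "modality")
})

test_that("splitTrainCvTest produces a stratified 172/22/22 split of 216", {
  labels <- makeTargets(metaGrid(18), "four_class")  # 216 rows, 54 each
  sp <- splitTrainCvTest(labels, seed = 1)
  expect_length(sp$train, 172)
  expect_length(sp$cv, 22)
  expect_length(sp$test, 22)
  all_idx <- c(sp$train, sp$cv, sp$test)
  expect_setequal(all_idx, seq_along(labels))
  expect_equal(anyDuplicated(all_idx), 0L)
  # stratification: test and cv cover every class nearly proportionally
  expect_true(all(table(labels[sp$test]) %in% 5:6))
  expect_true(all(table(labels[sp$cv]) %in% 5:6))
  # reproducible given the seed, different otherwise
  expect_identical(sp, splitTrainCvTest(labels, seed = 1))
  expect_false(identical(sp, splitTrainCvTest(labels, seed = 2)))
  expect_error(splitTrainCvTest(factor(c("a", "b")), 1), "at least 10")
  expect_error(splitTrainCvTest(factor(c(rep("a", 11), "b")), 1),
               "at least 3")
})

test_that("fitEvalSvm separates well-separated classes perfectly", {
  set.seed(13)
  n <- 60
  x <- rbind(matrix(rnorm(n * 4, 0), ncol = 4),
             matrix(rnorm(n * 4, 6), ncol = 4))
  y <- factor(rep(c("a", "b"), each = n))
  idx <- sample(2 * n, 30)
  fit <- fitEvalSvm(x[-idx, ], y[-idx], x[idx, ], y[idx])
  expect_equal(fit$accuracy, 1)
  expect_equal(sum(fit$confusion), 30)
  expect_equal(sum(diag(fit$confusion)), 30)
  expect_true(is.na(fit$cvAccuracy))
  expect_error(fitEvalSvm(x, factor(rep("a", 2 * n)), x, y), "degenerate")
})

test_that("repeatedAccuracy is seed-reproducible with valid distributions", {
  set.seed(2)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- factor(rep(c("u", "v"), 30))
  a1 <- repeatedAccuracy(x, "modality", targets = y, reps = 8, seed = 5)
  a2 <- repeatedAccuracy(x, "modality", targets = y, reps = 8, seed = 5)
  expect_s4_class(a1, "AccuracyDistribution")
  expect_identical(accuracies(a1), accuracies(a2))
  expect_length(accuracies(a1), 8)
  expect_true(all(accuracies(a1) >= 0 & accuracies(a1) <= 1))
  expect_equal(dim(confusions(a1)), c(2, 2, 8))
  # every repetition tests round(0.1 * 60) = 6 rows
  expect_true(all(apply(confusions(a1), 3, sum) == 6))
  expect_error(repeatedAccuracy(x, "modality", reps = 2), "targets")
})

test_that("the permutation chance level sits at the no-information rate", {
  set.seed(3)
  # pure noise features, balanced two-class problem
  x <- matrix(rnorm(120 * 5), 120, 5)
  y <- factor(rep(c("u", "v"), 60))
  ch <- permutationChance(x, "modality", targets = y, reps = 30, seed = 7)
  expect_equal(mean(accuracies(ch)), 0.5, tolerance = 0.12)
  # informative features still yield chance accuracy once labels are
  # shuffled
  xi <- x
  xi[, 1] <- ifelse(y == "u", -3, 3) + rnorm(120, sd = 0.1)
  chi <- permutationChance(xi, "modality", targets = y, reps = 30, seed = 7)
  expect_equal(mean(accuracies(chi)), 0.5, tolerance = 0.12)
  act <- repeatedAccuracy(xi, "modality", targets = y, reps = 10, seed = 7)
  expect_gt(mean(accuracies(act)), 0.95)
})

test_that("confusionGroupingCheck collapses classes exactly", {
  cm <- matrix(c(10, 2, 1, 0,
                 3, 9, 0, 1,
                 0, 1, 8, 4,
                 1, 0, 2, 12), 4, 4, byrow = TRUE,
               dimnames = list(1:4, 1:4))
  grouping <- list(visual = c(1, 2), audiovisual = c(3, 4))
  got <- confusionGroupingCheck(cm, grouping)
  manual <- (10 + 2 + 3 + 9 + 8 + 4 + 2 + 12) / sum(cm)
  expect_equal(got, manual)
  # collapsing never lowers accuracy
  expect_gte(got, sum(diag(cm)) / sum(cm))
  expect_error(confusionGroupingCheck(cm, list(a = 1:2, b = 3)),
               "partition")
})
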