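# Repeated-split Gaussian-kernel SVM classification of the feature matrices,
# with a label-permutation chance distribution. The classifier emulates the
# "medium Gaussian" preset: RBF kernel with kernel scale sqrt(P) for P
# features (libsvm gamma = 1/P), unit box constraint, one-vs-one multiclass,
# features standardized by the training-set mean and standard deviation.

#' Target labels for a scheme
#'
#' `four_class` codes (visual, low) = 1, (visual, high) = 2,
#' (audiovisual, low) = 3, (audiovisual, high) = 4, where load segments 1-3
#' are "low" and 4-6 "high"; `modality` and `load` are the two-class
#' collapses.
#'
#' @param meta data.frame with `modality` and `segment` columns (as from
#'   [obsData()]).
#' @param scheme `"four_class"`, `"modality"` or `"load"`.
#' @return factor of labels, one per row of `meta`.
#' @export
makeTargets <- function(meta, scheme = c("four_class", "modality", "load")) {
  scheme <- match.arg(scheme)
  if (any(!meta$segment %in% 1:6))
    stop("segment indices must lie in 1..6")
  if (any(!meta$modality %in% c("visual", "audiovisual")))
    stop("modality must be visual or audiovisual")
  load <- ifelse(meta$segment <= 3, "low", "high")
  switch(scheme,
    four_class = factor(ifelse(meta$modality == "visual",
                               ifelse(load == "low", 1L, 2L),
                               ifelse(load == "low", 3L, 4L)),
                        levels = 1:4),
    modality = factor(meta$modality, levels = c("visual", "audiovisual")),
    load = factor(load, levels = c("low", "high"))
  )
}

# Largest-remainder allocation of `total` slots over class counts.
.allocate <- function(counts, total) {
  quota <- counts * total / sum(counts)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified 80-10-10 split
#'
#' Randomly divides the observations into training, cross-validation and
#' test folds of 80/10/10% (cv and test sizes are `round(0.1 n)`, training
#' takes the rest, so 216 rows give 172/22/22), stratified by label with
#' largest-remainder per-class allocation.
#'
#' @param labels factor of class labels.
#' @param seed integer seed for this split.
#' @return list with integer index vectors `train`, `cv`, `test`
#'   (disjoint, exhaustive).
#' @export
splitTrainCvTest <- function(labels, seed) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (n < 10) stop("need at least 10 observations for an 80-10-10 split")
  counts <- table(labels)
  if (any(counts < 3))
    stop("every class needs at least 3 members to populate the three folds")
  nTest <- round(0.1 * n)
  nCv <- round(0.1 * n)
  testAlloc <- .allocate(as.numeric(counts), nTest)
  cvAlloc <- .allocate(as.numeric(counts), nCv)
  set.seed(seed)
  test <- integer()
  cv <- integer()
  for (k in seq_along(counts)) {
    rows <- which(labels == names(counts)[k])
    rows <- sample(rows)
    test <- c(test, rows[seq_len(testAlloc[k])])
    cv <- c(cv, rows[testAlloc[k] + seq_len(cvAlloc[k])])
  }
  train <- setdiff(seq_len(n), c(test, cv))
  list(train = sort(train), cv = sort(cv), test = sort(test))
}

#' Fit and evaluate the Gaussian-kernel SVM
#'
#' @param xTrain,yTrain training features (rows = observations) and labels.
#' @param xTest,yTest test fold.
#' @param xCv,yCv optional held-out cross-validation fold; it is only
#'   evaluated, never used for tuning.
#' @return list with `accuracy`, `confusion` (true x predicted counts over
#'   all classes) and `cvAccuracy` (NA when no cv fold is given).
#' @export
fitEvalSvm <- function(xTrain, yTrain, xTest, yTest,
                       xCv = NULL, yCv = NULL) {
  yTrain <- droplevels(as.factor(yTrain))
  if (nlevels(yTrain) < 2)
    stop("training set is degenerate: fewer than 2 classes present")
  mu <- colMeans(xTrain)
  sdv <- apply(xTrain, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  std <- function(m) sweep(sweep(m, 2, mu), 2, sdv, `/`)
  fit <- e1071::svm(std(xTrain), yTrain, kernel = "radial",
                    gamma = 1 / ncol(xTrain), cost = 1, scale = FALSE)
  pred <- predict(fit, std(xTest))
  lev <- levels(as.factor(yTest))
  lev <- union(levels(yTrain), lev)
  confusion <- table(factor(yTest, levels = lev),
                     factor(pred, levels = lev))
  cvAccuracy <- NA_real_
  if (!is.null(xCv) && length(yCv))
    cvAccuracy <- mean(predict(fit, std(xCv)) == yCv)
  list(accuracy = mean(pred == yTest),
       confusion = unclass(confusion),
       cvAccuracy = cvAccuracy)
}

.resolveFeatures <- function(features, targets, scheme) {
  if (is(features, "EEGFeatureSet")) {
    x <- featureValues(features)
    if (is.null(targets)) targets <- makeTargets(obsData(features), scheme)
  } else {
    x <- as.matrix(features)
    if (is.null(targets)) stop("targets are required for a plain matrix")
  }
  if (any(!is.finite(x))) stop("feature matrix contains missing values")
  list(x = x, y = as.factor(targets))
}

.repeatedProtocol <- function(features, scheme, targets, reps, seed,
                              permute) {
  fv <- .resolveFeatures(features, targets, scheme)
  x <- fv$x
  y <- fv$y
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, reps)
  k <- nlevels(y)
  confusions <- array(0L, c(k, k, reps),
                      dimnames = list(levels(y), levels(y), NULL))
  acc <- numeric(reps)
  cvAcc <- numeric(reps)
  for (r in seq_len(reps)) {
    sp <- splitTrainCvTest(y, repSeeds[r])
    yTrain <- y[sp$train]
    yCv <- y[sp$cv]
    if (permute) {
      # chance condition: randomize targets of the train + cv rows only;
      # the test labels stay untouched
      pool <- c(sp$train, sp$cv)
      shuffled <- sample(y[pool])
      yTrain <- shuffled[seq_along(sp$train)]
      yCv <- shuffled[length(sp$train) + seq_along(sp$cv)]
    }
    res <- fitEvalSvm(x[sp$train, , drop = FALSE], yTrain,
                      x[sp$test, , drop = FALSE], y[sp$test],
                      x[sp$cv, , drop = FALSE], yCv)
    acc[r] <- res$accuracy
    cvAcc[r] <- res$cvAccuracy
    confusions[, , r] <- res$confusion
  }
  new("AccuracyDistribution", accuracies = acc, cvAccuracies = cvAcc,
      confusions = confusions,
      condition = if (permute) "chance" else "actual",
      scheme = scheme, seeds = as.integer(repSeeds))
}

#' Repeated-split accuracy distribution
#'
#' Repeats the stratified 80-10-10 split / fit / test-accuracy protocol
#' `reps` times (200 in the study design), each repetition with an
#' independent split derived from the master seed.
#'
#' @param features an [EEGFeatureSet-class] or observations x features
#'   matrix.
#' @param scheme target scheme, see [makeTargets()].
#' @param targets optional explicit label factor (required for a matrix).
#' @param reps number of repetitions (default 200).
#' @param seed master seed governing all repetitions.
#' @return an [AccuracyDistribution-class] with `condition = "actual"`.
#' @export
repeatedAccuracy <- function(features, scheme = "four_class",
                             targets = NULL, reps = 200, seed = 1) {
  .repeatedProtocol(features, scheme, targets, reps, seed, permute = FALSE)
}

#' Label-permutation chance distribution
#'
#' Same protocol as [repeatedAccuracy()] but with the labels of the training
#' and cross-validation rows randomly permuted before each fit, estimating
#' the no-information accuracy level.
#'
#' @inheritParams repeatedAccuracy
#' @return an [AccuracyDistribution-class] with `condition = "chance"`.
#' @export
permutationChance <- function(features, scheme = "four_class",
                              targets = NULL, reps = 200, seed = 1) {
  .repeatedProtocol(features, scheme, targets, reps, seed, permute = TRUE)
}

#' Accuracy after collapsing classes
#'
#' Collapses a four-class confusion matrix by a grouping map (for example
#' classes 1+2 = visual vs 3+4 = audiovisual) and returns the grouped
#' accuracy. Collapsing can only move off-diagonal mass onto the diagonal,
#' so the grouped accuracy is never below the original.
#'
#' @param confusion k x k confusion matrix (true x predicted), or a k x k x
#'   reps array (summed over reps).
#' @param grouping named list mapping group name to class labels, e.g.
#'   `list(visual = c(1, 2), audiovisual = c(3, 4))`.
#' @return grouped accuracy in \[0, 1\].
#' @export
confusionGroupingCheck <- function(confusion, grouping) {
  if (length(dim(confusion)) == 3)
    confusion <- apply(confusion, c(1, 2), sum)
  labs <- rownames(confusion)
  member <- unlist(lapply(grouping, as.character))
  if (anyDuplicated(member) || !setequal(member, labs))
    stop("grouping must partition the class labels ",
         paste(labs, collapse = ", "))
  g <- vapply(labs, function(l)
    names(grouping)[vapply(grouping, function(v) l %in% as.character(v),
                           logical(1))], character(1))
  collapsed <- rowsum(t(rowsum(confusion, g)), g)
  sum(diag(as.matrix(collapsed))) / sum(collapsed)
}
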