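# ANOVA comparison of accuracy distributions with partial eta-squared and
# post-hoc observed power, plus the tabular report rendering.

#' One-way ANOVA on accuracy distributions
#'
#' Standard fixed-effects decomposition across groups (frequency bands):
#' df_effect = k - 1, df_error = N - k, partial eta-squared
#' = SS_effect / (SS_effect + SS_error), observed power from the noncentral
#' F with lambda = F * df_effect.
#'
#' @param groups named list of numeric vectors (one vector per group).
#' @return data.frame with rows `effect` and `error` and columns `SS`, `df`,
#'   `MS`, `F`, `p`, `partialEtaSq`, `power`.
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least two values")
  y <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(y)
  k <- length(groups)
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ssEff <- sum(tapply(y, g, length) * (means - grand) ^ 2)
  ssErr <- sum((y - means[g]) ^ 2)
  dfEff <- k - 1
  dfErr <- N - k
  msEff <- ssEff / dfEff
  msErr <- ssErr / dfErr
  f <- msEff / msErr
  data.frame(
    term = c("effect", "error"),
    SS = c(ssEff, ssErr),
    df = c(dfEff, dfErr),
    MS = c(msEff, msErr),
    F = c(f, NA),
    p = c(stats::pf(f, dfEff, dfErr, lower.tail = FALSE), NA),
    partialEtaSq = c(ssEff / (ssEff + ssErr), NA),
    power = c(observedPower(f, dfEff, dfErr), NA)
  )
}

#' Two-way ANOVA (bands x condition)
#'
#' Crossed fixed-effects ANOVA with interaction, used to compare the actual
#' accuracy distributions against the permutation chance level across
#' frequency bands (5 x 2 for power/connectivity, 4 x 2 for cross-frequency
#' coupling).
#'
#' @param values numeric response (accuracies).
#' @param factorBand,factorCondition factors of equal length.
#' @return data.frame with one row per term (`band`, `condition`,
#'   `band:condition`, `error`) and the same columns as [oneWayAnova()].
#' @export
twoWayAnova <- function(values, factorBand, factorCondition) {
  factorBand <- as.factor(factorBand)
  factorCondition <- as.factor(factorCondition)
  if (nlevels(factorBand) < 2 || nlevels(factorCondition) < 2 ||
      any(table(factorBand, factorCondition) == 0))
    stop("incomplete design: two levels per factor and data in every cell")
  fit <- stats::aov(values ~ factorBand * factorCondition)
  tab <- summary(fit)[[1]]
  ssErr <- tab["Residuals", "Sum Sq"]
  dfErr <- tab["Residuals", "Df"]
  terms <- rownames(tab)
  terms <- trimws(terms)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    isErr <- terms[i] == "Residuals"
    ss <- tab[i, "Sum Sq"]
    dfi <- tab[i, "Df"]
    f <- if (isErr) NA else tab[i, "F value"]
    data.frame(
      term = c(factorBand = "band", factorCondition = "condition",
               `factorBand:factorCondition` = "band:condition",
               Residuals = "error")[terms[i]],
      SS = ss, df = dfi, MS = ss / dfi, F = f,
      p = if (isErr) NA else tab[i, "Pr(>F)"],
      partialEtaSq = if (isErr) NA else ss / (ss + ssErr),
      power = if (isErr) NA else observedPower(f, dfi, dfErr)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Post-hoc observed power
#'
#' Power of the F test at the observed effect size, using the common
#' convention lambda = F * df_effect for the noncentrality parameter.
#'
#' @param F observed F statistic.
#' @param dfEff,dfErr numerator and denominator degrees of freedom.
#' @param alpha test level (default 0.05).
#' @return power in \[0, 1\].
#' @export
observedPower <- function(F, dfEff, dfErr, alpha = 0.05) {
  if (dfEff < 1 || dfErr < 1) stop("degrees of freedom must be >= 1")
  crit <- stats::qf(1 - alpha, dfEff, dfErr)
  stats::pf(crit, dfEff, dfErr, ncp = F * dfEff, lower.tail = FALSE)
}

#' Render the report tables
#'
#' Writes, per feature family, the mean and standard deviation of the
#' accuracy distribution per band and prediction scheme, plus the one-way
#' (across bands) and two-way (bands x actual/chance) ANOVA tables, as
#' tab-separated files.
#'
#' @param results nested list: `results[[family]][[band]][[scheme]]` holds a
#'   list with elements `actual` and `chance`
#'   ([AccuracyDistribution-class]s).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
renderTables <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (family in names(results)) {
    fam <- results[[family]]
    bandNames <- names(fam)
    schemes <- names(fam[[1]])
    rows <- list()
    for (b in bandNames) {
      for (s in schemes) {
        a <- accuracies(fam[[b]][[s]]$actual)
        ch <- fam[[b]][[s]]$chance
        rows[[length(rows) + 1]] <- data.frame(
          band = b, scheme = s,
          mean = round(mean(a), 2), sd = round(stats::sd(a), 2),
          chance_mean = if (!is.null(ch)) round(mean(accuracies(ch)), 2)
                        else NA)
      }
    }
    summary <- do.call(rbind, rows)
    p1 <- file.path(dir, paste0("accuracy_", family, ".tsv"))
    utils::write.table(summary, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p1)

    anovaRows <- list()
    for (s in schemes) {
      groups <- lapply(fam, function(bb) accuracies(bb[[s]]$actual))
      ow <- oneWayAnova(groups)
      ow <- cbind(scheme = s, analysis = "one_way_bands", ow)
      anovaRows[[length(anovaRows) + 1]] <- ow
      haveChance <- all(vapply(fam, function(bb)
        !is.null(bb[[s]]$chance), logical(1)))
      if (haveChance) {
        vals <- unlist(lapply(bandNames, function(b)
          c(accuracies(fam[[b]][[s]]$actual),
            accuracies(fam[[b]][[s]]$chance))))
        nA <- length(accuracies(fam[[1]][[s]]$actual))
        nC <- length(accuracies(fam[[1]][[s]]$chance))
        fb <- rep(bandNames, each = nA + nC)
        fc <- rep(rep(c("actual", "chance"), c(nA, nC)),
                  length(bandNames))
        tw <- twoWayAnova(vals, fb, fc)
        tw <- cbind(scheme = s, analysis = "two_way_band_condition", tw)
        anovaRows[[length(anovaRows) + 1]] <- tw
      }
    }
    p2 <- file.path(dir, paste0("anova_", family, ".tsv"))
    utils::write.table(do.call(rbind, anovaRows), p2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
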