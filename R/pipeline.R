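# End-to-end orchestration: simulate -> features -> decode -> report from a
# single configuration, streaming one participant at a time.

#' Per-recording features
#'
#' Computes the requested feature families for one high-passed, segmented
#' run. Power features use the untrimmed segments; connectivity and CFC trim
#' 200 ms per edge after filtering.
#'
#' @param segRun a [SegmentedRun-class].
#' @param families subset of `c("power", "connectivity", "cfc")`.
#' @param powerBandTable band table for power features.
#' @param connectivityBands character vector of band names (from
#'   `powerBandTable`) to compute connectivity for.
#' @param cfcPairs band-pair labels, see [cfcPairLabels()].
#' @param adjacency neighbor matrix (default: Delaunay on the standard
#'   montage).
#' @param trim_s edge trim (s).
#' @return nested list `out[[family]][[band]]` of 6 x channels matrices.
#' @export
recordingFeatures <- function(segRun,
                              families = c("power", "connectivity", "cfc"),
                              powerBandTable = powerBands(),
                              connectivityBands = powerBands()$name,
                              cfcPairs = cfcPairLabels(),
                              adjacency = NULL,
                              trim_s = 0.2) {
  known <- c("power", "connectivity", "cfc")
  bad <- setdiff(families, known)
  if (length(bad))
    stop("unknown feature family: ", paste(bad, collapse = ", "))
  out <- list()
  if ("power" %in% families) {
    bp <- .runBandPower(segRun, powerBandTable)
    out$power <- lapply(seq_len(nrow(powerBandTable)), function(b)
      bp[, , b])
    names(out$power) <- powerBandTable$name
  }
  if ("connectivity" %in% families) {
    if (is.null(adjacency)) adjacency <- buildAdjacency()
    out$connectivity <- lapply(connectivityBands, function(bn) {
      edges <- connectivityFilterBand(bn, powerBandTable)
      .connectivityRows(segRun, edges[1], edges[2], adjacency, trim_s)
    })
    names(out$connectivity) <- connectivityBands
  }
  if ("cfc" %in% families) {
    out$cfc <- lapply(cfcPairs, function(p) bandPairCfc(segRun, p, trim_s))
    names(out$cfc) <- cfcPairs
  }
  out
}

#' Cohort feature matrices
#'
#' Generates (or re-generates, streaming one participant at a time) the
#' synthetic cohort defined by `config`, applies the 0.5 Hz high-pass and
#' segmentation, and assembles one [EEGFeatureSet-class] per feature family
#' and band: rows = participant x task x load segment (216 for the default
#' cohort), columns = 64 channels.
#'
#' @param config a [cohortConfig()].
#' @inheritParams recordingFeatures
#' @param highpassCutoff high-pass edge (Hz).
#' @param verbose print per-participant progress.
#' @return nested list `out[[family]][[band]]` of [EEGFeatureSet-class]s.
#' @export
computeCohortFeatures <- function(config,
                                  families = c("power", "connectivity",
                                               "cfc"),
                                  powerBandTable = powerBands(),
                                  connectivityBands = powerBands()$name,
                                  cfcPairs = cfcPairLabels(),
                                  adjacency = NULL,
                                  trim_s = 0.2,
                                  highpassCutoff = 0.5,
                                  verbose = FALSE) {
  validateCohortConfig(config)
  if ("connectivity" %in% families && is.null(adjacency))
    adjacency <- buildAdjacency()
  acc <- list()
  meta <- list()
  for (p in seq_len(config$nParticipants)) {
    for (m in c("visual", "audiovisual")) {
      if (verbose)
        message(sprintf("participant %d / %s", p, m))
      rec <- generateRecording(config, p, m)$recording
      rec <- highpass(rec, highpassCutoff)
      segRun <- segmentAcquisition(rec)
      feats <- recordingFeatures(segRun, families, powerBandTable,
                                 connectivityBands, cfcPairs, adjacency,
                                 trim_s)
      meta[[length(meta) + 1]] <- data.frame(
        participant = rep(sprintf("P%02d", p), 6),
        modality = rep(m, 6), segment = 1:6)
      for (fam in names(feats)) {
        for (b in names(feats[[fam]])) {
          acc[[fam]][[b]] <- c(acc[[fam]][[b]], list(feats[[fam]][[b]]))
        }
      }
    }
  }
  meta <- do.call(rbind, meta)
  lapply(stats::setNames(names(acc), names(acc)), function(fam) lapply(
    stats::setNames(names(acc[[fam]]), names(acc[[fam]])), function(b)
      EEGFeatureSet(do.call(rbind, acc[[fam]][[b]]), meta,
                    family = fam, band = b)))
}

#' Read a pipeline run configuration
#'
#' YAML file with the cohort parameters plus the run controls
#' (`families`, `schemes`, `reps`, `seed`, `out`). Any omitted field keeps
#' its default. All study constants (band edges, 0.2 s trim, 200
#' repetitions, 80-10-10 split) are defaults, so deviations are explicit in
#' the file.
#'
#' @param path YAML file.
#' @return list with `cohort` (a [cohortConfig()]) and the run controls.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cohortArgs <- raw[intersect(names(raw),
                              names(formals(cohortConfig)))]
  if (!is.null(cohortArgs$modalityPowerEffect))
    cohortArgs$modalityPowerEffect <-
      do.call(rbind, cohortArgs$modalityPowerEffect)
  if (!is.null(cohortArgs$loadCouplingEffect))
    cohortArgs$loadCouplingEffect <-
      do.call(rbind, cohortArgs$loadCouplingEffect)
  list(cohort = do.call(cohortConfig, cohortArgs),
       families = raw$families %||% c("power", "connectivity", "cfc"),
       connectivityBands = raw$connectivityBands %||% powerBands()$name,
       cfcPairs = raw$cfcPairs %||% cfcPairLabels(),
       schemes = raw$schemes %||% c("four_class", "modality", "load"),
       reps = raw$reps %||% 200,
       seed = raw$seed %||% cohortArgs$seed %||% 1,
       out = raw$out %||% "eegwm_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' simulate -> features -> repeated-split decoding (actual + permutation
#' chance) -> ANOVA report. Writes the feature tables, accuracy tables,
#' ANOVA tables and a manifest sufficient to reproduce the run, and returns
#' the nested result list invisibly.
#'
#' @param config list as returned by [readRunConfig()], or a path to a YAML
#'   file, or `NULL` for all defaults.
#' @param out output directory (overrides the config).
#' @param verbose log stage progress.
#' @return invisibly, list with `features` and `decoding`.
#' @export
runPipeline <- function(config = NULL, out = NULL, verbose = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(config))
    config <- list(cohort = cohortConfig(),
                   families = c("power", "connectivity", "cfc"),
                   connectivityBands = powerBands()$name,
                   cfcPairs = cfcPairLabels(),
                   schemes = c("four_class", "modality", "load"),
                   reps = 200, seed = 1, out = "eegwm_run")
  if (!is.null(out)) config$out <- out
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(config$out, "run.log")
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = logFile, append = TRUE)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logf("stage %s: done (%.1f s)", name, proc.time()[3] - t0)
    res
  }

  feats <- stage("features", computeCohortFeatures(
    config$cohort, families = config$families,
    connectivityBands = config$connectivityBands,
    cfcPairs = config$cfcPairs, verbose = verbose))

  featDir <- file.path(config$out, "features")
  dir.create(featDir, showWarnings = FALSE)
  for (fam in names(feats)) {
    for (b in names(feats[[fam]])) {
      fsB <- feats[[fam]][[b]]
      tab <- cbind(obsData(fsB), featureValues(fsB))
      utils::write.table(tab,
        file.path(featDir, sprintf("%s_%s.tsv", fam, gsub("-", "_", b))),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  results <- stage("decoding", {
    res <- list()
    for (fam in names(feats)) {
      for (b in names(feats[[fam]])) {
        for (s in config$schemes) {
          sd1 <- .deriveSeed(config$seed, match(fam, config$families),
                             match(b, names(feats[[fam]])),
                             match(s, config$schemes), 1L)
          sd2 <- .deriveSeed(config$seed, match(fam, config$families),
                             match(b, names(feats[[fam]])),
                             match(s, config$schemes), 2L)
          res[[fam]][[b]][[s]] <- list(
            actual = repeatedAccuracy(feats[[fam]][[b]], s,
                                      reps = config$reps, seed = sd1),
            chance = permutationChance(feats[[fam]][[b]], s,
                                       reps = config$reps, seed = sd2))
        }
      }
    }
    res
  })

  stage("report", renderTables(results, file.path(config$out, "report")))

  manifest <- c(
    sprintf("eegwmdecode %s",
            as.character(utils::packageVersion("eegwmdecode"))),
    sprintf("seed: %s", config$seed),
    sprintf("reps: %d", config$reps),
    sprintf("families: %s", paste(config$families, collapse = ", ")),
    sprintf("schemes: %s", paste(config$schemes, collapse = ", ")),
    "cohort:",
    utils::capture.output(utils::str(unclass(config$cohort))))
  writeLines(manifest, file.path(config$out, "manifest.txt"))
  logf("pipeline complete")
  invisible(list(features = feats, decoding = results))
}
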