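#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Multi-channel EEG recording
#'
#' Container for one continuous recording: a channels-by-samples matrix in
#' microvolts, the sampling rate, 10-10 channel labels, an event table
#' delimiting the pre-task baseline, the six working-memory load segments and
#' the post-task baseline, plus participant and modality tags.
#'
#' @slot data numeric matrix, channels x samples (microvolts); rownames are
#'   the channel labels.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector of unique 10-10 labels.
#' @slot events data.frame with columns `onset` (0-based sample index),
#'   `duration` (samples) and `label`.
#' @slot modality `"visual"` or `"audiovisual"` (or `""` if untagged).
#' @slot participant participant identifier.
#'
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelNames = "character",
    events = "data.frame",
    modality = "character",
    participant = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "data must have one row per channel")
  ev <- object@events
  if (nrow(ev) > 0) {
    need <- c("onset", "duration", "label")
    if (!all(need %in% names(ev))) {
      msg <- c(msg, "events need columns onset, duration, label")
    } else if (any(ev$onset < 0 | ev$onset >= ncol(object@data))) {
      msg <- c(msg, "event onsets must lie within [0, n_samples)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate (Hz).
#' @param channelNames channel labels; defaults to `rownames(data)`.
#' @param events data.frame with `onset` (0-based samples), `duration`
#'   (samples), `label`.
#' @param modality,participant metadata tags.
#' @return An [EEGRecording-class] object.
#' @export
EEGRecording <- function(data, fs, channelNames = rownames(data),
                         events = data.frame(onset = integer(),
                                             duration = integer(),
                                             label = character()),
                         modality = "", participant = "") {
  data <- as.matrix(data)
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- channelNames
  events <- as.data.frame(events)
  if (nrow(events)) {
    events$onset <- as.integer(round(events$onset))
    events$duration <- as.integer(round(events$duration))
  }
  new("EEGRecording", data = data, fs = as.numeric(fs),
      channelNames = as.character(channelNames),
      events = events,
      modality = as.character(modality),
      participant = as.character(participant))
}

#' One recording cut into baselines and the six load segments
#'
#' @slot baselinePre,baselinePost channels x samples matrices.
#' @slot loadSegments list of exactly six channels x samples matrices, in
#'   staircase order (load 1 to load 6).
#' @slot fs sampling rate (Hz).
#' @slot modality,participant metadata tags.
#' @export
setClass("SegmentedRun",
  representation(
    baselinePre = "matrix",
    baselinePost = "matrix",
    loadSegments = "list",
    fs = "numeric",
    modality = "character",
    participant = "character"
  )
)

setValidity("SegmentedRun", function(object) {
  msg <- character()
  if (length(object@loadSegments) != 6L)
    msg <- c(msg, "a segmented run must hold exactly six load segments")
  if (!all(vapply(object@loadSegments, is.matrix, logical(1))))
    msg <- c(msg, "load segments must be channels x samples matrices")
  if (length(msg)) msg else TRUE
})

#' Labeled per-channel feature matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose assay holds one
#' feature value per channel (rows) and observation (columns); observations
#' are participant x task x load-segment combinations, described in
#' `colData` by `participant`, `modality` and `segment`. `metadata()` carries
#' the feature `family` (power, connectivity or cfc) and `band` label.
#'
#' @export
setClass("EEGFeatureSet", contains = "SummarizedExperiment")

setValidity("EEGFeatureSet", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("participant", "modality", "segment")
  if (!all(need %in% names(cd)))
    msg <- c(msg, "colData needs participant, modality and segment")
  else if (any(!cd$segment %in% 1:6))
    msg <- c(msg, "segment must be in 1..6")
  if (any(!is.finite(assay(object))))
    msg <- c(msg, "feature values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGFeatureSet
#'
#' @param values observations x channels numeric matrix (one row per
#'   participant x task x segment).
#' @param meta data.frame with columns `participant`, `modality`, `segment`
#'   (one row per observation).
#' @param family feature family label (`"power"`, `"connectivity"`, `"cfc"`).
#' @param band band or band-pair label.
#' @return An [EEGFeatureSet-class].
#' @export
EEGFeatureSet <- function(values, meta, family = "", band = "") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(meta))
  se <- SummarizedExperiment(
    assays = list(features = t(values)),
    colData = DataFrame(meta),
    metadata = list(family = family, band = band)
  )
  new("EEGFeatureSet", se)
}

#' Repeated-split classification accuracy distribution
#'
#' Holds the test-set accuracies from repeated random 80-10-10 splits, the
#' per-repetition confusion matrices and the split seeds, for either the
#' actual labels or the label-permuted chance condition.
#'
#' @slot accuracies numeric vector in \[0, 1\], one value per repetition.
#' @slot cvAccuracies accuracy on the held-out cross-validation fold.
#' @slot confusions k x k x reps array of test-set confusion counts
#'   (rows = true class, columns = predicted).
#' @slot condition `"actual"` or `"chance"`.
#' @slot scheme target scheme (`"four_class"`, `"modality"` or `"load"`).
#' @slot seeds integer seed used for each repetition's split.
#' @export
setClass("AccuracyDistribution",
  representation(
    accuracies = "numeric",
    cvAccuracies = "numeric",
    confusions = "array",
    condition = "character",
    scheme = "character",
    seeds = "integer"
  )
)

setValidity("AccuracyDistribution", function(object) {
  msg <- character()
  if (any(object@accuracies < 0 | object@accuracies > 1))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(object@seeds) != length(object@accuracies))
    msg <- c(msg, "one seed per repetition required")
  if (length(msg)) msg else TRUE
})

# ---- generics ----------------------------------------------------------

#' @rdname EEGRecording-class
#' @param object,x an object.
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EEGRecording-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname EEGRecording-class
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname EEGRecording-class
#' @export
setGeneric("modalityTag", function(x) standardGeneric("modalityTag"))
#' @rdname EEGRecording-class
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))
#' @rdname SegmentedRun-class
#' @param x an object.
#' @export
setGeneric("loadSegments", function(x) standardGeneric("loadSegments"))
#' @rdname SegmentedRun-class
#' @export
setGeneric("baselinePre", function(x) standardGeneric("baselinePre"))
#' @rdname SegmentedRun-class
#' @export
setGeneric("baselinePost", function(x) standardGeneric("baselinePost"))
#' @rdname EEGFeatureSet-class
#' @param x an object.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname EEGFeatureSet-class
#' @export
setGeneric("obsData", function(x) standardGeneric("obsData"))
#' @rdname AccuracyDistribution-class
#' @param x an object.
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))
#' @rdname AccuracyDistribution-class
#' @export
setGeneric("confusions", function(x) standardGeneric("confusions"))

#' @rdname EEGRecording-class
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname SegmentedRun-class
#' @export
setMethod("samplingRate", "SegmentedRun", function(x) x@fs)
#' @rdname EEGRecording-class
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)
#' @rdname EEGRecording-class
#' @export
setMethod("eventTable", "EEGRecording", function(x) x@events)
#' @rdname EEGRecording-class
#' @export
setMethod("modalityTag", "EEGRecording", function(x) x@modality)
#' @rdname SegmentedRun-class
#' @export
setMethod("modalityTag", "SegmentedRun", function(x) x@modality)
#' @rdname EEGRecording-class
#' @export
setMethod("participantId", "EEGRecording", function(x) x@participant)
#' @rdname SegmentedRun-class
#' @export
setMethod("participantId", "SegmentedRun", function(x) x@participant)
#' @rdname SegmentedRun-class
#' @export
setMethod("loadSegments", "SegmentedRun", function(x) x@loadSegments)
#' @rdname SegmentedRun-class
#' @export
setMethod("baselinePre", "SegmentedRun", function(x) x@baselinePre)
#' @rdname SegmentedRun-class
#' @export
setMethod("baselinePost", "SegmentedRun", function(x) x@baselinePost)
#' @rdname EEGFeatureSet-class
#' @export
setMethod("featureValues", "EEGFeatureSet", function(x) t(assay(x, "features")))
#' @rdname EEGFeatureSet-class
#' @export
setMethod("obsData", "EEGFeatureSet",
          function(x) as.data.frame(colData(x)))
#' @rdname AccuracyDistribution-class
#' @export
setMethod("accuracies", "AccuracyDistribution", function(x) x@accuracies)
#' @rdname AccuracyDistribution-class
#' @export
setMethod("confusions", "AccuracyDistribution", function(x) x@confusions)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(object@data), ncol(object@data), object@fs,
    ncol(object@data) / object@fs))
  if (nzchar(object@participant) || nzchar(object@modality))
    cat(sprintf("  participant: %s  modality: %s\n",
                object@participant, object@modality))
  if (nrow(object@events))
    cat("  events:", paste(object@events$label, collapse = ", "), "\n")
})

setMethod("show", "SegmentedRun", function(object) {
  lens <- vapply(object@loadSegments, ncol, integer(1))
  cat(sprintf(
    "SegmentedRun (%s, %s): 6 load segments of %s samples @ %g Hz\n",
    object@participant, object@modality,
    paste(lens, collapse = "/"), object@fs))
})

setMethod("show", "AccuracyDistribution", function(object) {
  cat(sprintf(
    "AccuracyDistribution [%s, %s]: %d repetitions, mean %.3f (sd %.3f)\n",
    object@scheme, object@condition, length(object@accuracies),
    mean(object@accuracies), stats::sd(object@accuracies)))
})
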