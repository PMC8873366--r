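## Accessors and show() methods.

#' @rdname accessors
setMethod("samplingRate", "Recording", function(object) object@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "Segment", function(object) object@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "TrialSchedule", function(object) object@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "ParadigmConfig", function(object) object@samplingRate)

#' @rdname accessors
setMethod("nChannels", "Recording", function(object) ncol(object@data))
#' @rdname accessors
setMethod("nChannels", "Segment", function(object) ncol(object@data))
#' @rdname accessors
setMethod("nChannels", "ParadigmConfig", function(object) object@nChannels)
#' @rdname accessors
setMethod("nChannels", "BFN", function(object) ncol(object@weights))

#' @rdname accessors
setMethod("signalMatrix", "Recording", function(object) object@data)
#' @rdname accessors
setMethod("signalMatrix", "Segment", function(object) object@data)

#' @rdname accessors
setMethod("edgeWeights", "BFN", function(object) object@weights)

#' @rdname accessors
setMethod("subjectId", "Recording", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "Segment", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "BFN", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "FingerprintSet", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "SubjectProfile", function(object) object@subjectId)

#' @rdname accessors
setMethod("view", "Recording", function(object) object@view)
#' @rdname accessors
setMethod("view", "Segment", function(object) object@view)
#' @rdname accessors
setMethod("view", "BFN", function(object) object@view)
#' @rdname accessors
setMethod("view", "FingerprintSet", function(object) object@view)

#' @rdname accessors
setMethod("accuracy", "IdentificationResult", function(object) object@accuracy)

#' @rdname accessors
setMethod("trialTable", "TrialSchedule", function(object) object@trials)
#' @rdname accessors
setMethod("trialTable", "Recording", function(object) object@schedule@trials)

#' @rdname accessors
setMethod("fingerprints", "FingerprintSet", function(object) object@fingerprints)

setMethod("show", "ParadigmConfig", function(object) {
  cat(sprintf(
    "ParadigmConfig: %d subjects, %d session(s) x %d trials, %d channels\n",
    object@nSubjects, object@nSessions, object@trialsPerSession,
    object@nChannels))
  cat(sprintf("  trial: %gs intro + %gs task + [%g, %g]s rest; fs = %.4f Hz\n",
              object@introDuration, object@taskDuration, object@restRange[1],
              object@restRange[2], object@samplingRate))
  cat(sprintf("  tasks: %s (+ %s)\n",
              paste(object@taskLabels, collapse = ", "), object@restLabel))
})

setMethod("show", "TrialSchedule", function(object) {
  tr <- object@trials
  cat(sprintf("TrialSchedule: %d trials over %d session(s)\n",
              nrow(tr), length(unique(tr$session))))
  if (nrow(tr)) print(table(tr$task))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: subject %s, view %s\n", object@subjectId, object@view))
  cat(sprintf("  %d samples x %d channels at %.4f Hz (%.1f s), %d trials\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              nrow(object@data) / object@samplingRate,
              nrow(object@schedule@trials)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "Segment", function(object) {
  cat(sprintf("Segment: subject %s, view %s, state %s (trial %d), %d x %d\n",
              object@subjectId, object@view, object@state, object@trialIndex,
              nrow(object@data), ncol(object@data)))
})

setMethod("show", "BFN", function(object) {
  cat(sprintf("BFN: %d x %d, subject %s, view %s, class %s (%d segment(s) averaged)\n",
              nrow(object@weights), ncol(object@weights), object@subjectId,
              object@view, object@classLabel, object@nSegmentsAveraged))
  off <- object@weights[upper.tri(object@weights)]
  cat(sprintf("  off-diagonal weights: median %.3f, range [%.3f, %.3f]\n",
              stats::median(off), min(off), max(off)))
})

setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet: subject %s, view %s, classes: %s\n",
              object@subjectId, object@view,
              paste(names(object@fingerprints), collapse = ", ")))
})

setMethod("show", "ModeSpec", function(object) {
  cat(sprintf("ModeSpec: source %s/%s -> target %s/%s\n",
              object@sourceClass, object@sourceView,
              object@targetClass, object@targetView))
})

setMethod("show", "IdentificationResult", function(object) {
  show(object@mode)
  cat(sprintf("  %d/%d correct (accuracy %.3f)\n",
              object@nCorrect, length(object@predictions), object@accuracy))
})
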