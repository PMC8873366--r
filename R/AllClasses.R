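
## ---------------------------------------------------------------------------
## ParadigmConfig
## ---------------------------------------------------------------------------

#' Acquisition-paradigm configuration
#'
#' Holds every constant of the block-design acquisition paradigm: cohort size,
#' session/trial structure, the three trial phases (a short introduction cue,
#' a task period, and a rest period of randomised length), sampling rate,
#' channel count and the task label set. The defaults describe a motor-cortex
#' finger/foot-tapping protocol: 30 subjects, 3 sessions of 25 trials, trials
#' of 2 s introduction + 10 s task + 17--19 s rest, 20 channels, three tasks
#' (right-handed tapping \code{RHT}, left-handed tapping \code{LHT}, foot
#' tapping \code{FT}) plus rest treated as a fourth state. The default
#' sampling rate, 30003/2250 Hz (~13.33 Hz), is the value consistent with a
#' 30003-sample recording spanning the ~2250 s paradigm.
#'
#' @slot nSubjects number of subjects in a simulated cohort.
#' @slot nSessions number of recording sessions per subject.
#' @slot trialsPerSession trials within one session.
#' @slot introDuration seconds of introduction cue at each trial start.
#' @slot taskDuration seconds of task execution per trial.
#' @slot restRange closed interval (seconds) rest durations are drawn from.
#' @slot samplingRate sampling rate in Hz.
#' @slot nChannels number of measurement channels.
#' @slot taskLabels ordered character vector of task state labels.
#' @slot restLabel label used for the rest state.
#'
#' @seealso [paradigmConfig()] for the user-facing constructor.
#' @export
setClass("ParadigmConfig", representation(
  nSubjects = "integer",
  nSessions = "integer",
  trialsPerSession = "integer",
  introDuration = "numeric",
  taskDuration = "numeric",
  restRange = "numeric",
  samplingRate = "numeric",
  nChannels = "integer",
  taskLabels = "character",
  restLabel = "character"
))

setValidity("ParadigmConfig", function(object) {
  msg <- character()
  counts <- c(nSubjects = object@nSubjects, nSessions = object@nSessions,
              trialsPerSession = object@trialsPerSession,
              nChannels = object@nChannels)
  if (any(counts < 1L))
    msg <- c(msg, sprintf("counts must be >= 1 (got %s)",
                          paste(names(counts)[counts < 1L], collapse = ", ")))
  if (length(object@restRange) != 2L || object@restRange[1] > object@restRange[2])
    msg <- c(msg, "restRange must be c(min, max) with min <= max")
  if (object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be positive")
  if (object@introDuration + object@taskDuration + object@restRange[1] <= 0)
    msg <- c(msg, "trial duration must be positive")
  if (anyDuplicated(object@taskLabels) || object@restLabel %in% object@taskLabels)
    msg <- c(msg, "task labels must be distinct and distinct from the rest label")
  if (length(msg)) msg else TRUE
})

#' Construct a ParadigmConfig
#'
#' @param nSubjects,nSessions,trialsPerSession cohort and session structure.
#' @param introDuration,taskDuration trial phase durations in seconds.
#' @param restRange length-2 numeric, the closed interval (seconds) that each
#'   trial's rest duration is drawn uniformly from.
#' @param samplingRate sampling rate in Hz.
#' @param nChannels number of channels.
#' @param taskLabels character vector of task labels.
#' @param restLabel label for the rest state.
#' @return A [ParadigmConfig-class] object.
#' @examples
#' paradigmConfig()
#' paradigmConfig(nSubjects = 5, nSessions = 1, trialsPerSession = 6)
#' @export
paradigmConfig <- function(nSubjects = 30L, nSessions = 3L,
                           trialsPerSession = 25L,
                           introDuration = 2, taskDuration = 10,
                           restRange = c(17, 19),
                           samplingRate = 30003 / 2250,
                           nChannels = 20L,
                           taskLabels = c("RHT", "LHT", "FT"),
                           restLabel = "REST") {
  new("ParadigmConfig",
      nSubjects = as.integer(nSubjects), nSessions = as.integer(nSessions),
      trialsPerSession = as.integer(trialsPerSession),
      introDuration = as.numeric(introDuration),
      taskDuration = as.numeric(taskDuration),
      restRange = as.numeric(restRange),
      samplingRate = as.numeric(samplingRate),
      nChannels = as.integer(nChannels),
      taskLabels = as.character(taskLabels),
      restLabel = as.character(restLabel))
}

## ---------------------------------------------------------------------------
## TrialSchedule
## ---------------------------------------------------------------------------

#' Trial schedule of one recording
#'
#' An ordered table of trials (session index, first-sample onset, task label,
#' rest duration and total trial length in samples) together with the phase
#' durations and sampling rate needed to locate the task and rest phases of
#' every trial. Sample onsets are 1-based and trials are contiguous: trial
#' \eqn{k+1} starts at \code{onset[k] + nSamples[k]}.
#'
#' @slot trials data.frame with columns \code{session}, \code{trial},
#'   \code{onset}, \code{task}, \code{restDuration}, \code{nSamples}.
#' @slot introDuration,taskDuration phase durations in seconds.
#' @slot samplingRate sampling rate in Hz.
#' @seealso [makeTrialSchedule()]
#' @export
setClass("TrialSchedule", representation(
  trials = "data.frame",
  introDuration = "numeric",
  taskDuration = "numeric",
  samplingRate = "numeric"
))

setValidity("TrialSchedule", function(object) {
  tr <- object@trials
  need <- c("session", "trial", "onset", "task", "restDuration", "nSamples")
  if (!all(need %in% names(tr)))
    return(sprintf("trials must have columns %s", paste(need, collapse = ", ")))
  if (nrow(tr) && any(diff(tr$onset) <= 0))
    return("trial onsets must be strictly increasing")
  if (nrow(tr) && any(tr$nSamples < 1))
    return("every trial must span at least one sample")
  TRUE
})

## ---------------------------------------------------------------------------
## SubjectProfile
## ---------------------------------------------------------------------------

#' Latent generative profile of one simulated subject
#'
#' Encodes the assumption that functional connectivity is intrinsic to the
#' individual: a subject-specific symmetric positive-definite spatial
#' covariance over channels (identity plus a scaled low-rank loading) and
#' per-task evoked-response channel gains. Subject-to-subject variation of
#' both components scales with a single \code{subjectEffect} factor, so a
#' zero effect yields a cohort of statistically identical subjects.
#'
#' @slot subjectId subject identifier.
#' @slot latentCovariance channels x channels SPD matrix.
#' @slot taskGains matrix (task x channel) of evoked amplitudes.
#' @slot subjectEffect the effect scale the profile was drawn with.
#' @slot seed integer seed the profile was drawn under.
#' @seealso [sampleSubjectProfile()]
#' @export
setClass("SubjectProfile", representation(
  subjectId = "character",
  latentCovariance = "matrix",
  taskGains = "matrix",
  subjectEffect = "numeric",
  seed = "integer"
))

setValidity("SubjectProfile", function(object) {
  S <- object@latentCovariance
  if (!isSquareNumericMatrix(S)) return("latentCovariance must be a square numeric matrix")
  if (max(abs(S - t(S))) > 1e-8) return("latentCovariance must be symmetric")
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    return("latentCovariance must be positive definite")
  if (!all(is.finite(object@taskGains))) return("taskGains must be finite")
  TRUE
})

## ---------------------------------------------------------------------------
## NoiseModel
## ---------------------------------------------------------------------------

#' Physiological and instrumental noise model
#'
#' Systemic physiological oscillations contaminating fNIRS signals are modeled
#' as spatially global sinusoids at the three canonical frequencies — ~0.1 Hz
#' (Mayer wave), ~0.25 Hz (respiration) and ~1 Hz (heartbeat) — plus white
#' measurement noise and a slow per-channel random-walk drift. The sinusoids
#' are global (identical across channels, random phase per component per
#' recording) because systemic physiology is spatially unspecific; this is
#' exactly the component that global-signal baseline correction removes.
#'
#' @slot mayerFreq,respirationFreq,heartbeatFreq component frequencies in Hz.
#' @slot componentAmplitudes length-3 amplitudes (Mayer, respiration, heartbeat).
#' @slot whiteNoiseSd standard deviation of white measurement noise.
#' @slot driftSd scale of the slow per-channel drift.
#' @seealso [noiseModel()]
#' @export
setClass("NoiseModel", representation(
  mayerFreq = "numeric",
  respirationFreq = "numeric",
  heartbeatFreq = "numeric",
  componentAmplitudes = "numeric",
  whiteNoiseSd = "numeric",
  driftSd = "numeric"
))

setValidity("NoiseModel", function(object) {
  f <- c(object@mayerFreq, object@respirationFreq, object@heartbeatFreq)
  if (any(f <= 0)) return("component frequencies must be positive")
  if (length(object@componentAmplitudes) != 3L ||
      any(object@componentAmplitudes < 0))
    return("componentAmplitudes must be three non-negative values")
  if (object@whiteNoiseSd < 0 || object@driftSd < 0)
    return("noise scales must be non-negative")
  TRUE
})

#' Construct a NoiseModel
#'
#' @param mayerFreq,respirationFreq,heartbeatFreq frequencies in Hz.
#' @param componentAmplitudes amplitudes of the three global sinusoids, in the
#'   same (arbitrary) concentration units as the simulated signal.
#' @param whiteNoiseSd white measurement-noise standard deviation.
#' @param driftSd scale of the slow random-walk drift (sd reached over one
#'   full recording).
#' @return A [NoiseModel-class] object.
#' @examples
#' noiseModel()                       # study-like noise
#' noiseModel(componentAmplitudes = c(0, 0, 0), whiteNoiseSd = 0)  # silence
#' @export
noiseModel <- function(mayerFreq = 0.1, respirationFreq = 0.25,
                       heartbeatFreq = 1.0,
                       componentAmplitudes = c(0.4, 0.3, 0.25),
                       whiteNoiseSd = 0.3, driftSd = 0.1) {
  new("NoiseModel", mayerFreq = mayerFreq, respirationFreq = respirationFreq,
      heartbeatFreq = heartbeatFreq,
      componentAmplitudes = as.numeric(componentAmplitudes),
      whiteNoiseSd = whiteNoiseSd, driftSd = driftSd)
}

## ---------------------------------------------------------------------------
## FilterSpec
## ---------------------------------------------------------------------------

#' Band-pass filter specification
#'
#' Third-order Butterworth band-pass with 0.01--0.1 Hz cut-offs by default,
#' the standard fNIRS preprocessing band that removes drift below 0.01 Hz and
#' the Mayer-wave/respiration/heartbeat physiology above 0.1 Hz.
#'
#' @slot lowCut,highCut cut-off frequencies in Hz.
#' @slot order filter order.
#' @slot family filter family label (only \code{"butterworth"}).
#' @seealso [filterSpec()], [bandpass()]
#' @export
setClass("FilterSpec", representation(
  lowCut = "numeric", highCut = "numeric",
  order = "integer", family = "character"
))

setValidity("FilterSpec", function(object) {
  if (object@lowCut <= 0 || object@highCut <= object@lowCut)
    return("need 0 < lowCut < highCut")
  if (object@order < 1L) return("order must be >= 1")
  if (!identical(object@family, "butterworth"))
    return("only the butterworth family is supported")
  TRUE
})

#' Construct a FilterSpec
#'
#' @param lowCut,highCut band edges in Hz.
#' @param order filter order.
#' @return A [FilterSpec-class] object.
#' @examples
#' filterSpec()
#' @export
filterSpec <- function(lowCut = 0.01, highCut = 0.1, order = 3L) {
  new("FilterSpec", lowCut = as.numeric(lowCut), highCut = as.numeric(highCut),
      order = as.integer(order), family = "butterworth")
}

## ---------------------------------------------------------------------------
## Recording
## ---------------------------------------------------------------------------

#' One subject x one view concentration-change recording
#'
#' A time x channels matrix of hemoglobin concentration changes (arbitrary
#' units) for one subject and one view (\code{OXY} or \code{DEOXY}), with its
#' sampling rate, channel labels, trial schedule and a free-form metadata list
#' recording provenance (seeds, preprocessing applied).
#'
#' @slot subjectId subject identifier.
#' @slot view \code{"OXY"} or \code{"DEOXY"}.
#' @slot data numeric matrix, time points in rows, channels in columns.
#' @slot samplingRate Hz.
#' @slot schedule a [TrialSchedule-class].
#' @slot channelLabels column labels.
#' @slot metadata named list of provenance entries.
#' @export
setClass("Recording", representation(
  subjectId = "character",
  view = "character",
  data = "matrix",
  samplingRate = "numeric",
  schedule = "TrialSchedule",
  channelLabels = "character",
  metadata = "list"
))

setValidity("Recording", function(object) {
  msg <- character()
  if (!object@view %in% c("OXY", "DEOXY"))
    msg <- c(msg, "view must be 'OXY' or 'DEOXY'")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "recording data contains non-finite values")
  if (length(object@channelLabels) != ncol(object@data))
    msg <- c(msg, sprintf("channelLabels length (%d) != data columns (%d)",
                          length(object@channelLabels), ncol(object@data)))
  tr <- object@schedule@trials
  if (nrow(tr)) {
    last <- tr$onset[nrow(tr)] + tr$nSamples[nrow(tr)] - 1L
    if (last > nrow(object@data))
      msg <- c(msg, sprintf(
        "schedule extends to sample %d but recording has only %d samples",
        last, nrow(object@data)))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Segment
## ---------------------------------------------------------------------------

#' One task- or rest-state epoch of a recording
#'
#' @slot subjectId,view provenance of the parent recording.
#' @slot state the trial's task label, or the rest label.
#' @slot trialIndex 1-based index of the parent trial.
#' @slot data samples x channels matrix.
#' @slot samplingRate Hz.
#' @export
setClass("Segment", representation(
  subjectId = "character",
  view = "character",
  state = "character",
  trialIndex = "integer",
  data = "matrix",
  samplingRate = "numeric"
))

setValidity("Segment", function(object) {
  if (!all(is.finite(object@data))) return("segment contains non-finite values")
  TRUE
})

## ---------------------------------------------------------------------------
## BFN
## ---------------------------------------------------------------------------

#' Brain functional network
#'
#' A symmetric channels x channels matrix of Pearson-correlation edge weights
#' with unit diagonal; either the network of a single segment
#' (\code{nSegmentsAveraged == 1}) or the element-wise average of all networks
#' of one class — the subject's task fingerprint.
#'
#' @slot weights symmetric numeric matrix, entries in [-1, 1], unit diagonal.
#' @slot classLabel task label or rest label.
#' @slot subjectId,view provenance.
#' @slot nSegmentsAveraged number of segment networks averaged in.
#' @export
setClass("BFN", representation(
  weights = "matrix",
  classLabel = "character",
  subjectId = "character",
  view = "character",
  nSegmentsAveraged = "integer"
))

setValidity("BFN", function(object) {
  W <- object@weights
  if (!isSquareNumericMatrix(W)) return("weights must be a square numeric matrix")
  if (max(abs(W - t(W))) > 1e-10) return("weights must be symmetric")
  if (any(abs(diag(W) - 1) > 1e-10)) return("diagonal must be 1")
  if (any(W < -1 - 1e-10 | W > 1 + 1e-10)) return("entries must lie in [-1, 1]")
  if (object@nSegmentsAveraged < 1L) return("nSegmentsAveraged must be >= 1")
  TRUE
})

## ---------------------------------------------------------------------------
## FingerprintSet
## ---------------------------------------------------------------------------

#' All class fingerprints of one subject in one view
#'
#' A named list with one averaged [BFN-class] per class (the task labels plus
#' rest: four entries under the default paradigm).
#'
#' @slot subjectId,view provenance.
#' @slot fingerprints named list of [BFN-class], one per class label.
#' @export
setClass("FingerprintSet", representation(
  subjectId = "character",
  view = "character",
  fingerprints = "list"
))

setValidity("FingerprintSet", function(object) {
  fp <- object@fingerprints
  if (!length(fp) || is.null(names(fp)) || anyDuplicated(names(fp)))
    return("fingerprints must be a uniquely named, non-empty list")
  if (!all(vapply(fp, is, logical(1), "BFN")))
    return("all fingerprints must be BFN objects")
  dims <- vapply(fp, function(b) nrow(b@weights), integer(1))
  if (length(unique(dims)) != 1L) return("all fingerprints must share one dimension")
  TRUE
})

## ---------------------------------------------------------------------------
## ModeSpec / IdentificationResult
## ---------------------------------------------------------------------------

#' Source/target mode of one identification experiment
#'
#' @slot sourceClass,targetClass class labels of the source and target sets.
#' @slot sourceView,targetView hemoglobin views of the two sets.
#' @export
setClass("ModeSpec", representation(
  sourceClass = "character", targetClass = "character",
  sourceView = "character", targetView = "character"
))

setValidity("ModeSpec", function(object) {
  if (!object@sourceView %in% c("OXY", "DEOXY") ||
      !object@targetView %in% c("OXY", "DEOXY"))
    return("views must be 'OXY' or 'DEOXY'")
  TRUE
})

#' Construct a ModeSpec
#'
#' @param sourceClass,targetClass class labels.
#' @param sourceView,targetView views.
#' @return A [ModeSpec-class].
#' @examples
#' modeSpec("REST", "RHT")
#' @export
modeSpec <- function(sourceClass, targetClass,
                     sourceView = "OXY", targetView = sourceView) {
  new("ModeSpec", sourceClass = sourceClass, targetClass = targetClass,
      sourceView = sourceView, targetView = targetView)
}

#' Result of one identification mode
#'
#' @slot mode the [ModeSpec-class] evaluated.
#' @slot predictions named character: predicted source subject per target subject.
#' @slot scores named numeric of 0/1 prediction scores.
#' @slot nCorrect number of correct predictions.
#' @slot accuracy fraction correct.
#' @slot similarityTable targets x sources similarity matrix.
#' @export
setClass("IdentificationResult", representation(
  mode = "ModeSpec",
  predictions = "character",
  scores = "numeric",
  nCorrect = "integer",
  accuracy = "numeric",
  similarityTable = "matrix"
))

setValidity("IdentificationResult", function(object) {
  n <- length(object@predictions)
  if (length(object@scores) != n) return("scores and predictions differ in length")
  if (!isTRUE(all.equal(object@accuracy, object@nCorrect / n)))
    return("accuracy must equal nCorrect / n subjects")
  ok <- as.numeric(names(object@predictions) == object@predictions)
  if (!identical(unname(object@scores), ok))
    return("scores inconsistent with predictions")
  TRUE
})
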