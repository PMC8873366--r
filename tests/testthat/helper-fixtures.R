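## Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

tinyParadigm <- function(nSubjects = 2L, nSessions = 1L, trialsPerSession = 3L,
                         nChannels = 8L) {
  paradigmConfig(nSubjects = nSubjects, nSessions = nSessions,
                 trialsPerSession = trialsPerSession, nChannels = nChannels)
}

quietNoise <- function(white = 0.05) {
  noiseModel(componentAmplitudes = c(0, 0, 0), whiteNoiseSd = white,
             driftSd = 0)
}

## One raw full-scale recording under the default paradigm (75 trials, 20
## channels) and its preprocessed version; several files assert the printed
## pipeline counts on it.
defaultRecording <- function() cached("defaultRecording", {
  par <- paradigmConfig()
  simulateRecording(sampleSubjectProfile(par, seed = 1, subjectEffect = 3),
                    makeTrialSchedule(par, seed = 1), par, noiseModel(),
                    "OXY", seed = 1)
})

defaultPreprocessed <- function() cached("defaultPreprocessed", {
  preprocessRecording(defaultRecording())
})

defaultSegments <- function() cached("defaultSegments", {
  segmentTrials(defaultPreprocessed())
})

## Build a small symmetric unit-diagonal BFN from its upper-triangular vector.
makeBFN <- function(upper, subject = "S1", viewLabel = "OXY", class = "RHT",
                    n = NULL) {
  if (is.null(n)) n <- (1 + sqrt(1 + 8 * length(upper))) / 2
  W <- diag(n)
  W[upper.tri(W)] <- upper
  W <- W + t(W) - diag(n)
  new("BFN", weights = W, classLabel = class, subjectId = subject,
      view = viewLabel, nSegmentsAveraged = 1L)
}

## Wrap a bare matrix as a Recording with a single all-spanning trial.
recordingFromMatrix <- function(X, fs = 30003 / 2250, subject = "S1",
                                viewLabel = "OXY") {
  n <- nrow(X)
  colnames(X) <- sprintf("CH%02d", seq_len(ncol(X)))
  sch <- new("TrialSchedule",
             trials = data.frame(session = 1L, trial = 1L, onset = 1L,
                                 task = "RHT", restDuration = 1,
                                 nSamples = as.integer(n)),
             introDuration = 0, taskDuration = 0, samplingRate = fs)
  new("Recording", subjectId = subject, view = viewLabel, data = X,
      samplingRate = fs, schedule = sch,
      channelLabels = colnames(X), metadata = list())
}

## Fingerprint sets of a quick strong-effect dual-view cohort.
smallCohortFPs <- function() cached("smallCohortFPs", {
  par <- tinyParadigm(nSubjects = 5L, trialsPerSession = 6L, nChannels = 12L)
  coh <- simulateCohort(par, noiseModel(), subjectEffect = 3, masterSeed = 7)
  fps <- list()
  for (subj in coh) for (rec in subj)
    fps[[length(fps) + 1L]] <- estimateFingerprints(rec)
  fps
})

offDiag <- function(m) m[upper.tri(m)]

## seconds -> samples, rounding half up (the schedule's convention)
roundN <- function(sec, fs) as.integer(floor(sec * fs + 0.5))
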