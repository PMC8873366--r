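## Trial segmentation: task epochs + centred rest epochs.

#' Segment a recording into task- and rest-state epochs
#'
#' Per trial, two epochs are extracted: the task epoch, starting at task
#' onset (the introduction cue is discarded) and spanning
#' `floor(taskDuration * fs)` samples, and a rest epoch of
#' `floor(restWindow * fs)` samples centred in that trial's rest phase — only
#' the intermediate of the rest phase is kept, shielding the epoch from
#' task/rest transition transients on both sides. When the guard left over is
#' an odd number of samples the extra sample is left before the window. Under
#' the default paradigm (75 trials, ~13.33 Hz) this yields 150 epochs: 75
#' task epochs of 133 samples and 75 rest epochs of 200 samples.
#'
#' The 15-s default rest window is the duration that spans exactly 200
#' samples at the default sampling rate while leaving at least 1 s of guard
#' inside the shortest (17 s) rest phase.
#'
#' @param recording a [Recording-class] carrying its [TrialSchedule-class].
#' @param restWindow rest epoch duration in seconds; must not exceed any
#'   trial's rest duration.
#' @return List of [Segment-class], two per trial (task epoch first).
#' @examples
#' par <- paradigmConfig(nSubjects = 1, nSessions = 1, trialsPerSession = 3)
#' rec <- simulateRecording(sampleSubjectProfile(par, 1),
#'                          makeTrialSchedule(par, 1), par, noiseModel(),
#'                          "OXY", seed = 1)
#' segs <- segmentTrials(rec)
#' length(segs)   # 6 = 2 per trial
#' @export
segmentTrials <- function(recording, restWindow = 15.0) {
  stopifnot(is(recording, "Recording"))
  sch <- recording@schedule
  fs <- sch@samplingRate
  tr <- sch@trials
  if (!nrow(tr)) stopf("recording has an empty trial schedule")
  introN <- roundHalfUp(sch@introDuration * fs)
  taskN <- as.integer(floor(sch@taskDuration * fs))
  restWindowN <- as.integer(floor(restWindow * fs))
  if (restWindowN < 1L) stopf("restWindow too small: spans no samples")
  n <- nrow(recording@data)
  segments <- vector("list", 2L * nrow(tr))
  for (i in seq_len(nrow(tr))) {
    if (restWindow > tr$restDuration[i])
      stopf("restWindow %.3g s exceeds the %.3g s rest phase of trial %d",
            restWindow, tr$restDuration[i], tr$trial[i])
    taskFrom <- tr$onset[i] + introN
    taskTo <- taskFrom + taskN - 1L
    restFrom0 <- taskFrom + roundHalfUp(sch@taskDuration * fs)  # rest phase start
    restLen <- tr$onset[i] + tr$nSamples[i] - restFrom0
    guard <- restLen - restWindowN
    restFrom <- restFrom0 + as.integer(ceiling(guard / 2))
    restTo <- restFrom + restWindowN - 1L
    if (taskTo > n || restTo > n)
      stopf("trial %d extends beyond the recording (%d samples)", tr$trial[i], n)
    segments[[2L * i - 1L]] <- new("Segment",
      subjectId = recording@subjectId, view = recording@view,
      state = tr$task[i], trialIndex = tr$trial[i],
      data = recording@data[taskFrom:taskTo, , drop = FALSE],
      samplingRate = fs)
    segments[[2L * i]] <- new("Segment",
      subjectId = recording@subjectId, view = recording@view,
      state = "REST", trialIndex = tr$trial[i],
      data = recording@data[restFrom:restTo, , drop = FALSE],
      samplingRate = fs)
  }
  segments
}
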