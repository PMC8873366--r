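## Synthetic cohort generator.
##
## Generative model, per subject and view (time x channels, arbitrary
## concentration units):
##
##   X = slowAmp * (shared structured slow signal + view-specific structured
##       slow signal) + evoked responses + global physiological sinusoids +
##       white noise + slow drift
##
## The shared slow signal has spatial covariance I + subjectEffect * L L' (the
## subject's intrinsic connectivity); the view-specific term adds
## subjectEffect * viewDistortion * Lv Lv' with an independent loading per
## view, so the two hemoglobin views agree on the subject's core network but
## differ by a stable view-private component. DEOXY carries -kappa times the
## shared components (the canonical oxy/deoxy anticorrelation). All
## subject-specific structure scales with subjectEffect: at zero the cohort is
## exchangeable and identification must sit at chance.

#' Build a balanced random trial schedule
#'
#' Draws one task label per trial such that every task appears equally often
#' within the whole schedule, randomises the order, draws each trial's rest
#' duration uniformly from the paradigm's rest interval, and lays trials out
#' contiguously in samples. Durations are converted to samples by rounding
#' half up, so identical seeds give bit-identical schedules.
#'
#' @param paradigm a [ParadigmConfig-class].
#' @param seed integer seed for task order and rest durations.
#' @return A [TrialSchedule-class] with
#'   `nSessions * trialsPerSession` trials.
#' @examples
#' sch <- makeTrialSchedule(paradigmConfig(), seed = 1)
#' table(trialTable(sch)$task)   # 25 trials per task
#' @export
makeTrialSchedule <- function(paradigm, seed) {
  stopifnot(is(paradigm, "ParadigmConfig"))
  nTrials <- paradigm@nSessions * paradigm@trialsPerSession
  nTasks <- length(paradigm@taskLabels)
  if (nTrials %% nTasks != 0L)
    stopf(paste0("cannot balance %d trials (%d sessions x %d trials) over %d",
                 " task labels: counts are not divisible"),
          nTrials, paradigm@nSessions, paradigm@trialsPerSession, nTasks)
  fs <- paradigm@samplingRate
  withr::with_seed(deriveSeed(seed, 1L), {
    tasks <- sample(rep(paradigm@taskLabels, nTrials / nTasks))
    restDur <- stats::runif(nTrials, paradigm@restRange[1], paradigm@restRange[2])
  })
  introN <- roundHalfUp(paradigm@introDuration * fs)
  taskN <- roundHalfUp(paradigm@taskDuration * fs)
  restN <- roundHalfUp(restDur * fs)
  nSamples <- as.integer(introN + taskN + restN)
  onset <- as.integer(1L + c(0, cumsum(nSamples[-nTrials])))
  trials <- data.frame(
    session = rep(seq_len(paradigm@nSessions), each = paradigm@trialsPerSession),
    trial = seq_len(nTrials),
    onset = onset,
    task = tasks,
    restDuration = restDur,
    nSamples = nSamples,
    stringsAsFactors = FALSE)
  new("TrialSchedule", trials = trials,
      introDuration = paradigm@introDuration,
      taskDuration = paradigm@taskDuration,
      samplingRate = fs)
}

#' Draw the latent generative profile of one subject
#'
#' The subject's intrinsic spatial covariance is `I + subjectEffect * L L'`
#' with `L` a channels x 4 standard-normal loading scaled by `1/sqrt(4)`,
#' guaranteeing symmetry and a minimum eigenvalue of at least 1. Evoked task
#' gains are a fixed smooth cortical activation pattern per task (identical
#' for all subjects) plus a subject-specific deviation scaled by
#' `subjectEffect`, so that with a zero effect subjects share both their
#' connectivity and their evoked topography.
#'
#' @param paradigm a [ParadigmConfig-class].
#' @param seed integer seed.
#' @param subjectEffect non-negative scale of subject-specific structure.
#' @param subjectId identifier stored in the profile.
#' @return A [SubjectProfile-class].
#' @examples
#' p <- sampleSubjectProfile(paradigmConfig(), seed = 7, subjectEffect = 1)
#' min(eigen(p@latentCovariance)$values) >= 1
#' @export
sampleSubjectProfile <- function(paradigm, seed, subjectEffect = 1,
                                 subjectId = sprintf("S%03d", seed %% 1000L)) {
  stopifnot(is(paradigm, "ParadigmConfig"), subjectEffect >= 0)
  C <- paradigm@nChannels
  rank <- 4L
  withr::with_seed(deriveSeed(seed, 2L), {
    L <- matrix(stats::rnorm(C * rank, sd = sqrt(1 / rank)), C, rank)
    gainDev <- matrix(stats::rnorm(length(paradigm@taskLabels) * C, sd = 0.1),
                      length(paradigm@taskLabels), C)
  })
  Sigma <- diag(C) + subjectEffect * tcrossprod(L)
  Sigma <- (Sigma + t(Sigma)) / 2
  gains <- baseTaskGains(paradigm) + subjectEffect * gainDev
  rownames(gains) <- paradigm@taskLabels
  new("SubjectProfile", subjectId = subjectId, latentCovariance = Sigma,
      taskGains = gains, subjectEffect = as.numeric(subjectEffect),
      seed = as.integer(seed))
}

## Fixed population-level activation topographies: one smooth channel bump per
## task (lateralised hand areas, midline foot area), identical for every
## subject. Units match the slow-signal scale.
baseTaskGains <- function(paradigm) {
  C <- paradigm@nChannels
  centers <- seq(0.25, 0.75, length.out = length(paradigm@taskLabels))
  pos <- (seq_len(C) - 0.5) / C
  g <- t(vapply(centers,
                function(ctr) 0.3 * exp(-((pos - ctr) / 0.15)^2),
                numeric(C)))
  rownames(g) <- paradigm@taskLabels
  g
}

#' Canonical double-gamma hemodynamic response function
#'
#' Standard two-gamma HRF (response peaking near 6 s, undershoot near 16 s,
#' undershoot ratio 1/6), sampled at `fs` over `duration` seconds and
#' normalised to unit peak.
#'
#' @param fs sampling rate in Hz.
#' @param duration kernel length in seconds.
#' @return Numeric vector of kernel samples.
#' @examples
#' h <- canonicalHRF(10)
#' which.max(h) / 10   # peak near 5-6 s
#' @export
canonicalHRF <- function(fs, duration = 32) {
  t <- seq(0, duration, by = 1 / fs)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

## Temporally smoothed standard-normal matrix (n x k), rescaled so the average
## column sd is 1; a shared scalar rescaling preserves spatial covariance.
## The 2nd-order 0.3 Hz low-pass confines the slow components to physiological
## bandwidth while keeping their coherence time (~3 s) short relative to the
## inter-trial spacing.
smoothNoise <- function(n, k, fs) {
  z <- matrix(stats::rnorm(n * k), n, k)
  bf <- signal::butter(2, min(0.3 / (fs / 2), 0.99), type = "low")
  for (j in seq_len(k)) z[, j] <- signal::filter(bf, z[, j])
  sds <- sqrt(colMeans(z^2))
  z / mean(sds)
}

## Evoked component: per task, convolve that task's 10-s boxcar train with the
## canonical HRF, then spread over channels with the profile's task gains.
evokedComponent <- function(profile, schedule, n, fs) {
  tr <- schedule@trials
  introN <- roundHalfUp(schedule@introDuration * fs)
  taskN <- roundHalfUp(schedule@taskDuration * fs)
  h <- canonicalHRF(fs)
  ## normalise so one isolated task block peaks at exactly the task gain
  blockPeak <- max(stats::convolve(rep(1, taskN), rev(h), type = "open"))
  E <- matrix(0, n, ncol(profile@taskGains))
  for (task in rownames(profile@taskGains)) {
    rows <- tr[tr$task == task, , drop = FALSE]
    if (!nrow(rows)) next
    box <- numeric(n)
    for (i in seq_len(nrow(rows))) {
      from <- rows$onset[i] + introN
      to <- min(from + taskN - 1L, n)
      box[from:to] <- 1
    }
    resp <- stats::convolve(box, rev(h), type = "open")[seq_len(n)] / blockPeak
    E <- E + outer(resp, profile@taskGains[task, ])
  }
  E
}

#' Simulate one subject x view recording
#'
#' Assembles the generative model described in the package vignette: a
#' subject-structured slow signal (spatial covariance `I + subjectEffect *
#' L L'`), a stable view-private structured component (strength
#' `viewDistortion`), canonical-HRF task-evoked responses, spatially global
#' physiological sinusoids at the Mayer/respiration/heartbeat frequencies with
#' random phases, white measurement noise, and slow per-channel drift. The
#' DEOXY view carries `-kappa` times the shared slow and evoked components
#' plus its own view-private component and nuisance draws; the shared
#' components are seeded by the profile, so OXY/DEOXY recordings built from
#' the same profile and schedule share them exactly.
#'
#' @param profile a [SubjectProfile-class].
#' @param schedule a [TrialSchedule-class].
#' @param paradigm the [ParadigmConfig-class] the schedule was built from.
#' @param noise a [NoiseModel-class].
#' @param view `"OXY"` or `"DEOXY"`.
#' @param seed integer seed for the nuisance components.
#' @param kappa anticorrelation factor applied to the DEOXY shared components.
#' @param viewDistortion relative strength of the view-private structured
#'   component (scaled, like all subject-specific structure, by the profile's
#'   `subjectEffect`).
#' @param slowAmp amplitude of the slow structured signal.
#' @return A [Recording-class]; identical arguments give identical output.
#' @examples
#' par <- paradigmConfig(nSubjects = 1, nSessions = 1, trialsPerSession = 3)
#' sch <- makeTrialSchedule(par, seed = 1)
#' prof <- sampleSubjectProfile(par, seed = 1)
#' rec <- simulateRecording(prof, sch, par, noiseModel(), "OXY", seed = 1)
#' dim(signalMatrix(rec))
#' @export
simulateRecording <- function(profile, schedule, paradigm, noise,
                              view = c("OXY", "DEOXY"), seed,
                              kappa = 0.5, viewDistortion = 0.5,
                              slowAmp = 1) {
  view <- match.arg(view)
  stopifnot(is(profile, "SubjectProfile"), is(schedule, "TrialSchedule"),
            is(paradigm, "ParadigmConfig"), is(noise, "NoiseModel"))
  fs <- schedule@samplingRate
  tr <- schedule@trials
  if (!nrow(tr)) stopf("schedule has no trials")
  n <- tr$onset[nrow(tr)] + tr$nSamples[nrow(tr)] - 1L
  C <- paradigm@nChannels
  sE <- profile@subjectEffect

  ## Shared (view-agnostic) components, seeded by the profile so both views
  ## of a subject agree on them.
  shared <- withr::with_seed(deriveSeed(profile@seed, 11L), {
    U <- smoothNoise(n, C, fs)
    Fm <- smoothNoise(n, 4L, fs)
    L <- subjectLoading(profile)
    U + sqrt(sE) * Fm %*% t(L)
  })
  evoked <- evokedComponent(profile, schedule, n, fs)

  ## View-private structured component: independent loading per view, stable
  ## over the recording, vanishing with the subject effect.
  viewPart <- withr::with_seed(deriveSeed(profile@seed, 13L + viewOffset(view)), {
    Lv <- matrix(stats::rnorm(C * 2L, sd = sqrt(1 / 2)), C, 2L)
    Fv <- smoothNoise(n, 2L, fs)
    sqrt(sE * viewDistortion) * Fv %*% t(Lv)
  })

  sgn <- if (view == "DEOXY") -kappa else 1
  X <- slowAmp * (sgn * shared + viewPart) + sgn * evoked

  ## Nuisance components, seeded by the run seed and view.
  amps <- noise@componentAmplitudes
  freqs <- c(noise@mayerFreq, noise@respirationFreq, noise@heartbeatFreq)
  X <- X + withr::with_seed(deriveSeed(seed, 17L + viewOffset(view)), {
    tt <- (seq_len(n) - 1) / fs
    globalSig <- numeric(n)
    phases <- stats::runif(3, 0, 2 * pi)
    for (k in 1:3) globalSig <- globalSig + amps[k] * sin(2 * pi * freqs[k] * tt + phases[k])
    drift <- matrix(stats::rnorm(n * C), n, C)
    drift <- apply(drift, 2, cumsum) * (noise@driftSd / sqrt(n))
    white <- matrix(stats::rnorm(n * C, sd = noise@whiteNoiseSd), n, C)
    matrix(globalSig, n, C) + drift + white
  })

  labels <- sprintf("CH%02d", seq_len(C))
  colnames(X) <- labels
  new("Recording", subjectId = profile@subjectId, view = view, data = X,
      samplingRate = fs, schedule = schedule, channelLabels = labels,
      metadata = list(seed = as.integer(seed), profileSeed = profile@seed,
                      subjectEffect = sE, kappa = kappa,
                      viewDistortion = viewDistortion, slowAmp = slowAmp))
}

## Re-derive the subject's low-rank loading from its seed (kept out of the
## profile object to avoid duplicating state; identical draw as in
## sampleSubjectProfile).
subjectLoading <- function(profile) {
  C <- nrow(profile@latentCovariance)
  withr::with_seed(deriveSeed(profile@seed, 2L), {
    matrix(stats::rnorm(C * 4L, sd = sqrt(1 / 4)), C, 4L)
  })
}

#' Simulate a full dual-view cohort
#'
#' Draws one profile and one schedule per subject from sub-seeds derived
#' reproducibly from `masterSeed`, then simulates the requested views for
#' every subject. Both views of a subject share the profile-seeded slow and
#' evoked components.
#'
#' @param paradigm a [ParadigmConfig-class] (`nSubjects >= 2`).
#' @param noise a [NoiseModel-class].
#' @param subjectEffect scale of subject-specific structure.
#' @param masterSeed integer master seed.
#' @param views which views to simulate.
#' @param kappa,viewDistortion,slowAmp passed to [simulateRecording()].
#' @return Named list with one element per subject, each a list of
#'   [Recording-class] objects named by view.
#' @examples
#' par <- paradigmConfig(nSubjects = 2, nSessions = 1, trialsPerSession = 3)
#' coh <- simulateCohort(par, noiseModel(), subjectEffect = 1, masterSeed = 1)
#' length(coh)            # 2 subjects
#' names(coh[[1]])        # "OXY" "DEOXY"
#' @export
simulateCohort <- function(paradigm, noise = noiseModel(), subjectEffect = 1,
                           masterSeed = 1L, views = c("OXY", "DEOXY"),
                           kappa = 0.5, viewDistortion = 0.5, slowAmp = 1) {
  stopifnot(is(paradigm, "ParadigmConfig"))
  if (paradigm@nSubjects < 2L)
    stopf("a cohort needs at least 2 subjects (got %d)", paradigm@nSubjects)
  views <- match.arg(views, several.ok = TRUE)
  cohort <- vector("list", paradigm@nSubjects)
  names(cohort) <- sprintf("S%03d", seq_len(paradigm@nSubjects))
  for (i in seq_len(paradigm@nSubjects)) {
    sid <- names(cohort)[i]
    profSeed <- deriveSeed(masterSeed, 100L + i)
    profile <- sampleSubjectProfile(paradigm, seed = profSeed,
                                    subjectEffect = subjectEffect,
                                    subjectId = sid)
    schedule <- makeTrialSchedule(paradigm, seed = deriveSeed(masterSeed, 200L + i))
    cohort[[i]] <- lapply(stats::setNames(views, views), function(v)
      simulateRecording(profile, schedule, paradigm, noise, view = v,
                        seed = deriveSeed(masterSeed, 300L + i),
                        kappa = kappa, viewDistortion = viewDistortion,
                        slowAmp = slowAmp))
    attr(cohort[[i]], "profile") <- profile
  }
  cohort
}
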