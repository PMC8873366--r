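test_that("default schedule has 75 balanced trials with increasing onsets", {
  sch <- makeTrialSchedule(paradigmConfig(), seed = 42)
  tr <- trialTable(sch)
  expect_equal(nrow(tr), 75L)
  expect_equal(as.integer(table(tr$task)), rep(25L, 3))
  expect_true(all(diff(tr$onset) > 0))
  expect_true(all(tr$restDuration >= 17 & tr$restDuration <= 19))
  ## trials are contiguous in samples
  expect_equal(tr$onset[-1], (tr$onset + tr$nSamples)[-75])
})

test_that("scheduling is deterministic under a fixed seed and balances exactly", {
  par <- tinyParadigm(trialsPerSession = 3L)
  s1 <- makeTrialSchedule(par, seed = 5)
  s2 <- makeTrialSchedule(par, seed = 5)
  expect_identical(trialTable(s1), trialTable(s2))
  expect_equal(as.integer(table(trialTable(s1)$task)), rep(1L, 3))
  ## a different seed reorders tasks eventually
  orders <- vapply(1:10, function(s)
    paste(trialTable(makeTrialSchedule(par, seed = s))$task, collapse = ""),
    character(1))
  expect_gt(length(unique(orders)), 1L)
})

test_that("unbalanced trial counts are rejected with the counts named", {
  par <- tinyParadigm(trialsPerSession = 4L)
  expect_error(makeTrialSchedule(par, seed = 1), "4 trials")
  expect_error(makeTrialSchedule(par, seed = 1), "3 task labels")
})

test_that("subject profiles are SPD with identity at zero subject effect", {
  par <- tinyParadigm()
  p0 <- sampleSubjectProfile(par, seed = 3, subjectEffect = 0)
  expect_equal(p0@latentCovariance, diag(nChannels(par)))
  for (s in 1:5) {
    p <- sampleSubjectProfile(par, seed = s, subjectEffect = 2)
    ev <- eigen(p@latentCovariance, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 1 - 1e-10)
  }
  pa <- sampleSubjectProfile(par, seed = 1, subjectEffect = 1)
  pb <- sampleSubjectProfile(par, seed = 2, subjectEffect = 1)
  expect_gt(max(abs(pa@latentCovariance - pb@latentCovariance)), 0)
})

test_that("a default-paradigm recording matches the expected data shape", {
  rec <- defaultRecording()
  X <- signalMatrix(rec)
  expect_equal(ncol(X), 20L)
  ## 75 trials of ~30 s at ~13.33 Hz: ~30003 samples up to rest-duration
  ## randomisation (at most ~1 s per trial)
  expect_lt(abs(nrow(X) / samplingRate(rec) - 2250), 75)
  expect_true(all(is.finite(X)))
})

test_that("the simulator is silent when all signal sources are off", {
  par <- tinyParadigm()
  prof <- sampleSubjectProfile(par, seed = 1, subjectEffect = 0)
  prof@taskGains[] <- 0
  sch <- makeTrialSchedule(par, seed = 1)
  nm0 <- noiseModel(componentAmplitudes = c(0, 0, 0), whiteNoiseSd = 0,
                    driftSd = 0)
  rec <- simulateRecording(prof, sch, par, nm0, "OXY", seed = 1, slowAmp = 0)
  expect_equal(max(abs(signalMatrix(rec))), 0)
})

test_that("recordings are bit-reproducible under fixed seeds", {
  par <- tinyParadigm()
  prof <- sampleSubjectProfile(par, seed = 2, subjectEffect = 1)
  sch <- makeTrialSchedule(par, seed = 2)
  r1 <- simulateRecording(prof, sch, par, noiseModel(), "OXY", seed = 9)
  r2 <- simulateRecording(prof, sch, par, noiseModel(), "OXY", seed = 9)
  expect_identical(signalMatrix(r1), signalMatrix(r2))
  r3 <- simulateRecording(prof, sch, par, noiseModel(), "OXY", seed = 10)
  expect_gt(max(abs(signalMatrix(r1) - signalMatrix(r3))), 0)
})

test_that("rest-state covariance recovers the latent covariance", {
  par <- paradigmConfig(nSubjects = 1, nSessions = 1, trialsPerSession = 12)
  prof <- sampleSubjectProfile(par, seed = 3, subjectEffect = 5)
  rec <- simulateRecording(prof, makeTrialSchedule(par, seed = 3), par,
                           quietNoise(), "OXY", seed = 3, viewDistortion = 0)
  rest <- do.call(rbind, lapply(
    Filter(function(s) s@state == "REST", segmentTrials(rec)), signalMatrix))
  expect_gt(cor(offDiag(cov(rest)), offDiag(prof@latentCovariance)), 0.9)
})

test_that("simulated signals carry spectral peaks at the physiological frequencies", {
  ## ~600 s recording, raw periodogram: local maxima at 0.1 / 0.25 / 1 Hz
  par <- paradigmConfig(nSubjects = 1, nSessions = 1, trialsPerSession = 21)
  rec <- simulateRecording(sampleSubjectProfile(par, seed = 1),
                           makeTrialSchedule(par, seed = 1), par, noiseModel(),
                           "OXY", seed = 1)
  x <- stats::ts(signalMatrix(rec)[, 1], frequency = samplingRate(rec))
  pg <- stats::spec.pgram(x, taper = 0, detrend = TRUE, plot = FALSE)
  for (f0 in c(0.1, 0.25, 1.0)) {
    idx <- which.min(abs(pg$freq - f0))
    win <- (idx - 4):(idx + 4)
    peak <- win[which.max(pg$spec[win])]
    expect_lte(abs(peak - idx), 1)
  }
})

test_that("cohorts produce paired views sharing the latent components", {
  par <- tinyParadigm()
  coh <- simulateCohort(par, quietNoise(0), subjectEffect = 3, masterSeed = 1,
                        viewDistortion = 0)
  expect_length(coh, 2L)
  expect_named(coh[[1]], c("OXY", "DEOXY"))
  ## with no view distortion and no noise, DEOXY is exactly -kappa x OXY's
  ## structured signal minus the evoked flip: correlation patterns coincide
  co <- cor(signalMatrix(coh[[1]]$OXY))
  cd <- cor(signalMatrix(coh[[1]]$DEOXY))
  expect_equal(co, cd, tolerance = 1e-8)
  ## determinism of the whole cohort
  coh2 <- simulateCohort(par, quietNoise(0), subjectEffect = 3, masterSeed = 1,
                         viewDistortion = 0)
  expect_identical(signalMatrix(coh[[2]]$DEOXY), signalMatrix(coh2[[2]]$DEOXY))
})

test_that("subjects are separable from rest-state covariance when an effect exists", {
  par <- paradigmConfig(nSubjects = 10, nSessions = 1, trialsPerSession = 6)
  coh <- simulateCohort(par, noiseModel(), subjectEffect = 1, masterSeed = 4,
                        views = "OXY")
  halves <- list()
  for (subj in coh) {
    rs <- Filter(function(s) s@state == "REST", segmentTrials(subj$OXY))
    halves <- c(halves,
                list(cov(do.call(rbind, lapply(rs[1:3], signalMatrix))),
                     cov(do.call(rbind, lapply(rs[4:6], signalMatrix)))))
  }
  lab <- rep(seq_len(10), each = 2)
  D <- matrix(0, 20, 20)
  for (i in 1:19) for (j in (i + 1):20)
    D[i, j] <- sqrt(sum((offDiag(halves[[i]]) - offDiag(halves[[j]]))^2))
  statf <- function(lab) {
    same <- outer(lab, lab, "==") & upper.tri(D)
    diff <- outer(lab, lab, "!=") & upper.tri(D)
    mean(D[diff]) - mean(D[same])
  }
  obs <- statf(lab)
  expect_gt(obs, 0)
  set.seed(1)
  perm <- replicate(199, statf(sample(lab)))
  pval <- (1 + sum(perm >= obs)) / 200
  expect_lt(pval, 0.05)
})
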