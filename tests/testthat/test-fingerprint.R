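## Independent double-loop implementation of the Pearson-correlation network;
## the brute-force oracle the fast path must agree with.
bruteForceNetwork <- function(X) {
  C <- ncol(X)
  W <- diag(C)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    if (i == j) next
    xi <- X[, i]; xj <- X[, j]
    num <- sum((xi - mean(xi)) * (xj - mean(xj)))
    den <- sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    W[i, j] <- num / den
  }
  W
}

segFromMatrix <- function(X, state = "RHT") {
  colnames(X) <- sprintf("CH%02d", seq_len(ncol(X)))
  new("Segment", subjectId = "S1", view = "OXY", state = state,
      trialIndex = 1L, data = X, samplingRate = 13.3)
}

test_that("exact linear dependencies give unit-magnitude edge weights", {
  X <- cbind(1:5, c(2, 4, 6, 8, 10), 5:1)
  W <- edgeWeights(pearsonNetwork(segFromMatrix(X)))
  expect_equal(W[1, 2], 1)
  expect_equal(W[1, 3], -1)
  expect_equal(W[2, 3], -1)
  expect_equal(diag(W), rep(1, 3), ignore_attr = TRUE)
  ## identical and negated series
  Y <- cbind(rnorm(10), 0, 0); Y[, 2] <- Y[, 1]; Y[, 3] <- -Y[, 1]
  W2 <- edgeWeights(pearsonNetwork(segFromMatrix(Y)))
  expect_equal(W2[1, 2], 1)
  expect_equal(W2[1, 3], -1)
})

test_that("the network agrees with a brute-force oracle to 1e-12", {
  set.seed(11)
  for (rep in 1:10) {
    X <- matrix(rnorm(133 * 20), 133, 20)
    W <- edgeWeights(pearsonNetwork(segFromMatrix(X)))
    expect_equal(unname(W), bruteForceNetwork(X), tolerance = 1e-12)
  }
})

test_that("zero-variance channels are rejected by name, not propagated as NaN", {
  X <- matrix(rnorm(30), 10, 3)
  X[, 2] <- 4
  expect_error(pearsonNetwork(segFromMatrix(X)), "CH02")
  expect_error(pearsonNetwork(segFromMatrix(X[1:2, ])), "3 samples")
})

test_that("the network is invariant to positive per-channel affine rescaling", {
  set.seed(12)
  X <- matrix(rnorm(60 * 6), 60, 6)
  scales <- runif(6, 0.1, 5)
  shifts <- rnorm(6, sd = 10)
  Y <- sweep(sweep(X, 2, scales, "*"), 2, shifts, "+")
  expect_equal(edgeWeights(pearsonNetwork(segFromMatrix(X))),
               edgeWeights(pearsonNetwork(segFromMatrix(Y))),
               tolerance = 1e-12)
})

test_that("class averaging is an element-wise mean within each class", {
  a <- makeBFN(0.4, class = "RHT", n = 2)
  b <- makeBFN(0.8, class = "RHT", n = 2)
  r <- makeBFN(0.1, class = "REST", n = 2)
  fp <- groupAndAverage(list(a, b, r))
  expect_named(fingerprints(fp), c("REST", "RHT"))
  expect_equal(edgeWeights(fingerprints(fp)$RHT)[1, 2], 0.6)
  expect_equal(fingerprints(fp)$RHT@nSegmentsAveraged, 2L)
  expect_equal(fingerprints(fp)$REST@nSegmentsAveraged, 1L)
  ## averaging identical networks reproduces them
  same <- groupAndAverage(list(a, a, a))
  expect_equal(edgeWeights(fingerprints(same)$RHT), a@weights)
})

test_that("averaging refuses mixed subjects or views and empty input", {
  a <- makeBFN(0.4, subject = "S1")
  b <- makeBFN(0.5, subject = "S2")
  expect_error(groupAndAverage(list(a, b)), "mixed subjects")
  c2 <- makeBFN(0.5, viewLabel = "DEOXY")
  expect_error(groupAndAverage(list(a, c2)), "views")
  expect_error(groupAndAverage(list()), "no networks")
})

test_that("a default recording averages 25 networks per task and 75 for rest", {
  fp <- groupAndAverage(lapply(defaultSegments(), pearsonNetwork))
  expect_length(fingerprints(fp), 4L)
  counts <- vapply(fingerprints(fp), function(b) b@nSegmentsAveraged, integer(1))
  expect_equal(counts[["REST"]], 75L)
  expect_equal(unname(counts[c("RHT", "LHT", "FT")]), rep(25L, 3))
  ## averaged fingerprints remain valid networks
  for (b in fingerprints(fp)) {
    W <- edgeWeights(b)
    expect_equal(W, t(W))
    expect_equal(diag(W), rep(1, 20), ignore_attr = TRUE)
    expect_true(all(W >= -1 & W <= 1))
  }
})

test_that("Fisher-z averaging differs from raw averaging but stays valid", {
  a <- makeBFN(0.2, class = "RHT", n = 2)
  b <- makeBFN(0.9, class = "RHT", n = 2)
  raw <- edgeWeights(fingerprints(groupAndAverage(list(a, b)))$RHT)[1, 2]
  fz <- edgeWeights(fingerprints(groupAndAverage(list(a, b),
                                                 fisherZ = TRUE))$RHT)[1, 2]
  expect_equal(raw, 0.55)
  expect_equal(fz, tanh(mean(atanh(c(0.2, 0.9)))))
  expect_gt(fz, raw)
})

test_that("the rest fingerprint recovers the subject's latent connectivity", {
  par <- paradigmConfig(nSubjects = 1)
  prof <- sampleSubjectProfile(par, seed = 3, subjectEffect = 5)
  rec <- simulateRecording(prof, makeTrialSchedule(par, seed = 3), par,
                           quietNoise(), "OXY", seed = 3, viewDistortion = 0)
  fp <- estimateFingerprints(rec)
  pc <- cor(offDiag(edgeWeights(fingerprints(fp)$REST)),
            offDiag(prof@latentCovariance))
  expect_gt(pc, 0.8)
})
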