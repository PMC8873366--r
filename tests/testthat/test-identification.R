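## Exhaustive scan used as the independent oracle for nearest-neighbour
## prediction: compute every pairwise similarity by hand and take the argmax.
bruteForcePredict <- function(target, sourceSet) {
  vec <- function(b) { W <- b@weights; W[upper.tri(W)] }
  sims <- sapply(sourceSet, function(s) cor(vec(target), vec(s)))
  sourceSet[[which.max(sims)]]@subjectId
}

test_that("similarity is the correlation of upper-triangular weights", {
  a <- makeBFN(c(0.1, 0.2, 0.3))
  b <- makeBFN(c(0.3, 0.2, 0.1))
  expect_equal(similarity(a, b), -1)
  expect_equal(similarity(a, a), 1)
  ## affine transforms of the off-diagonals leave similarity at 1
  c2 <- makeBFN(0.1 + 2 * c(0.1, 0.2, 0.3))
  expect_equal(similarity(a, c2), 1)
  ## symmetry in the arguments
  set.seed(4)
  x <- makeBFN(runif(10, -0.5, 0.5), n = 5)
  y <- makeBFN(runif(10, -0.5, 0.5), n = 5)
  expect_equal(similarity(x, y), similarity(y, x))
})

test_that("degenerate or mismatched networks are rejected", {
  a <- makeBFN(c(0.1, 0.2, 0.3))
  flat <- makeBFN(c(0.2, 0.2, 0.2))
  expect_error(similarity(a, flat), "zero edge-weight variance")
  big <- makeBFN(runif(10), n = 5)
  expect_error(similarity(a, big), "differ in dimension")
})

test_that("full-matrix vectorization is available and differs from upper", {
  set.seed(5)
  x <- makeBFN(runif(6, -0.5, 0.5), n = 4)
  y <- makeBFN(runif(6, -0.5, 0.5), n = 4)
  su <- similarity(x, y, "upper")
  sf <- similarity(x, y, "full")
  ## the constant diagonal inflates the full-matrix similarity
  expect_gt(sf, su)
})

test_that("nearest-neighbour prediction picks the most similar source", {
  set.seed(6)
  sources <- lapply(1:5, function(i)
    makeBFN(runif(10, -0.5, 0.5), subject = sprintf("S%d", i), n = 5))
  ## identical target: similarity exactly 1 dominates
  expect_equal(as.character(predictIdentity(sources[[3]], sources)), "S3")
  ## one-element source set
  expect_equal(as.character(predictIdentity(sources[[1]], sources[2])), "S2")
  ## agreement with the exhaustive oracle on random targets
  for (r in 1:20) {
    target <- makeBFN(runif(10, -0.5, 0.5), n = 5)
    expect_equal(as.character(predictIdentity(target, sources)),
                 bruteForcePredict(target, sources))
  }
})

test_that("ties break to the lowest subject index with a warning", {
  a <- makeBFN(c(0.1, 0.2, 0.3), subject = "S1")
  b <- makeBFN(c(0.2, 0.4, 0.6), subject = "S2")  # same pattern: tie at 1
  target <- makeBFN(c(0.1, 0.2, 0.3), subject = "S9")
  expect_warning(p <- predictIdentity(target, list(a, b)), "tie")
  expect_equal(as.character(p), "S1")
  dup <- makeBFN(c(0.5, 0.1, 0), subject = "S1")
  expect_error(predictIdentity(target, list(a, dup)), "duplicate")
})

test_that("runMode scores predictions against true identities", {
  fps <- smallCohortFPs()
  res <- runMode(modeSpec("REST", "RHT"), fps)
  expect_s4_class(res, "IdentificationResult")
  expect_equal(accuracy(res), res@nCorrect / 5)
  expect_equal(dim(res@similarityTable), c(5L, 5L))
  ## each row's argmax is the prediction
  for (i in 1:5) {
    s <- res@similarityTable[i, ]
    expect_equal(unname(res@predictions[i]), names(s)[which.max(s)])
  }
  ## self-match: same class, same view
  self <- runMode(modeSpec("RHT", "RHT"), fps)
  expect_equal(accuracy(self), 1)
  expect_error(runMode(modeSpec("UNKNOWN", "RHT"), fps), "UNKNOWN")
})

test_that("cross-task and cross-view matrices have the full mode combinatorics", {
  fps <- smallCohortFPs()
  ct <- crossTaskMatrix(fps, view = "OXY")
  expect_equal(dim(ct), c(4L, 4L))
  expect_equal(unname(diag(ct)), rep(1, 4))
  expect_true(all(ct >= 0 & ct <= 1))
  ## same-view "cross-view" reduces exactly to cross-task
  cv <- crossViewMatrix(fps, "OXY", "OXY")
  expect_equal(cv, ct)
  cvx <- crossViewMatrix(fps, "OXY", "DEOXY")
  expect_equal(dim(cvx), c(4L, 4L))
})

test_that("accuracies are invariant to subject order", {
  fps <- smallCohortFPs()
  ct1 <- crossTaskMatrix(fps, view = "OXY")
  set.seed(8)
  ct2 <- crossTaskMatrix(sample(fps), view = "OXY")
  expect_equal(ct1, ct2)
})

test_that("summaries aggregate the requested cells", {
  expect_equal(summarizeAccuracy(matrix(1, 3, 3)),
               c(mean = 1, sd = 0))
  m <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(unname(summarizeAccuracy(m, includeDiagonal = TRUE)["mean"]),
               0.75)
  expect_equal(unname(summarizeAccuracy(m, includeDiagonal = FALSE)["mean"]),
               0.5)
  ## diagonal-included and off-diagonal summaries differ when the diagonal
  ## is perfect and any off-diagonal is not
  expect_false(summarizeAccuracy(m, TRUE)["mean"] ==
                 summarizeAccuracy(m, FALSE)["mean"])
})

test_that("identification accuracy increases with the subject effect", {
  par <- tinyParadigm(nSubjects = 6L, trialsPerSession = 6L, nChannels = 12L)
  grid <- expand.grid(effect = c(0, 0.5, 1.5, 3), seed = 1:3)
  acc <- mapply(function(eff, seed) {
    res <- runPipeline(pipelineConfig(paradigm = par, subjectEffect = eff,
                                      seed = seed, views = "OXY",
                                      design = "cross-task"))
    summarizeAccuracy(res$crossTask$OXY)["mean"]
  }, grid$effect, grid$seed)
  trend <- cor(grid$effect, acc, method = "spearman")
  expect_gt(trend, 0)
  ## and the strongest effect beats the null on average
  expect_gt(mean(acc[grid$effect == 3]), mean(acc[grid$effect == 0]))
})

test_that("task-task identification sits at chance for exchangeable subjects", {
  ## subjectEffect = 0: no subject-specific structure; the six task-task
  ## modes (disjoint trials, well-separated epochs) must be at chance
  par <- paradigmConfig(nSubjects = 10, nSessions = 1, trialsPerSession = 6)
  taskCells <- function(m) {
    tt <- m[1:3, 1:3]
    tt[row(tt) != col(tt)]
  }
  correct <- 0
  nSeeds <- 5
  for (s in 1:nSeeds) {
    res <- runPipeline(pipelineConfig(paradigm = par, subjectEffect = 0,
                                      seed = s, views = "OXY",
                                      design = "cross-task"))
    correct <- correct + sum(taskCells(res$crossTask$OXY) * 10)
  }
  nTrials <- nSeeds * 6 * 10   # seeds x task-task cells x subjects
  expect_gte(correct, qbinom(0.005, nTrials, 1 / 10))
  expect_lte(correct, qbinom(0.995, nTrials, 1 / 10))
})
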