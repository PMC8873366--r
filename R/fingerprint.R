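## BFN estimation and class averaging.

#' Estimate the Pearson-correlation network of one segment
#'
#' Edge weight (i, j) is the Pearson correlation between the time series of
#' channels i and j over the segment's samples; nodes are channels, the
#' diagonal is exactly 1 and the matrix is symmetric by construction. A
#' channel with zero variance has no defined correlation and raises an error
#' naming the channel — silent NaN propagation is forbidden, since all
#' channels are retained throughout the pipeline.
#'
#' @param segment a [Segment-class] with at least 3 samples.
#' @return A [BFN-class] with `nSegmentsAveraged = 1`.
#' @examples
#' seg <- new("Segment", subjectId = "S1", view = "OXY", state = "RHT",
#'            trialIndex = 1L, data = cbind(a = 1:5, b = c(2, 4, 6, 8, 10),
#'                                          c = 5:1), samplingRate = 1)
#' edgeWeights(pearsonNetwork(seg))
#' @export
pearsonNetwork <- function(segment) {
  stopifnot(is(segment, "Segment"))
  X <- segment@data
  if (nrow(X) < 3L)
    stopf("need >= 3 samples to estimate correlations (got %d)", nrow(X))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    labs <- if (!is.null(colnames(X))) colnames(X)[bad] else as.character(bad)
    stopf("zero-variance channel(s) %s in trial %d (%s): correlation undefined",
          paste(labs, collapse = ", "), segment@trialIndex, segment@state)
  }
  W <- stats::cor(X)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  new("BFN", weights = W, classLabel = segment@state,
      subjectId = segment@subjectId, view = segment@view,
      nSegmentsAveraged = 1L)
}

#' Average networks by class into a subject's fingerprints
#'
#' Groups a subject's single-segment networks by class label and averages
#' them element-wise within each class, producing one fingerprint per class
#' (the subject's four task fingerprints under the default paradigm: 25
#' networks averaged per task class and 75 for rest). Raw correlation
#' elements are averaged; `fisherZ = TRUE` averages on the Fisher z scale
#' and transforms back.
#'
#' @param bfns list of [BFN-class] from one subject and view.
#' @param fisherZ average on the Fisher z scale instead of raw correlations.
#' @return A [FingerprintSet-class].
#' @examples
#' par <- paradigmConfig(nSubjects = 1, nSessions = 1, trialsPerSession = 3)
#' rec <- simulateRecording(sampleSubjectProfile(par, 1),
#'                          makeTrialSchedule(par, 1), par, noiseModel(),
#'                          "OXY", seed = 1)
#' fp <- groupAndAverage(lapply(segmentTrials(rec), pearsonNetwork))
#' names(fingerprints(fp))
#' @export
groupAndAverage <- function(bfns, fisherZ = FALSE) {
  if (!length(bfns)) stopf("no networks to average")
  stopifnot(all(vapply(bfns, is, logical(1), "BFN")))
  sids <- unique(vapply(bfns, function(b) b@subjectId, character(1)))
  views <- unique(vapply(bfns, function(b) b@view, character(1)))
  if (length(sids) != 1L || length(views) != 1L)
    stopf("cannot average networks from mixed subjects (%s) or views (%s)",
          paste(sids, collapse = ", "), paste(views, collapse = ", "))
  dims <- unique(vapply(bfns, function(b) nrow(b@weights), integer(1)))
  if (length(dims) != 1L) stopf("networks differ in dimension")
  classes <- vapply(bfns, function(b) b@classLabel, character(1))
  fps <- lapply(split(bfns, classes), function(group) {
    Ws <- lapply(group, function(b) b@weights)
    if (fisherZ) {
      Z <- Reduce(`+`, lapply(Ws, function(W) atanh(pmin(pmax(W, -1 + 1e-15),
                                                         1 - 1e-15))))
      M <- tanh(Z / length(Ws))
    } else {
      M <- Reduce(`+`, Ws) / length(Ws)
    }
    M <- (M + t(M)) / 2
    diag(M) <- 1
    new("BFN", weights = M, classLabel = group[[1]]@classLabel,
        subjectId = sids, view = views,
        nSegmentsAveraged = length(group))
  })
  new("FingerprintSet", subjectId = sids, view = views, fingerprints = fps)
}

#' Full fingerprint estimation for one recording
#'
#' Convenience wrapper running the full per-recording path in the canonical
#' order: band-pass filter, global-signal removal, trial segmentation,
#' per-segment Pearson network, class averaging.
#'
#' @param recording a raw [Recording-class].
#' @param spec a [FilterSpec-class].
#' @param restWindow rest epoch duration in seconds.
#' @param causal passed to [bandpass()].
#' @param fisherZ passed to [groupAndAverage()].
#' @return A [FingerprintSet-class].
#' @export
estimateFingerprints <- function(recording, spec = filterSpec(),
                                 restWindow = 15.0, causal = FALSE,
                                 fisherZ = FALSE) {
  pre <- preprocessRecording(recording, spec, causal = causal)
  segs <- segmentTrials(pre, restWindow = restWindow)
  groupAndAverage(lapply(segs, pearsonNetwork), fisherZ = fisherZ)
}
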