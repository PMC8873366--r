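## Nearest-neighbour individual identification.

bfnVector <- function(bfn, vectorization = c("upper", "full")) {
  vectorization <- match.arg(vectorization)
  W <- bfn@weights
  if (vectorization == "upper") W[upper.tri(W)] else as.numeric(W)
}

#' Similarity between two networks
#'
#' Pearson correlation between the two networks' edge-weight vectors. By
#' default only the strictly upper-triangular off-diagonal weights enter: the
#' unit diagonal is constant across all networks and the lower triangle
#' duplicates the upper, so including them inflates similarity without adding
#' information. `vectorization = "full"` flattens the whole matrix instead.
#'
#' @param a,b [BFN-class] objects of the same dimension.
#' @param vectorization `"upper"` (default) or `"full"`.
#' @return Similarity value in [-1, 1]; symmetric in its arguments.
#' @examples
#' mkb <- function(v) new("BFN", weights = {
#'   W <- diag(3); W[upper.tri(W)] <- v; W[lower.tri(W)] <- t(W)[lower.tri(W)]; W
#' }, classLabel = "RHT", subjectId = "S1", view = "OXY",
#'    nSegmentsAveraged = 1L)
#' similarity(mkb(c(.1, .2, .3)), mkb(c(.3, .2, .1)))   # -1
#' @export
similarity <- function(a, b, vectorization = c("upper", "full")) {
  stopifnot(is(a, "BFN"), is(b, "BFN"))
  if (!identical(dim(a@weights), dim(b@weights)))
    stopf("networks differ in dimension (%d vs %d)",
          nrow(a@weights), nrow(b@weights))
  va <- bfnVector(a, vectorization)
  vb <- bfnVector(b, vectorization)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stopf("similarity undefined: a network has zero edge-weight variance")
  stats::cor(va, vb)
}

#' Predict a target network's identity by nearest neighbour
#'
#' Returns the subject whose source network is most similar to the target
#' (the argmax of the similarity over the source set). Exact ties are broken
#' toward the lowest subject index in the source set, with a warning.
#'
#' @param target a [BFN-class].
#' @param sourceSet list of [BFN-class], exactly one per subject.
#' @param vectorization passed to [similarity()].
#' @return The predicted subject identifier (character scalar), with the
#'   similarity vector attached as attribute `"similarities"`.
#' @export
predictIdentity <- function(target, sourceSet,
                            vectorization = c("upper", "full")) {
  if (!length(sourceSet)) stopf("empty source set")
  ids <- vapply(sourceSet, function(b) b@subjectId, character(1))
  if (anyDuplicated(ids))
    stopf("duplicate subject id(s) in source set: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sims <- vapply(sourceSet, function(s) similarity(target, s, vectorization),
                 numeric(1))
  best <- which(sims == max(sims))
  if (length(best) > 1L)
    warning(sprintf("similarity tie between %s; picking the first",
                    paste(ids[best], collapse = ", ")), call. = FALSE)
  structure(ids[best[1L]], similarities = stats::setNames(sims, ids))
}

findFingerprint <- function(fpSets, subject, class, viewLabel) {
  for (fs in fpSets) {
    if (fs@subjectId == subject && fs@view == viewLabel &&
        class %in% names(fs@fingerprints))
      return(fs@fingerprints[[class]])
  }
  stopf("no %s/%s fingerprint for subject %s", class, viewLabel, subject)
}

#' Run one identification mode over a cohort
#'
#' For every subject, takes its target-class/target-view fingerprint and
#' matches it by nearest neighbour against the source set assembled from all
#' subjects' source-class/source-view fingerprints. The prediction score of a
#' subject is 1 if the predicted identity equals the true one and 0
#' otherwise; accuracy is the sum of scores over the number of subjects. The
#' full targets x sources similarity table is retained.
#'
#' @param mode a [ModeSpec-class].
#' @param fpSets list of [FingerprintSet-class] covering every subject in the
#'   classes and views the mode requires.
#' @param vectorization passed to [similarity()].
#' @return An [IdentificationResult-class].
#' @export
runMode <- function(mode, fpSets, vectorization = c("upper", "full")) {
  stopifnot(is(mode, "ModeSpec"))
  subjects <- unique(vapply(fpSets, function(x) x@subjectId, character(1)))
  if (!length(subjects)) stopf("no fingerprint sets supplied")
  sourceSet <- lapply(subjects, findFingerprint, fpSets = fpSets,
                      class = mode@sourceClass, viewLabel = mode@sourceView)
  preds <- character(length(subjects))
  simTab <- matrix(NA_real_, length(subjects), length(subjects),
                   dimnames = list(target = subjects, source = subjects))
  for (i in seq_along(subjects)) {
    target <- findFingerprint(fpSets, subjects[i], mode@targetClass,
                              mode@targetView)
    p <- predictIdentity(target, sourceSet, vectorization)
    preds[i] <- as.character(p)
    simTab[i, ] <- attr(p, "similarities")
  }
  names(preds) <- subjects
  scores <- as.numeric(preds == subjects)
  names(scores) <- subjects
  new("IdentificationResult", mode = mode, predictions = preds,
      scores = scores, nCorrect = as.integer(sum(scores)),
      accuracy = sum(scores) / length(subjects), similarityTable = simTab)
}

accuracyMatrix <- function(fpSets, classes, sourceView, targetView,
                           vectorization) {
  acc <- matrix(NA_real_, length(classes), length(classes),
                dimnames = list(target = classes, source = classes))
  for (tgt in classes) for (src in classes) {
    res <- runMode(modeSpec(src, tgt, sourceView, targetView), fpSets,
                   vectorization)
    acc[tgt, src] <- res@accuracy
  }
  acc
}

#' Cross-task accuracy matrix
#'
#' Identification accuracy for every ordered (source class, target class)
#' pair within one view: 16 modes over the three tasks plus rest. Rows are
#' target sets, columns are source sets.
#'
#' @param fpSets list of [FingerprintSet-class].
#' @param view the view to evaluate.
#' @param classes class labels defining the matrix order.
#' @param vectorization passed to [similarity()].
#' @return 4 x 4 numeric matrix (targets x sources) of accuracies.
#' @export
crossTaskMatrix <- function(fpSets, view = "OXY",
                            classes = c("RHT", "LHT", "FT", "REST"),
                            vectorization = c("upper", "full")) {
  accuracyMatrix(fpSets, classes, sourceView = view, targetView = view,
                 vectorization = vectorization)
}

#' Cross-view accuracy matrix
#'
#' Identification accuracy for every ordered class pair with the source set
#' drawn from one hemoglobin view and the target set from the other. With
#' `sourceView == targetView` this reduces exactly to [crossTaskMatrix()].
#'
#' @param fpSets list of [FingerprintSet-class] covering both views.
#' @param sourceView,targetView views of the source and target sets.
#' @param classes class labels defining the matrix order.
#' @param vectorization passed to [similarity()].
#' @return 4 x 4 numeric matrix (targets x sources) of accuracies.
#' @export
crossViewMatrix <- function(fpSets, sourceView = "OXY", targetView = "DEOXY",
                            classes = c("RHT", "LHT", "FT", "REST"),
                            vectorization = c("upper", "full")) {
  accuracyMatrix(fpSets, classes, sourceView = sourceView,
                 targetView = targetView, vectorization = vectorization)
}

#' Summarise an accuracy matrix
#'
#' Mean and standard deviation over the matrix cells. The diagonal of a
#' same-view matrix is the trivial self-match (accuracy 1 by construction),
#' so the default summarises off-diagonal cells only; both variants are
#' informative and callers should report which they used.
#'
#' @param mat numeric accuracy matrix.
#' @param includeDiagonal include the diagonal cells.
#' @return Named numeric vector `c(mean = ..., sd = ...)`.
#' @examples
#' summarizeAccuracy(matrix(c(1, .9, .8, 1), 2))
#' @export
summarizeAccuracy <- function(mat, includeDiagonal = FALSE) {
  stopifnot(is.matrix(mat), length(mat) > 0)
  cells <- if (includeDiagonal) as.numeric(mat) else mat[row(mat) != col(mat)]
  if (!length(cells)) cells <- as.numeric(mat)
  c(mean = mean(cells), sd = stats::sd(cells))
}
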