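## Interchange formats and the end-to-end pipeline driver.
##
## Native interchange is a plain-text pair: a TSV holding the signal matrix
## (header row of channel labels, one row per sample) and a JSON sidecar
## holding subject, view, sampling rate, trial schedule and provenance
## metadata. Sample indices in the sidecar are 1-based, matching R. An
## adapter for other acquisition formats (e.g. SNIRF exports) would plug in
## by constructing a Recording from its time series and onsets and calling
## writeRecording().

fmtMatrix <- function(m) {
  apply(m, c(1, 2), function(x) sprintf("%.17g", x))
}

#' Write / read a recording (TSV + JSON sidecar)
#'
#' `writeRecording` writes `<prefix>.tsv` (signal matrix, full precision) and
#' `<prefix>.json` (subject, view, sampling rate, channel labels, schedule,
#' metadata). `readRecording` reads the pair back, validating that the two
#' files agree; the round trip reproduces the data to full precision.
#'
#' @param recording a [Recording-class].
#' @param prefix file path without extension.
#' @return `writeRecording` returns `prefix` invisibly; `readRecording`
#'   returns the [Recording-class].
#' @examples
#' par <- paradigmConfig(nSubjects = 1, nSessions = 1, trialsPerSession = 3)
#' rec <- simulateRecording(sampleSubjectProfile(par, 1),
#'                          makeTrialSchedule(par, 1), par, noiseModel(),
#'                          "OXY", seed = 1)
#' pre <- file.path(tempdir(), "rec")
#' writeRecording(rec, pre)
#' rec2 <- readRecording(pre)
#' identical(signalMatrix(rec), signalMatrix(rec2))
#' @export
writeRecording <- function(recording, prefix) {
  stopifnot(is(recording, "Recording"))
  utils::write.table(fmtMatrix(recording@data), paste0(prefix, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = recording@channelLabels)
  sch <- recording@schedule
  sidecar <- list(
    subjectId = recording@subjectId,
    view = recording@view,
    samplingRate = recording@samplingRate,
    channelLabels = recording@channelLabels,
    nSamples = nrow(recording@data),
    schedule = list(introDuration = sch@introDuration,
                    taskDuration = sch@taskDuration,
                    samplingRate = sch@samplingRate,
                    trials = sch@trials),
    metadata = recording@metadata)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname writeRecording
#' @export
readRecording <- function(prefix) {
  tsv <- paste0(prefix, ".tsv")
  sc <- paste0(prefix, ".json")
  if (!file.exists(tsv)) stopf("signal file not found: %s", tsv)
  if (!file.exists(sc)) stopf("missing JSON sidecar: %s", sc)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  X <- as.matrix(utils::read.delim(tsv, check.names = FALSE))
  if (ncol(X) != length(side$channelLabels))
    stopf("shape mismatch: TSV has %d columns but sidecar lists %d channels",
          ncol(X), length(side$channelLabels))
  if (nrow(X) != side$nSamples)
    stopf("shape mismatch: TSV has %d rows but sidecar records %d samples",
          nrow(X), side$nSamples)
  if (!all(is.finite(X)))
    stopf("non-finite values in %s", tsv)
  trials <- as.data.frame(side$schedule$trials)
  trials$onset <- as.integer(trials$onset)
  trials$nSamples <- as.integer(trials$nSamples)
  trials$session <- as.integer(trials$session)
  trials$trial <- as.integer(trials$trial)
  schedule <- new("TrialSchedule", trials = trials,
                  introDuration = side$schedule$introDuration,
                  taskDuration = side$schedule$taskDuration,
                  samplingRate = side$schedule$samplingRate)
  colnames(X) <- side$channelLabels
  md <- side$metadata
  new("Recording", subjectId = side$subjectId, view = side$view, data = X,
      samplingRate = side$samplingRate, schedule = schedule,
      channelLabels = side$channelLabels,
      metadata = if (is.null(md)) list() else as.list(md))
}

#' Write / read a network (TSV + JSON sidecar)
#'
#' The weight matrix goes to `<prefix>.tsv` with a channel-label header; the
#' class label, subject, view and averaging count go to `<prefix>.json`.
#'
#' @param bfn a [BFN-class].
#' @param prefix file path without extension.
#' @return `writeBFN` returns `prefix` invisibly; `readBFN` the [BFN-class].
#' @export
writeBFN <- function(bfn, prefix) {
  stopifnot(is(bfn, "BFN"))
  labs <- colnames(bfn@weights)
  if (is.null(labs)) labs <- sprintf("CH%02d", seq_len(ncol(bfn@weights)))
  utils::write.table(fmtMatrix(bfn@weights), paste0(prefix, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = labs)
  jsonlite::write_json(list(subjectId = bfn@subjectId, view = bfn@view,
                            classLabel = bfn@classLabel,
                            nSegmentsAveraged = bfn@nSegmentsAveraged,
                            channelLabels = labs),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeBFN
#' @export
readBFN <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  W <- as.matrix(utils::read.delim(paste0(prefix, ".tsv"), check.names = FALSE))
  dimnames(W) <- list(side$channelLabels, side$channelLabels)
  new("BFN", weights = W, classLabel = side$classLabel,
      subjectId = side$subjectId, view = side$view,
      nSegmentsAveraged = as.integer(side$nSegmentsAveraged))
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: the acquisition paradigm, the
#' noise model and subject-effect scale of the simulator, the filter, the
#' rest window, the similarity vectorization, the experimental design, and a
#' master seed from which all stage seeds derive.
#'
#' @param paradigm a [ParadigmConfig-class].
#' @param noise a [NoiseModel-class].
#' @param filter a [FilterSpec-class].
#' @param restWindow rest epoch duration in seconds.
#' @param subjectEffect,kappa,viewDistortion,slowAmp simulator parameters
#'   (see [simulateRecording()]).
#' @param seed master seed; all stage seeds are derived from it.
#' @param views views to simulate and analyse.
#' @param design `"cross-task"`, `"cross-view"` or `"both"`.
#' @param vectorization similarity vectorization (see [similarity()]).
#' @param causal,fisherZ stage options (see [bandpass()], [groupAndAverage()]).
#' @return A named list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(paradigm = paradigmConfig(), noise = noiseModel(),
                           filter = filterSpec(), restWindow = 15.0,
                           subjectEffect = 1, kappa = 0.5,
                           viewDistortion = 0.5, slowAmp = 1, seed = 1L,
                           views = c("OXY", "DEOXY"),
                           design = c("both", "cross-task", "cross-view"),
                           vectorization = c("upper", "full"),
                           causal = FALSE, fisherZ = FALSE) {
  structure(list(paradigm = paradigm, noise = noise, filter = filter,
                 restWindow = restWindow, subjectEffect = subjectEffect,
                 kappa = kappa, viewDistortion = viewDistortion,
                 slowAmp = slowAmp, seed = as.integer(seed), views = views,
                 design = match.arg(design),
                 vectorization = match.arg(vectorization),
                 causal = causal, fisherZ = fisherZ),
            class = "PipelineConfig")
}

## Cheap deterministic checksum of the configuration for the manifest.
configChecksum <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 3))
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 97 + 1)) %% 4294967296)
}

#' Run the full pipeline
#'
#' Executes simulate -> preprocess -> segment -> fingerprint -> identify ->
#' report for a synthetic cohort: simulates the configured cohort, estimates
#' every subject's fingerprints in every configured view, computes the
#' cross-task accuracy matrix per view and/or the cross-view matrices in both
#' directions, and summarises them. A manifest records the configuration
#' checksum, all seeds and per-stage record counts. With `outDir` set, the
#' accuracy matrices (CSV), the results and the manifest (JSON) are
#' persisted.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir optional output directory.
#' @return List with elements `fingerprints` (list of
#'   [FingerprintSet-class]), `crossTask` (named list of matrices, one per
#'   view), `crossView` (named list of matrices, one per direction),
#'   `summaries` (off-diagonal mean/sd per matrix) and `manifest`.
#' @examples
#' cfg <- pipelineConfig(paradigm = paradigmConfig(nSubjects = 2,
#'                       nSessions = 1, trialsPerSession = 6),
#'                       subjectEffect = 3, seed = 1)
#' res <- runPipeline(cfg)
#' res$crossTask$OXY
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- "simulate"
  result <- tryCatch({
    cohort <- simulateCohort(config$paradigm, config$noise,
                             subjectEffect = config$subjectEffect,
                             masterSeed = config$seed, views = config$views,
                             kappa = config$kappa,
                             viewDistortion = config$viewDistortion,
                             slowAmp = config$slowAmp)
    stage <- "fingerprint"
    nSegments <- 0L
    fpSets <- list()
    for (subj in cohort) for (rec in subj) {
      pre <- preprocessRecording(rec, config$filter, causal = config$causal)
      segs <- segmentTrials(pre, restWindow = config$restWindow)
      nSegments <- nSegments + length(segs)
      fpSets[[length(fpSets) + 1L]] <-
        groupAndAverage(lapply(segs, pearsonNetwork), fisherZ = config$fisherZ)
    }
    stage <- "identify"
    crossTask <- list()
    crossView <- list()
    classes <- c(config$paradigm@taskLabels, "REST")
    if (config$design %in% c("both", "cross-task")) {
      for (v in config$views)
        crossTask[[v]] <- crossTaskMatrix(fpSets, view = v, classes = classes,
                                          vectorization = config$vectorization)
    }
    if (config$design %in% c("both", "cross-view") &&
        all(c("OXY", "DEOXY") %in% config$views)) {
      crossView[["OXY->DEOXY"]] <- crossViewMatrix(fpSets, "OXY", "DEOXY",
        classes = classes, vectorization = config$vectorization)
      crossView[["DEOXY->OXY"]] <- crossViewMatrix(fpSets, "DEOXY", "OXY",
        classes = classes, vectorization = config$vectorization)
    }
    stage <- "report"
    summaries <- lapply(c(crossTask, crossView), function(m) list(
      offDiagonal = summarizeAccuracy(m, includeDiagonal = FALSE),
      full = summarizeAccuracy(m, includeDiagonal = TRUE)))
    manifest <- list(
      package = "nirsBFN",
      version = as.character(utils::packageVersion("nirsBFN")),
      configChecksum = configChecksum(config),
      seed = config$seed,
      nSubjects = length(cohort),
      views = config$views,
      nRecordings = length(fpSets),
      segmentsPerRecording = nSegments / max(length(fpSets), 1L),
      fingerprintsPerRecording =
        length(fpSets[[1]]@fingerprints),
      accuracyMatrixCells = vapply(c(crossTask, crossView), length, integer(1)))
    list(fingerprints = fpSets, crossTask = crossTask, crossView = crossView,
         summaries = summaries, manifest = manifest)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(result$crossTask))
      utils::write.csv(result$crossTask[[nm]],
                       file.path(outDir, sprintf("cross_task_%s.csv", nm)))
    for (nm in names(result$crossView))
      utils::write.csv(result$crossView[[nm]],
                       file.path(outDir, sprintf("cross_view_%s.csv",
                                                 gsub("->", "_to_", nm))))
    jsonlite::write_json(result$summaries, file.path(outDir, "summaries.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(result$manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
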