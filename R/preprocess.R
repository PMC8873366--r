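## Preprocessing: Butterworth band-pass + global-signal baseline correction.

## Settling length (samples) used both for the minimum-length precondition and
## for the reflective padding: half a period of the low cut-off, ample for the
## third-order transient.
settlingSamples <- function(spec, fs) as.integer(ceiling(0.5 * fs / spec@lowCut))

#' Band-pass filter a recording
#'
#' Applies a Butterworth band-pass (third order, 0.01--0.1 Hz by default) to
#' every channel independently. By default filtering is zero-phase
#' (forward-backward), which leaves no inter-channel lag to distort later
#' correlation estimates but squares the magnitude response; `causal = TRUE`
#' restores a single forward pass. Start-up transients are suppressed by
#' odd-reflection padding of one settling length (one period of the low
#' cut-off) at each end, trimmed after filtering.
#'
#' @param recording a [Recording-class].
#' @param spec a [FilterSpec-class].
#' @param causal single forward pass instead of zero-phase filtering.
#' @return The filtered [Recording-class]; metadata records the filter.
#' @examples
#' par <- paradigmConfig(nSubjects = 1, nSessions = 1, trialsPerSession = 12)
#' rec <- simulateRecording(sampleSubjectProfile(par, 1),
#'                          makeTrialSchedule(par, 1), par, noiseModel(),
#'                          "OXY", seed = 1)
#' filt <- bandpass(rec, filterSpec())
## Butterworth band-pass as a cascade of second-order sections. The 0.01 Hz
## edge puts poles within 0.002 of the unit circle, where a single
## sixth-order recursion loses several digits; biquads keep the recursion
## well conditioned. Zeros (order copies at z = 1 and z = -1) contribute
## (1, 0, -1) numerators; the gain is spread evenly over the sections.
butterBandSos <- function(spec, fs) {
  n <- spec@order
  Wt <- 2 / 2 * tan(pi * (c(spec@lowCut, spec@highCut) / (fs / 2)) / 2)
  pole <- exp(1i * pi * (2 * seq_len(n) + n - 1) / (2 * n))
  if (n %% 2 == 1) pole[(n + 1) / 2] <- -1
  zpg <- signal::bilinear(
    signal::sftrans(signal::Zpg(zero = numeric(0), pole = pole, gain = 1),
                    W = Wt, stop = FALSE), T = 2)
  p <- zpg$pole
  cplx <- p[Im(p) > 1e-12]
  reals <- sort(Re(p[abs(Im(p)) <= 1e-12]))
  pairs <- lapply(cplx, function(pc) c(pc, Conj(pc)))
  while (length(reals) >= 2) {
    pairs[[length(pairs) + 1L]] <- c(reals[1], reals[length(reals)])
    reals <- reals[-c(1, length(reals))]
  }
  g <- Re(zpg$gain)^(1 / length(pairs))
  lapply(pairs, function(pp) list(
    b = g * c(1, 0, -1),
    a = c(1, -Re(pp[1] + pp[2]), Re(pp[1] * pp[2]))))
}

sosApply <- function(sos, x) {
  for (s in sos) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

#' @export
bandpass <- function(recording, spec = filterSpec(), causal = FALSE) {
  stopifnot(is(recording, "Recording"), is(spec, "FilterSpec"))
  fs <- recording@samplingRate
  if (spec@highCut >= fs / 2)
    stopf("highCut %.3g Hz violates the Nyquist limit of samplingRate %.4f Hz",
          spec@highCut, fs)
  pad <- settlingSamples(spec, fs)
  n <- nrow(recording@data)
  if (n < 3L * pad)
    stopf(paste0("recording too short for stable filtering: %d samples < 3",
                 " settling lengths (3 x %d samples at lowCut %.3g Hz)"),
          n, pad, spec@lowCut)
  sos <- butterBandSos(spec, fs)
  filt1 <- function(x) {
    ## the filter blocks DC, so demeaning leaves the ideal output unchanged
    ## while removing the step that excites the slow start-up transient;
    ## odd reflection about each endpoint smooths what remains
    x <- x - mean(x)
    xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    y <- sosApply(sos, xp)
    if (!causal) y <- rev(sosApply(sos, rev(y)))
    y[(pad + 1L):(pad + n)]
  }
  out <- recording
  out@data <- apply(recording@data, 2, filt1)
  colnames(out@data) <- recording@channelLabels
  out@metadata <- c(recording@metadata, list(
    bandpass = list(lowCut = spec@lowCut, highCut = spec@highCut,
                    order = spec@order, family = spec@family,
                    zeroPhase = !causal)))
  validObject(out)
  out
}

#' Remove the global signal
#'
#' Baseline correction by subtracting, at every time point, the mean over all
#' channels (the global signal) from every channel. After correction the
#' channel mean at each time point is exactly zero; systemic physiology that
#' is spatially uniform is removed entirely. The operation is idempotent.
#'
#' @param recording a [Recording-class] with at least 2 channels.
#' @return The corrected [Recording-class]; metadata records the step.
#' @examples
#' par <- paradigmConfig(nSubjects = 1, nSessions = 1, trialsPerSession = 3)
#' rec <- simulateRecording(sampleSubjectProfile(par, 1),
#'                          makeTrialSchedule(par, 1), par, noiseModel(),
#'                          "OXY", seed = 1)
#' cor0 <- removeGlobalSignal(rec)
#' max(abs(rowMeans(signalMatrix(cor0))))  # ~0
#' @export
removeGlobalSignal <- function(recording) {
  stopifnot(is(recording, "Recording"))
  if (ncol(recording@data) < 2L)
    stopf("global-signal correction needs >= 2 channels (got %d)",
          ncol(recording@data))
  out <- recording
  out@data <- recording@data - rowMeans(recording@data)
  out@metadata <- c(recording@metadata, list(globalSignalRemoved = TRUE))
  out
}

#' Preprocess a recording (filter, then baseline-correct)
#'
#' Canonical preprocessing order: band-pass filtering first, global-signal
#' subtraction second. The order is enforced here and recorded in metadata.
#'
#' @inheritParams bandpass
#' @return The preprocessed [Recording-class].
#' @export
preprocessRecording <- function(recording, spec = filterSpec(), causal = FALSE) {
  removeGlobalSignal(bandpass(recording, spec, causal = causal))
}
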