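#' @useDynLib thetaSME, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats coef dist fft lm median nextn predict pt qt quantile
#'   residuals rlnorm rnorm rpois runif sd t.test var
#' @importFrom utils head read.delim write.table
NULL

# ---- configuration value classes -------------------------------------------

#' Arena geometry for the virtual treasure-hunt environment
#'
#' The rectangular virtual beach in which chests appear, measured in the
#' task's internal "virtual units". Retrieval takes place from an elevated
#' viewpoint at one of the two short ends of the arena.
#'
#' @slot width arena extent along x (virtual units)
#' @slot height arena extent along y (virtual units)
#' @slot responseCircleRadius radius of the response target circle used for
#'   the in-task correct/incorrect feedback (virtual units)
#' @slot viewpoints 2 x 2 matrix of retrieval viewpoint coordinates (rows =
#'   the two viewpoints, columns = x, y), at opposite short ends
#' @export
setClass("ArenaConfig", representation(
  width = "numeric", height = "numeric",
  responseCircleRadius = "numeric", viewpoints = "matrix"
))

setValidity("ArenaConfig", function(object) {
  msg <- NULL
  if (object@width <= 0 || object@height <= 0)
    msg <- c(msg, "arena width and height must be positive")
  if (object@responseCircleRadius <= 0 ||
      object@responseCircleRadius >= min(object@width, object@height) / 2)
    msg <- c(msg, "responseCircleRadius must lie in (0, min(width, height)/2)")
  if (!all(dim(object@viewpoints) == c(2L, 2L)))
    msg <- c(msg, "exactly two retrieval viewpoints (2 x 2 matrix) required")
  if (is.null(msg)) TRUE else msg
})

#' Construct an arena configuration
#'
#' Defaults reproduce the task's 100 x 70 virtual-unit beach with a
#' 13-unit response circle and retrieval viewpoints centred on the two
#' short ends.
#'
#' @param width,height arena size in virtual units
#' @param responseCircleRadius response circle radius in virtual units
#' @param viewpoints 2 x 2 matrix of viewpoint coordinates; default places
#'   them at the midpoints of the two short (x = 0 and x = width) ends
#' @return an [ArenaConfig-class] object
#' @examples
#' arenaConfig()
#' @export
arenaConfig <- function(width = 100, height = 70, responseCircleRadius = 13,
                        viewpoints = NULL) {
  if (is.null(viewpoints))
    viewpoints <- rbind(c(0, height / 2), c(width, height / 2))
  new("ArenaConfig", width = width, height = height,
      responseCircleRadius = responseCircleRadius,
      viewpoints = viewpoints)
}

#' Task design parameters
#'
#' @slot nTrials trials per session
#' @slot chestsPerTrial chests visited per trial
#' @slot nObjectChests chests containing an object per session
#' @slot nEmptyChests empty chests per session
#' @slot itemDisplayMs duration of the item display after a chest opens (ms)
#' @slot movementFraction target fraction of navigation timepoints spent in
#'   motion
#' @export
setClass("TaskConfig", representation(
  nTrials = "integer", chestsPerTrial = "integer",
  nObjectChests = "integer", nEmptyChests = "integer",
  itemDisplayMs = "numeric", movementFraction = "numeric"
))

setValidity("TaskConfig", function(object) {
  msg <- NULL
  tot <- object@nTrials * object@chestsPerTrial
  if (object@nObjectChests + object@nEmptyChests != tot)
    msg <- c(msg, "object + empty chest totals must equal nTrials * chestsPerTrial")
  # with 4 chests/trial, 2-3 objects per trial bounds the session totals
  n3 <- object@nObjectChests - 2L * object@nTrials
  if (n3 < 0L || n3 > object@nTrials)
    msg <- c(msg, "totals unreachable with 2-3 object chests per trial")
  if (object@movementFraction <= 0 || object@movementFraction > 1)
    msg <- c(msg, "movementFraction must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Construct a task configuration
#'
#' Defaults are the full session design: 40 trials of 4 chests each,
#' 100 object chests and 60 empty chests, 1500-ms item displays.
#'
#' @param nTrials,chestsPerTrial,nObjectChests,nEmptyChests session design
#'   counts; the totals must be reachable with 2-3 object chests per trial
#' @param itemDisplayMs item display duration in ms
#' @param movementFraction fraction of navigation samples in motion
#' @return a [TaskConfig-class] object
#' @examples
#' taskConfig()                 # full 160-chest session
#' taskConfig(nTrials = 10)     # shortened session for simulations
#' @export
taskConfig <- function(nTrials = 40, chestsPerTrial = 4,
                       nObjectChests = NULL, nEmptyChests = NULL,
                       itemDisplayMs = 1500, movementFraction = 0.96) {
  nTrials <- as.integer(nTrials); chestsPerTrial <- as.integer(chestsPerTrial)
  if (is.null(nObjectChests)) nObjectChests <- as.integer(round(2.5 * nTrials))
  if (is.null(nEmptyChests))
    nEmptyChests <- nTrials * chestsPerTrial - as.integer(nObjectChests)
  new("TaskConfig", nTrials = nTrials, chestsPerTrial = chestsPerTrial,
      nObjectChests = as.integer(nObjectChests),
      nEmptyChests = as.integer(nEmptyChests),
      itemDisplayMs = itemDisplayMs, movementFraction = movementFraction)
}

#' Behavioral response model for the simulator
#'
#' Ground-truth memory success is drawn first (Bernoulli per studied item);
#' the placement error and the confidence report are then drawn conditional
#' on it, so planted neural gains and behavioral labels agree by
#' construction. Remembered items receive an isotropic Gaussian placement
#' error; forgotten items respond uniformly at random with probability
#' \code{guessRate} and with an inflated Gaussian error otherwise.
#' Confidence degrades stochastically with the realized error.
#'
#' @slot pRemember probability an object is encoded successfully
#' @slot errorSd placement error SD for remembered items (virtual units)
#' @slot guessRate probability a forgotten item draws a uniform response
#' @slot confYes,confMaybe error thresholds (virtual units) below which the
#'   reported confidence tends to "Yes" / "Maybe"
#' @slot confSlack SD of the noise added to the error before thresholding,
#'   so confidence only degrades with error in expectation
#' @export
setClass("BehaviorModel", representation(
  pRemember = "numeric", errorSd = "numeric", guessRate = "numeric",
  confYes = "numeric", confMaybe = "numeric", confSlack = "numeric"
))

setValidity("BehaviorModel", function(object) {
  msg <- NULL
  if (object@errorSd <= 0) msg <- c(msg, "errorSd must be positive")
  if (object@guessRate < 0 || object@guessRate > 1)
    msg <- c(msg, "guessRate must lie in [0, 1]")
  if (object@confYes >= object@confMaybe)
    msg <- c(msg, "confYes threshold must be below confMaybe")
  if (is.null(msg)) TRUE else msg
})

#' @rdname BehaviorModel-class
#' @param pRemember,errorSd,guessRate,confYes,confMaybe,confSlack see slots
#' @return a [BehaviorModel-class] object
#' @export
behaviorModel <- function(pRemember = 0.5, errorSd = 6, guessRate = 0.5,
                          confYes = 12, confMaybe = 28, confSlack = 6) {
  new("BehaviorModel", pRemember = pRemember, errorSd = errorSd,
      guessRate = guessRate, confYes = confYes, confMaybe = confMaybe,
      confSlack = confSlack)
}

#' Neural signal model for the simulator
#'
#' Each physical contact receives independent power-law background noise
#' plus Hann-windowed oscillatory bursts whose amplitude depends on the
#' behavioral epoch: during encoding of subsequently remembered items the
#' burst amplitude is multiplied by the hemisphere's memory gain, during
#' navigation by the hemisphere's navigation gain; forgotten-item encoding
#' and pre-trial baselines receive unit-gain bursts. A 60-Hz line sinusoid,
#' Poisson transient artifacts, and a broadband 40-100-Hz component during
#' item displays complete the signal. All gains equal to 1 yields a null
#' recording in which every downstream contrast is centred on zero.
#'
#' @slot backgroundExponent power-law exponent of the background spectrum
#'   (power ~ 1/f^exponent)
#' @slot oscFreqHz planted burst frequency (Hz)
#' @slot leftMemoryGain,rightMemoryGain burst-amplitude factors for
#'   remembered-item encoding epochs, per hemisphere
#' @slot leftNavGain,rightNavGain burst-amplitude factors for navigation
#'   epochs, per hemisphere
#' @slot lineNoiseAmp 60-Hz sinusoid amplitude (uV)
#' @slot artifactRate transient high-amplitude artifacts per minute
#' @slot hfaItemGain multiplicative 40-100-Hz amplitude factor during
#'   object-item displays (empty-chest displays receive unit gain)
#' @slot burstAmp baseline burst amplitude (uV)
#' @slot burstRate expected bursts per second within an epoch
#' @slot noiseSd background noise SD (uV)
#' @slot hfaAmp baseline 40-100-Hz component amplitude during chest
#'   displays (uV)
#' @export
setClass("NeuralModel", representation(
  backgroundExponent = "numeric", oscFreqHz = "numeric",
  leftMemoryGain = "numeric", rightMemoryGain = "numeric",
  leftNavGain = "numeric", rightNavGain = "numeric",
  lineNoiseAmp = "numeric", artifactRate = "numeric", hfaItemGain = "numeric",
  burstAmp = "numeric", burstRate = "numeric", noiseSd = "numeric",
  hfaAmp = "numeric"
))

setValidity("NeuralModel", function(object) {
  msg <- NULL
  gains <- c(object@leftMemoryGain, object@rightMemoryGain,
             object@leftNavGain, object@rightNavGain, object@hfaItemGain)
  if (any(gains < 0)) msg <- c(msg, "all gains must be >= 0")
  if (object@oscFreqHz < 1 || object@oscFreqHz > 50)
    msg <- c(msg, "oscFreqHz must lie within 1-50 Hz")
  if (object@backgroundExponent < 0)
    msg <- c(msg, "backgroundExponent must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' @rdname NeuralModel-class
#' @param backgroundExponent,oscFreqHz,leftMemoryGain,rightMemoryGain,leftNavGain,rightNavGain,lineNoiseAmp,artifactRate,hfaItemGain,burstAmp,burstRate,noiseSd,hfaAmp
#'   see slots; defaults are the null model (all gains 1)
#' @return a [NeuralModel-class] object
#' @examples
#' neuralModel()                                    # null model
#' neuralModel(leftMemoryGain = 2, rightNavGain = 2) # lateralized effects
#' @export
neuralModel <- function(backgroundExponent = 2, oscFreqHz = 3,
                        leftMemoryGain = 1, rightMemoryGain = 1,
                        leftNavGain = 1, rightNavGain = 1,
                        lineNoiseAmp = 2, artifactRate = 0, hfaItemGain = 1,
                        burstAmp = 12, burstRate = 1, noiseSd = 10,
                        hfaAmp = 2) {
  new("NeuralModel", backgroundExponent = backgroundExponent,
      oscFreqHz = oscFreqHz, leftMemoryGain = leftMemoryGain,
      rightMemoryGain = rightMemoryGain, leftNavGain = leftNavGain,
      rightNavGain = rightNavGain, lineNoiseAmp = lineNoiseAmp,
      artifactRate = artifactRate, hfaItemGain = hfaItemGain,
      burstAmp = burstAmp, burstRate = burstRate, noiseSd = noiseSd,
      hfaAmp = hfaAmp)
}

# ---- data container classes ------------------------------------------------

#' A simulated (or imported) task session
#'
#' Holds the event timeline (chest displays, navigation epochs, pre-trial
#' baselines) and the retrieval responses of one subject-session.
#'
#' The \code{events} table has one row per event with columns \code{type}
#' (\code{"encoding"}, \code{"no_item"}, \code{"navigation"},
#' \code{"baseline"}), \code{trial}, \code{onset_ms}, \code{offset_ms},
#' \code{x}, \code{y}, \code{object_id}, \code{item} and \code{remembered}
#' (simulator ground truth; NA off chest events). The \code{responses}
#' table has one row per probed object: true and reported locations,
#' confidence, and the trial's retrieval viewpoint index.
#'
#' @slot subject subject identifier
#' @slot session session identifier
#' @slot arena the [ArenaConfig-class] used
#' @slot task the [TaskConfig-class] used
#' @slot events event timeline data.frame
#' @slot responses retrieval response data.frame
#' @slot durationS total session duration (s)
#' @export
setClass("TaskSession", representation(
  subject = "character", session = "character",
  arena = "ArenaConfig", task = "TaskConfig",
  events = "data.frame", responses = "data.frame", durationS = "numeric"
))

setValidity("TaskSession", function(object) {
  ev <- object@events
  msg <- NULL
  need <- c("type", "trial", "onset_ms", "offset_ms", "x", "y",
            "object_id", "item", "remembered")
  if (!all(need %in% names(ev)))
    msg <- c(msg, paste("events table missing columns:",
                        paste(setdiff(need, names(ev)), collapse = ", ")))
  else {
    if (any(ev$offset_ms <= ev$onset_ms))
      msg <- c(msg, "event offsets must exceed onsets")
    on <- sort(ev$onset_ms)
    if (is.unsorted(ev$onset_ms[order(ev$trial, ev$onset_ms)]))
      msg <- c(msg, "event onsets must increase within trials")
  }
  if (is.null(msg)) TRUE else msg
})

#' Multichannel voltage recording
#'
#' @slot data channels x samples voltage matrix (uV)
#' @slot fs sampling rate (Hz)
#' @slot channels per-channel metadata data.frame (id, probe, contact, x, y,
#'   z, hemisphere, region, soz)
#' @export
setClass("Recording", representation(
  data = "matrix", fs = "numeric", channels = "data.frame"
))

setValidity("Recording", function(object) {
  msg <- NULL
  if (nrow(object@data) != nrow(object@channels))
    msg <- c(msg, "one metadata row per channel required")
  if (anyDuplicated(object@channels$id))
    msg <- c(msg, "channel ids must be unique")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Bipolar-referenced recording
#'
#' A [Recording-class] whose channels are virtual bipolar pairs; the
#' channel table additionally records the parent contact ids, and channel
#' coordinates are pair midpoints.
#'
#' @export
setClass("BipolarRecording", contains = "Recording")

#' A set of event-locked voltage epochs
#'
#' Epochs are stored as a list of channels x samples matrices (ragged
#' lengths allowed for variable-duration navigation/baseline epochs). The
#' stored slice covers the requested window plus a symmetric buffer used to
#' absorb wavelet edge effects; analysis operations act on the unbuffered
#' window.
#'
#' @slot epochs list of channels x samples matrices, one per retained event
#' @slot events metadata for retained events (plus a \code{kept} flag for
#'   events dropped at extraction)
#' @slot channels channel metadata inherited from the recording
#' @slot fs sampling rate (Hz)
#' @slot windowMs requested window relative to event onset, or NA for
#'   full-epoch (onset-to-offset) extraction
#' @slot bufferMs buffer attached to each side (ms)
#' @slot rejected events x channels logical rejection mask
#' @export
setClass("EpochSet", representation(
  epochs = "list", events = "data.frame", channels = "data.frame",
  fs = "numeric", windowMs = "numeric", bufferMs = "numeric",
  rejected = "matrix"
))

setValidity("EpochSet", function(object) {
  msg <- NULL
  if (length(object@epochs) != nrow(object@events))
    msg <- c(msg, "one epoch per event row required")
  if (!all(dim(object@rejected) ==
           c(length(object@epochs), nrow(object@channels))))
    msg <- c(msg, "rejection mask must be events x channels")
  if (is.null(msg)) TRUE else msg
})

#' Logarithmic wavelet frequency grid
#'
#' @slot frequencies strictly increasing, log-spaced frequencies (Hz)
#' @slot wavenumber Morlet wave number (cycles)
#' @export
setClass("FrequencyGrid", representation(
  frequencies = "numeric", wavenumber = "numeric"
))

setValidity("FrequencyGrid", function(object) {
  f <- object@frequencies
  msg <- NULL
  if (any(diff(f) <= 0)) msg <- c(msg, "frequencies must strictly increase")
  if (min(f) < 1) msg <- c(msg, "minimum frequency must be >= 1 Hz")
  if (length(f) > 2) {
    r <- diff(log(f))
    if (max(abs(r - r[1])) > 1e-9)
      msg <- c(msg, "frequencies must be logarithmically spaced")
  }
  if (object@wavenumber <= 0) msg <- c(msg, "wavenumber must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct a log-spaced frequency grid
#'
#' Defaults give the analysis grid of 50 logarithmically spaced
#' frequencies between 1 and 200 Hz with Morlet wave number 5.
#'
#' @param n number of frequencies
#' @param lo,hi frequency range (Hz)
#' @param wavenumber Morlet wave number (cycles per Gaussian SD window)
#' @return a [FrequencyGrid-class]
#' @examples
#' frequencyGrid()                    # 50 freqs, 1-200 Hz
#' frequencyGrid(10, 1, 10)           # classifier low-frequency set
#' @export
frequencyGrid <- function(n = 50, lo = 1, hi = 200, wavenumber = 5) {
  new("FrequencyGrid", frequencies = exp(seq(log(lo), log(hi), length.out = n)),
      wavenumber = wavenumber)
}

#' Spectral power tensor
#'
#' Events x channels x frequencies (x time bins) array of Morlet power with
#' its scale state. Scale transitions run raw -> log -> z only; z-scoring
#' statistics are computed over the normalization event set (encoding,
#' navigation, baseline) per session x channel x frequency (x time bin).
#'
#' @slot values numeric array, 3-D (events x channels x frequencies) or 4-D
#'   with trailing time-bin dimension
#' @slot scale one of "raw", "log", "z"
#' @slot events event metadata (type tags, labels, session, subject)
#' @slot channels channel metadata
#' @slot grid the [FrequencyGrid-class] used
#' @slot timesMs centres of time bins (ms, relative to event onset), or
#'   numeric(0) for time-averaged tensors
#' @slot grouping description of the z-scoring group structure
#' @export
setClass("PowerTensor", representation(
  values = "array", scale = "character", events = "data.frame",
  channels = "data.frame", grid = "FrequencyGrid", timesMs = "numeric",
  grouping = "character"
))

setValidity("PowerTensor", function(object) {
  d <- dim(object@values)
  msg <- NULL
  if (!length(d) %in% c(3L, 4L))
    msg <- c(msg, "values must be a 3-D or 4-D array")
  else {
    if (d[1] != nrow(object@events)) msg <- c(msg, "dim 1 must match events")
    if (d[2] != nrow(object@channels)) msg <- c(msg, "dim 2 must match channels")
    if (d[3] != length(object@grid@frequencies))
      msg <- c(msg, "dim 3 must match the frequency grid")
    if (length(d) == 4L && d[4] != length(object@timesMs))
      msg <- c(msg, "dim 4 must match timesMs")
  }
  if (!object@scale %in% c("raw", "log", "z"))
    msg <- c(msg, "scale must be raw, log or z")
  if (is.null(msg)) TRUE else msg
})

# ---- accessors and show methods --------------------------------------------

#' @describeIn TaskSession-class event timeline
#' @param x,object a TaskSession
#' @export
sessionEvents <- function(x) x@events

#' @describeIn TaskSession-class retrieval responses
#' @export
sessionResponses <- function(x) x@responses

#' @describeIn Recording-class voltage matrix (channels x samples)
#' @param x,object a Recording
#' @export
recordingData <- function(x) x@data

#' @describeIn Recording-class sampling rate in Hz
#' @export
sampleRate <- function(x) x@fs

#' Channel metadata of a recording, epoch set or power tensor
#' @param x a [Recording-class], [EpochSet-class] or [PowerTensor-class]
#' @return data.frame of per-channel metadata
#' @export
channelInfo <- function(x) x@channels

#' Event metadata of an epoch set or power tensor
#' @param x an [EpochSet-class] or [PowerTensor-class]
#' @return data.frame of per-event metadata
#' @export
eventInfo <- function(x) x@events

#' @describeIn PowerTensor-class the power array
#' @param x,object a PowerTensor
#' @export
powerValues <- function(x) x@values

#' @describeIn PowerTensor-class the scale state ("raw", "log" or "z")
#' @export
powerScale <- function(x) x@scale

#' @describeIn FrequencyGrid-class the frequency vector (Hz)
#' @param x,object a FrequencyGrid
#' @export
gridFrequencies <- function(x) x@frequencies

setMethod("show", "TaskSession", function(object) {
  ev <- object@events
  cat("TaskSession", object@subject, "/", object@session, "\n")
  cat(sprintf("  %d trials, %.1f s; events: %s\n",
              object@task@nTrials, object@durationS,
              paste(names(table(ev$type)), table(ev$type),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  %d retrieval responses\n", nrow(object@responses)))
})

setMethod("show", "Recording", function(object) {
  cat(class(object), ":", nrow(object@data), "channels x",
      ncol(object@data), "samples @", object@fs, "Hz (",
      sprintf("%.1f", ncol(object@data) / object@fs), "s )\n")
})

setMethod("show", "EpochSet", function(object) {
  cat("EpochSet:", length(object@epochs), "events x",
      nrow(object@channels), "channels @", object@fs, "Hz\n")
  if (!any(is.na(object@windowMs)))
    cat(sprintf("  window %g..%g ms + %g ms buffer\n",
                object@windowMs[1], object@windowMs[2], object@bufferMs))
  else cat(sprintf("  full-epoch (ragged) + %g ms buffer\n", object@bufferMs))
  cat(sprintf("  rejected: %.1f%%\n", 100 * mean(object@rejected)))
})

setMethod("show", "PowerTensor", function(object) {
  d <- dim(object@values)
  cat("PowerTensor [", object@scale, "]:",
      paste(d, collapse = " x "),
      if (length(d) == 4L) "(events x channels x freqs x time)\n"
      else "(events x channels x freqs)\n")
  f <- object@grid@frequencies
  cat(sprintf("  %d freqs %.3g-%.3g Hz; grouping: %s\n",
              length(f), min(f), max(f), object@grouping))
})

setMethod("show", "FrequencyGrid", function(object) {
  f <- object@frequencies
  cat(sprintf("FrequencyGrid: %d log-spaced frequencies %.3g-%.3g Hz, wave number %g\n",
              length(f), min(f), max(f), object@wavenumber))
})
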