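# Morlet wavelet power, log/z transforms, band averages, time-frequency
# binning, baseline normalization, and mean spectra.

#' Standard analysis bands
#'
#' Low theta (1-3 Hz), theta (3-10 Hz) and high-frequency activity
#' (40-100 Hz), plus the classifier's wider 1-10-Hz low-frequency range.
#' Band membership uses the closed interval, so a grid frequency at
#' exactly 3 Hz belongs to both low theta and theta.
#'
#' @return named list of c(lo, hi) pairs in Hz
#' @export
bandDefs <- function() {
  list(low_theta = c(1, 3), theta = c(3, 10), hfa = c(40, 100),
       classifier_low = c(1, 10))
}

# complex Morlet kernel: wavenumber cycles within +-1 SD of the Gaussian
# envelope; unit L2 norm so power is comparable across frequencies
.morletKernel <- function(f, fs, wavenumber) {
  sigmaT <- wavenumber / (2 * pi * f)
  half <- ceiling(4 * sigmaT * fs)
  t <- (-half:half) / fs
  k <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigmaT^2))
  k / sqrt(sum(Mod(k)^2))
}

# continuous wavelet power of one signal: length(freqs) x length(x)
.morletPowerVec <- function(x, fs, grid) {
  n <- length(x)
  maxHalf <- ceiling(4 * (grid@wavenumber / (2 * pi * min(grid@frequencies))) * fs)
  M <- stats::nextn(n + 2 * maxHalf + 1, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, M - n)))
  out <- matrix(0, length(grid@frequencies), n)
  for (fi in seq_along(grid@frequencies)) {
    k <- .morletKernel(grid@frequencies[fi], fs, grid@wavenumber)
    L <- length(k); cidx <- (L + 1) %/% 2
    K <- stats::fft(c(k, rep(0, M - L)))
    y <- stats::fft(X * K, inverse = TRUE) / M
    out[fi, ] <- Mod(y[cidx:(cidx + n - 1)])^2
  }
  out
}

#' Morlet wavelet power of an epoch set
#'
#' Convolves every epoch and channel with complex Morlet wavelets (wave
#' number set by the grid, default 5) at each grid frequency and returns
#' squared magnitude. Buffers are trimmed after the convolution. For
#' fixed-window epoch sets the result is a 4-D events x channels x
#' frequencies x time tensor (per-sample, \code{timeAverage = FALSE}) or
#' a 3-D time-averaged tensor; ragged epoch sets are always
#' time-averaged.
#'
#' @param epochSet an [EpochSet-class]
#' @param grid a [FrequencyGrid-class]; the top frequency must stay below
#'   Nyquist
#' @param timeAverage average power over the analysis window per event
#' @return a raw-scale [PowerTensor-class]
#' @export
morletPower <- function(epochSet, grid = frequencyGrid(),
                        timeAverage = FALSE) {
  fs <- epochSet@fs
  if (fs < 2 * max(grid@frequencies))
    stop("fs must be at least twice the maximum grid frequency")
  ragged <- any(is.na(epochSet@windowMs))
  if (ragged && !timeAverage)
    stop("ragged epoch sets support only time-averaged power")
  nev <- length(epochSet@epochs); nch <- nrow(epochSet@channels)
  nf <- length(grid@frequencies)
  if (!timeAverage) {
    nt <- length(.unbufferedIdx(epochSet, which(epochSet@events$kept)[1]))
    vals <- array(0, c(nev, nch, nf, nt))
  } else vals <- array(0, c(nev, nch, nf))
  zeroFlag <- matrix(FALSE, nev, nch)
  for (i in seq_len(nev)) {
    idx <- .unbufferedIdx(epochSet, i)
    if (!length(idx)) next
    m <- epochSet@epochs[[i]]
    for (ch in seq_len(nch)) {
      if (all(m[ch, ] == 0)) { zeroFlag[i, ch] <- TRUE; next }
      p <- .morletPowerVec(m[ch, ], fs, grid)[, idx, drop = FALSE]
      if (timeAverage) vals[i, ch, ] <- rowMeans(p)
      else vals[i, ch, , ] <- p
    }
  }
  ev <- epochSet@events
  if (is.null(ev$type)) ev$type <- "encoding"
  if (is.null(ev$session)) ev$session <- "0"
  tms <- if (!timeAverage)
    epochSet@windowMs[1] + (seq_len(dim(vals)[4]) - 0.5) / fs * 1000
  else numeric(0)
  pt <- new("PowerTensor", values = vals, scale = "raw", events = ev,
            channels = epochSet@channels, grid = grid, timesMs = tms,
            grouping = "none")
  attr(pt@values, "zeroFlag") <- zeroFlag
  pt
}

#' Time-averaged event power from a continuous recording
#'
#' The pipeline workhorse: wavelet-transforms each channel of the
#' continuous recording once and averages power per event — over the
#' item-presentation window for chest events (encoding / no_item) and
#' over the full epoch for navigation and baseline events. Equivalent to
#' buffered epoch-wise decomposition because every event lies at least a
#' buffer length from the recording edges.
#'
#' @param recording a (bipolar) [Recording-class]
#' @param session a [TaskSession-class]
#' @param grid a [FrequencyGrid-class]
#' @param windowMs item-presentation analysis window (ms from chest onset)
#' @return raw-scale 3-D [PowerTensor-class] with one row per session
#'   event (all four types)
#' @export
eventPower <- function(recording, session, grid = frequencyGrid(),
                       windowMs = c(0, 1500)) {
  fs <- recording@fs
  if (fs < 2 * max(grid@frequencies))
    stop("fs must be at least twice the maximum grid frequency")
  ev <- session@events
  n <- ncol(recording@data)
  a <- integer(nrow(ev)); b <- integer(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    w <- if (ev$type[i] %in% c("encoding", "no_item")) windowMs
         else c(0, ev$offset_ms[i] - ev$onset_ms[i])
    a[i] <- max(1L, round((ev$onset_ms[i] + w[1]) / 1000 * fs) + 1L)
    b[i] <- min(n, round((ev$onset_ms[i] + w[2]) / 1000 * fs))
  }
  nch <- nrow(recording@channels); nf <- length(grid@frequencies)
  vals <- array(0, c(nrow(ev), nch, nf))
  for (ch in seq_len(nch)) {
    p <- .morletPowerVec(recording@data[ch, ], fs, grid)
    for (fi in seq_len(nf)) {
      cp <- cumsum(p[fi, ])
      vals[, ch, fi] <- (cp[b] - cp[a] + p[fi, a]) / (b - a + 1)
    }
  }
  ev$session <- session@session
  ev$subject <- session@subject
  new("PowerTensor", values = vals, scale = "raw", events = ev,
      channels = recording@channels, grid = grid, timesMs = numeric(0),
      grouping = "none")
}

#' Combine power tensors across sessions
#'
#' Stacks the event dimension of two or more tensors recorded on the
#' same montage and frequency grid (e.g. multiple sessions of one
#' subject), so z-scoring can be applied per session and decoding can
#' use leave-one-session-out folds.
#'
#' @param ... [PowerTensor-class] objects of identical scale, channels
#'   and grid
#' @return a single combined [PowerTensor-class]
#' @export
bindTensors <- function(...) {
  ts <- list(...)
  if (length(ts) == 1 && is.list(ts[[1]])) ts <- ts[[1]]
  stopifnot(length(ts) >= 1)
  ref <- ts[[1]]
  for (t2 in ts[-1]) {
    stopifnot(identical(t2@scale, ref@scale),
              identical(t2@channels$id, ref@channels$id),
              isTRUE(all.equal(t2@grid@frequencies, ref@grid@frequencies)),
              length(dim(t2@values)) == length(dim(ref@values)))
  }
  d <- dim(ref@values)
  vals <- do.call(rbind, lapply(ts, function(t2)
    matrix(t2@values, nrow = dim(t2@values)[1])))
  dim(vals) <- c(nrow(vals), d[-1])
  ev <- do.call(rbind, lapply(ts, function(t2) t2@events))
  rownames(ev) <- NULL
  new("PowerTensor", values = vals, scale = ref@scale, events = ev,
      channels = ref@channels, grid = ref@grid, timesMs = ref@timesMs,
      grouping = ref@grouping)
}

#' Log transform and z-score spectral power
#'
#' Natural-log transforms raw power, then z-scores separately for every
#' session, channel and frequency (and time bin, for 4-D tensors). The
#' normalization statistics are computed over all events of the types
#' encoding, navigation and baseline; no_item events are transformed with
#' the same group statistics but do not contribute to them.
#'
#' Zero (or negative) power values cannot be log-transformed: the
#' affected cells are set to NA with a warning. A normalization group
#' with zero standard deviation raises an error.
#'
#' @param power a raw-scale [PowerTensor-class]
#' @return the tensor on the z scale
#' @export
logAndZscore <- function(power) {
  if (power@scale != "raw") stop("expected a raw-scale tensor")
  v <- power@values
  bad <- v <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive power values set to NA before log")
    v[bad] <- NA
  }
  v <- log(v)
  ev <- power@events
  normEv <- ev$type %in% c("encoding", "navigation", "baseline")
  if (!any(normEv)) stop("no normalization events (encoding/navigation/baseline)")
  sess <- if (is.null(ev$session)) rep("0", nrow(ev)) else ev$session
  d <- dim(v)
  for (s in unique(sess)) {
    inS <- sess == s
    grp <- inS & normEv
    if (!any(grp)) stop("session ", s, " has no normalization events")
    if (length(d) == 3) {
      mu <- apply(v[grp, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE)
      sg <- apply(v[grp, , , drop = FALSE], c(2, 3), sd, na.rm = TRUE)
    } else {
      mu <- apply(v[grp, , , , drop = FALSE], c(2, 3, 4), mean, na.rm = TRUE)
      sg <- apply(v[grp, , , , drop = FALSE], c(2, 3, 4), sd, na.rm = TRUE)
    }
    if (any(!is.na(sg) & sg == 0))
      stop("zero standard deviation in a normalization group")
    for (i in which(inS)) {
      if (length(d) == 3) v[i, , ] <- (v[i, , ] - mu) / sg
      else v[i, , , ] <- (v[i, , , ] - mu) / sg
    }
  }
  power@values <- v
  power@scale <- "z"
  power@grouping <- paste0("session x channel x frequency",
                           if (length(d) == 4) " x time" else "")
  power
}

#' Band-averaged power per event and channel
#'
#' Averages a z-scaled tensor over time within the given interval (4-D
#' tensors only) and then over the grid frequencies falling inside the
#' closed band interval.
#'
#' @param power a z-scale [PowerTensor-class]
#' @param band c(lo, hi) in Hz, or a name from [bandDefs()]
#' @param intervalMs time interval for 4-D tensors (ms relative to onset)
#' @return events x channels matrix
#' @examples
#' # bandPower(zPow, "low_theta")
#' @export
bandPower <- function(power, band, intervalMs = c(0, 1500)) {
  if (is.character(band)) band <- bandDefs()[[band]]
  f <- power@grid@frequencies
  sel <- which(f >= band[1] & f <= band[2])
  if (!length(sel)) stop("band contains no grid frequencies")
  v <- power@values
  if (length(dim(v)) == 4) {
    tsel <- which(power@timesMs >= intervalMs[1] & power@timesMs <= intervalMs[2])
    if (!length(tsel)) stop("interval contains no time points")
    v <- apply(v[, , , tsel, drop = FALSE], c(1, 2, 3), mean)
  }
  out <- apply(v[, , sel, drop = FALSE], c(1, 2), mean)
  dimnames(out) <- list(NULL, power@channels$id)
  out
}

#' Overlapping-window layout
#'
#' Number and edges of fully contained overlapping windows of
#' \code{widthMs} stepped by \code{stepMs} across a span. The default
#' time-frequency layouts are 69 bins (100-ms windows, 50-ms steps, -1500
#' to 2000 ms) and 56 bins (500-ms windows, 100-ms steps, -2250 to 3750
#' ms).
#'
#' @param spanMs total span (ms)
#' @param widthMs window width (ms)
#' @param stepMs step between window starts (ms)
#' @return list with \code{n}, \code{starts}, \code{centers} (ms,
#'   relative to span start)
#' @examples
#' windowCount(3500, 100, 50)$n   # 69
#' windowCount(6000, 500, 100)$n  # 56
#' @export
windowCount <- function(spanMs, widthMs, stepMs) {
  if (widthMs > spanMs) stop("window width exceeds span")
  if (stepMs <= 0) stop("step must be positive")
  n <- floor((spanMs - widthMs) / stepMs) + 1
  starts <- (seq_len(n) - 1) * stepMs
  list(n = as.integer(n), starts = starts, centers = starts + widthMs / 2)
}

#' Re-center z power on the pre-trial baseline
#'
#' Subtracts, per session, channel and frequency (and time bin), the mean
#' z power of the baseline-tagged events, so baseline events average zero
#' and other event types are expressed relative to the pre-trial state.
#'
#' @param power a z-scale [PowerTensor-class] containing baseline events
#' @return the re-centered tensor
#' @export
baselineNormalize <- function(power) {
  if (power@scale != "z") stop("baseline normalization expects a z-scale tensor")
  ev <- power@events
  sess <- if (is.null(ev$session)) rep("0", nrow(ev)) else ev$session
  v <- power@values; d <- dim(v)
  for (s in unique(sess)) {
    base <- sess == s & ev$type == "baseline"
    if (!any(base)) stop("session ", s, " has no baseline events")
    if (length(d) == 3) {
      mu <- apply(v[base, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE)
      for (i in which(sess == s)) v[i, , ] <- v[i, , ] - mu
    } else {
      mu <- apply(v[base, , , , drop = FALSE], c(2, 3, 4), mean, na.rm = TRUE)
      for (i in which(sess == s)) v[i, , , ] <- v[i, , , ] - mu
    }
  }
  power@values <- v
  power@grouping <- paste(power@grouping, "- baseline-centered")
  power
}

#' Mean log-power spectrum per electrode and condition
#'
#' Averages log power across the selected events (and over time, for 4-D
#' tensors) for each channel at every grid frequency within the range.
#' Input may be raw (log is applied) or log/z scale (used as is).
#'
#' @param power a [PowerTensor-class]
#' @param select logical or integer index of events forming the condition
#' @param rangeHz frequency range (default 1-50 Hz)
#' @return channels x frequencies matrix; frequencies as an attribute
#'   \code{"frequencies"}
#' @export
meanSpectrum <- function(power, select, rangeHz = c(1, 50)) {
  if (is.logical(select)) select <- which(select)
  if (!length(select)) stop("empty condition")
  f <- power@grid@frequencies
  sel <- which(f >= rangeHz[1] & f <= rangeHz[2])
  v <- power@values
  if (length(dim(v)) == 4) v <- apply(v, c(1, 2, 3), mean)
  v <- v[select, , sel, drop = FALSE]
  if (power@scale == "raw") v <- log(v)
  out <- apply(v, c(2, 3), mean, na.rm = TRUE)
  dimnames(out) <- list(power@channels$id, NULL)
  attr(out, "frequencies") <- f[sel]
  out
}
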