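# Referencing, filtering, epoching and artifact rejection.

#' Bipolar referencing
#'
#' Forms one virtual channel per pair of immediately adjacent contacts on
#' the same probe (consecutive contact indices), as the voltage difference
#' first minus second. The virtual channel is located at the midpoint of
#' the pair and inherits hemisphere and region from its parents; if the
#' parent labels disagree the region is set to "boundary". Probes with a
#' single contact contribute no virtual channels.
#'
#' Common-mode components (e.g. shared reference noise) cancel exactly in
#' the subtraction.
#'
#' @param recording a [Recording-class]
#' @return a [BipolarRecording-class]; its channel table adds
#'   \code{parent1}/\code{parent2} contact ids
#' @examples
#' s <- generateSession(taskConfig(nTrials = 1), seed = 1)
#' r <- generateRecording(s, synthMontage(), seed = 1)
#' bipolarReference(r)
#' @export
bipolarReference <- function(recording) {
  mont <- recording@channels
  ord <- order(mont$probe, mont$contact)
  mont <- mont[ord, ]; dat <- recording@data[ord, , drop = FALSE]
  rows <- list(); sigs <- list()
  for (pr in unique(mont$probe)) {
    idx <- which(mont$probe == pr)
    if (length(idx) < 2) {
      message("probe ", pr, " has a single contact; no virtual channels")
      next
    }
    for (k in seq_len(length(idx) - 1)) {
      i <- idx[k]; j <- idx[k + 1]
      if (mont$contact[j] != mont$contact[i] + 1L) next
      hemi <- if (mont$hemisphere[i] == mont$hemisphere[j])
        mont$hemisphere[i] else "boundary"
      region <- if (mont$region[i] == mont$region[j])
        mont$region[i] else "boundary"
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste(mont$id[i], mont$id[j], sep = "-"),
        probe = pr, contact = mont$contact[i],
        x = (mont$x[i] + mont$x[j]) / 2,
        y = (mont$y[i] + mont$y[j]) / 2,
        z = (mont$z[i] + mont$z[j]) / 2,
        hemisphere = hemi, region = region,
        soz = mont$soz[i] | mont$soz[j],
        parent1 = mont$id[i], parent2 = mont$id[j],
        stringsAsFactors = FALSE)
      sigs[[length(sigs) + 1L]] <- dat[i, ] - dat[j, ]
    }
  }
  if (!length(rows)) stop("montage yields no adjacent contact pairs")
  new("BipolarRecording", data = do.call(rbind, sigs), fs = recording@fs,
      channels = do.call(rbind, rows))
}

#' Band-stop (notch) filter for line noise
#'
#' 4th-order Butterworth band-stop at 58-62 Hz, applied forward-backward
#' (zero phase), so the effective attenuation is the squared magnitude
#' response. Pass-band gain is within 1% outside 50-70 Hz.
#'
#' @param recording a [Recording-class] (or [BipolarRecording-class])
#' @param stopLo,stopHi stop-band edges (Hz)
#' @param order filter order
#' @return the recording with filtered data
#' @export
notchFilter <- function(recording, stopLo = 58, stopHi = 62, order = 4) {
  fs <- recording@fs
  if (fs <= 2 * stopHi)
    stop("sampling rate too low: need fs > ", 2 * stopHi, " Hz")
  bf <- signal::butter(order, c(stopLo, stopHi) / (fs / 2), type = "stop")
  dat <- recording@data
  n <- ncol(dat)
  # zero-phase (forward-backward) application: multiply the spectrum by
  # the squared magnitude response of the designed filter. This is the
  # steady-state equivalent of filtfilt and avoids the start-up
  # transients of the nearly-unit-circle IIR recursion. Mirror padding
  # keeps the circular wrap-around away from the data.
  npad <- min(n - 1L, as.integer(3 * fs))
  L <- n + 2L * npad
  M <- stats::nextn(L, c(2, 3, 5))
  w <- 2 * pi * (seq_len(M) - 1) / M
  ew <- exp(-1i * outer(w, 0:(length(bf$b) - 1)))
  G <- Mod((ew %*% bf$b) / (ew %*% bf$a))^2   # |H|^2: forward + backward
  for (ch in seq_len(nrow(dat))) {
    x <- dat[ch, ]
    xp <- c(rev(x[2:(npad + 1)]), x, rev(x[(n - npad):(n - 1)]),
            rep(0, M - L))
    y <- Re(stats::fft(stats::fft(xp) * as.vector(G), inverse = TRUE)) / M
    dat[ch, ] <- y[(npad + 1):(npad + n)]
  }
  recording@data <- dat
  recording
}

#' Extract event-locked epochs with buffers
#'
#' Slices the recording around each event. With a fixed \code{windowMs}
#' (relative to event onset) all epochs share a length; with
#' \code{windowMs = NULL} each event's own onset-to-offset span is used
#' (ragged, for variable-duration navigation/baseline epochs). A
#' symmetric buffer (default 3000 ms) is attached to each side to absorb
#' wavelet edge effects and is trimmed again after spectral
#' decomposition. Events whose buffered window leaves the recording are
#' dropped with a warning and flagged \code{kept = FALSE}.
#'
#' @param recording a [Recording-class]
#' @param events data.frame with at least \code{onset_ms} (and
#'   \code{offset_ms} when \code{windowMs} is NULL)
#' @param windowMs length-2 window in ms relative to onset, or NULL
#' @param bufferMs buffer per side in ms
#' @return an [EpochSet-class]
#' @export
extractEpochs <- function(recording, events, windowMs = c(0, 1500),
                          bufferMs = 3000) {
  fs <- recording@fs; n <- ncol(recording@data)
  nb <- round(bufferMs / 1000 * fs)
  ragged <- is.null(windowMs)
  events$kept <- TRUE
  epochs <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    w <- if (ragged) c(0, events$offset_ms[i] - events$onset_ms[i]) else windowMs
    i0 <- round((events$onset_ms[i] + w[1]) / 1000 * fs) + 1L
    i1 <- round((events$onset_ms[i] + w[2]) / 1000 * fs)
    if (i0 - nb < 1 || i1 + nb > n) {
      warning("event ", i, ": buffered window outside recording; dropped")
      events$kept[i] <- FALSE
      epochs[[i]] <- matrix(0, nrow(recording@data), 0)
    } else {
      epochs[[i]] <- recording@data[, (i0 - nb):(i1 + nb), drop = FALSE]
    }
  }
  new("EpochSet", epochs = epochs, events = events,
      channels = recording@channels, fs = fs,
      windowMs = if (ragged) c(NA_real_, NA_real_) else windowMs,
      bufferMs = bufferMs,
      rejected = matrix(!events$kept, nrow(events), nrow(recording@channels)))
}

#' @describeIn EpochSet-class events x channels rejection mask
#' @export
rejectionMask <- function(x) x@rejected

# columns of the unbuffered analysis window of epoch i
.unbufferedIdx <- function(epochSet, i) {
  m <- epochSet@epochs[[i]]
  nb <- round(epochSet@bufferMs / 1000 * epochSet@fs)
  if (ncol(m) <= 2 * nb) return(integer(0))
  (nb + 1L):(ncol(m) - nb)
}

#' Kurtosis-based artifact rejection
#'
#' Computes, per event and channel, the plain (non-excess) kurtosis of the
#' unbuffered voltage trace — so Gaussian noise sits near 3 — and marks an
#' event x channel cell excluded when kurtosis exceeds the threshold
#' (default 5). Zero-variance traces are excluded as well (kurtosis
#' undefined). The buffer is not included: only the analysis window is
#' screened.
#'
#' @param epochSet an [EpochSet-class]
#' @param threshold kurtosis threshold
#' @return the epoch set with its rejection mask updated; the overall
#'   exclusion fraction is attached as attribute \code{"fraction"} of the
#'   mask
#' @export
kurtosisReject <- function(epochSet, threshold = 5) {
  mask <- epochSet@rejected
  for (i in seq_along(epochSet@epochs)) {
    idx <- .unbufferedIdx(epochSet, i)
    if (!length(idx)) { mask[i, ] <- TRUE; next }
    m <- epochSet@epochs[[i]][, idx, drop = FALSE]
    for (ch in seq_len(nrow(m))) {
      x <- m[ch, ] - mean(m[ch, ])
      v <- mean(x^2)
      if (v <= 0) { mask[i, ch] <- TRUE; next }
      if (mean(x^4) / v^2 > threshold) mask[i, ch] <- TRUE
    }
  }
  attr(mask, "fraction") <- mean(mask)
  epochSet@rejected <- mask
  epochSet
}
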