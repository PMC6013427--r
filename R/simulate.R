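# Synthetic task sessions and recordings with known planted effects.
# Everything downstream (scoring, preprocessing, spectral analysis,
# statistics, decoding) is exercised against these generators.

#' Generate a synthetic electrode montage
#'
#' Builds a depth-electrode style montage: one or more linear probes per
#' hemisphere with equally spaced contacts, suitable for bipolar
#' referencing (adjacency = same probe, consecutive contact index).
#' Left-hemisphere probes are placed around a nominal hippocampal target
#' and mirrored on the right.
#'
#' @param contactsPerProbe contacts on each linear probe
#' @param probesPerHemisphere probes per hemisphere
#' @param region region label applied to all contacts
#' @param spacingMm inter-contact spacing along the probe (mm)
#' @param sozHemisphere optionally flag all contacts of one hemisphere
#'   ("L"/"R") as lying in the seizure-onset zone
#' @return data.frame with columns id, probe, contact, x, y, z,
#'   hemisphere, region, soz
#' @examples
#' m <- synthMontage()
#' table(m$hemisphere)
#' @export
synthMontage <- function(contactsPerProbe = 5, probesPerHemisphere = 1,
                         region = "hippocampus", spacingMm = 10,
                         sozHemisphere = NULL) {
  rows <- list()
  for (h in c("L", "R")) {
    sgn <- if (h == "L") -1 else 1
    for (p in seq_len(probesPerHemisphere)) {
      probe <- sprintf("%s%s%d", h, toupper(substr(region, 1, 1)), p)
      k <- seq_len(contactsPerProbe)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s-%d", probe, k), probe = probe, contact = k,
        x = sgn * 30, y = -25 - (p - 1) * 8 + (k - 1) * spacingMm,
        z = -12,
        hemisphere = h, region = region,
        soz = !is.null(sozHemisphere) && h %in% sozHemisphere,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic task session
#'
#' Lays out the full trial timeline of the virtual treasure-hunt task:
#' per trial one pre-trial baseline epoch, alternating navigation epochs
#' and chest-display events (four chests per trial, two or three containing
#' an object), and retrieval responses with confidence reports drawn from
#' the behavioral model. Ground-truth memory success is drawn per studied
#' object first; response placement error and confidence are conditional
#' on it.
#'
#' Exactly \code{nObjectChests - 2 * nTrials} trials carry three objects
#' and the remainder two, so the session totals (100 object / 60 empty
#' chests under the defaults) are met exactly for every seed; the
#' assignment of counts to trials and of objects to chest positions is
#' shuffled by the seed.
#'
#' @param task a [TaskConfig-class]
#' @param arena an [ArenaConfig-class]
#' @param behavior a [BehaviorModel-class]
#' @param seed integer seed; identical seeds give identical sessions
#' @param subject,session identifiers stored on the object
#' @return a [TaskSession-class]
#' @examples
#' s <- generateSession(seed = 1)
#' table(sessionEvents(s)$type)
#' @export
generateSession <- function(task = taskConfig(), arena = arenaConfig(),
                            behavior = behaviorModel(), seed,
                            subject = "S01", session = "0") {
  stopifnot(is(task, "TaskConfig"), is(arena, "ArenaConfig"),
            is(behavior, "BehaviorModel"))
  validObject(task); validObject(arena); validObject(behavior)
  set.seed(seed)
  nT <- task@nTrials; cpt <- task@chestsPerTrial
  n3 <- task@nObjectChests - 2L * nT
  if (n3 < 0L || n3 > nT)
    stop("object/empty totals not reachable with 2-3 objects per trial")
  objPerTrial <- sample(c(rep(3L, n3), rep(2L, nT - n3)))

  events <- vector("list", nT * (2L * cpt + 1L))
  resp <- vector("list", nT)
  t <- 3000  # ms; leading margin so buffered epochs fit in the recording
  ei <- 0L; objCounter <- 0L
  for (tr in seq_len(nT)) {
    bdur <- runif(1, 2000, 6000)
    ei <- ei + 1L
    events[[ei]] <- data.frame(type = "baseline", trial = tr,
                               onset_ms = t, offset_ms = t + bdur,
                               x = NA_real_, y = NA_real_,
                               object_id = NA_character_, item = NA,
                               remembered = NA)
    t <- t + bdur
    isObj <- sample(rep(c(TRUE, FALSE), c(objPerTrial[tr], cpt - objPerTrial[tr])))
    trueLoc <- cbind(runif(cpt, 0, arena@width), runif(cpt, 0, arena@height))
    rem <- rep(NA, cpt); oid <- rep(NA_character_, cpt)
    for (j in seq_len(cpt)) {
      ndur <- pmin(pmax(rlnorm(1, log(6000), 0.35), 2000), 20000)
      ei <- ei + 1L
      events[[ei]] <- data.frame(type = "navigation", trial = tr,
                                 onset_ms = t, offset_ms = t + ndur,
                                 x = NA_real_, y = NA_real_,
                                 object_id = NA_character_, item = NA,
                                 remembered = NA)
      t <- t + ndur
      if (isObj[j]) {
        objCounter <- objCounter + 1L
        oid[j] <- sprintf("obj%03d", objCounter)
        rem[j] <- runif(1) < behavior@pRemember
      }
      ei <- ei + 1L
      events[[ei]] <- data.frame(
        type = if (isObj[j]) "encoding" else "no_item", trial = tr,
        onset_ms = t, offset_ms = t + task@itemDisplayMs,
        x = trueLoc[j, 1], y = trueLoc[j, 2],
        object_id = oid[j], item = isObj[j], remembered = rem[j])
      t <- t + task@itemDisplayMs
    }
    # retrieval: distractor + one probe per studied object (not modeled
    # neurally; advances the clock so trials never overlap)
    vp <- sample(1:2, 1)
    ridx <- which(isObj)
    rr <- vector("list", length(ridx))
    for (k in seq_along(ridx)) {
      j <- ridx[k]
      if (rem[j]) {
        rx <- trueLoc[j, 1] + rnorm(1, 0, behavior@errorSd)
        ry <- trueLoc[j, 2] + rnorm(1, 0, behavior@errorSd)
      } else if (runif(1) < behavior@guessRate) {
        rx <- runif(1, 0, arena@width); ry <- runif(1, 0, arena@height)
      } else {
        rx <- trueLoc[j, 1] + rnorm(1, 0, 4 * behavior@errorSd)
        ry <- trueLoc[j, 2] + rnorm(1, 0, 4 * behavior@errorSd)
      }
      rx <- min(max(rx, 0), arena@width); ry <- min(max(ry, 0), arena@height)
      err <- sqrt((rx - trueLoc[j, 1])^2 + (ry - trueLoc[j, 2])^2)
      s <- err + rnorm(1, 0, behavior@confSlack)
      conf <- if (s < behavior@confYes) "Yes" else
        if (s < behavior@confMaybe) "Maybe" else "No"
      rr[[k]] <- data.frame(object_id = oid[j], trial = tr,
                            true_x = trueLoc[j, 1], true_y = trueLoc[j, 2],
                            response_x = rx, response_y = ry,
                            confidence = conf, raw_error = err,
                            accuracy = NA_real_, viewpoint = vp,
                            remembered_truth = rem[j])
    }
    resp[[tr]] <- do.call(rbind, rr)
    t <- t + 2000 + 3000 * length(ridx)
  }
  events <- do.call(rbind, events[seq_len(ei)])
  rownames(events) <- NULL
  responses <- do.call(rbind, resp); rownames(responses) <- NULL
  new("TaskSession", subject = subject, session = session,
      arena = arena, task = task, events = events, responses = responses,
      durationS = (t + 3000) / 1000)
}

# band-limited 40-100 Hz noise segment via FFT masking
# (synthesis runs at a 2/3/5-smooth length for fast mixed-radix FFTs)
.hfaNoise <- function(n, fs) {
  if (n < 8) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))
  W <- stats::fft(stats::rnorm(m))
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f <- pmin(f, fs - f)
  W[f < 40 | f > 100] <- 0
  x <- Re(stats::fft(W, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# power-law shaped background noise, amplitude ~ f^(-exponent/2), DC zeroed
.powerlawNoise <- function(n, fs, exponent, targetSd) {
  m <- stats::nextn(n, c(2, 3, 5))
  W <- stats::fft(stats::rnorm(m))
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f <- pmin(f, fs - f)
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE))[seq_len(n)] / m
  x * targetSd / stats::sd(x)
}

#' Generate a synthetic multichannel recording for a session
#'
#' Synthesizes one voltage trace per montage contact covering the whole
#' session: power-law background noise, Hann-windowed oscillatory bursts
#' at the model's burst frequency during behavioral epochs (amplitude
#' scaled by the hemisphere-specific memory gain for subsequently
#' remembered encoding events and by the navigation gain during
#' navigation; unit gain otherwise), a 60-Hz line sinusoid, Poisson
#' transient artifacts, and a broadband 40-100-Hz component during chest
#' displays scaled by \code{hfaItemGain} when an object is shown.
#' Contacts receive independent noise and burst phases, so bipolar
#' referencing does not cancel the planted oscillations.
#'
#' @param session a [TaskSession-class]
#' @param montage montage data.frame as from [synthMontage()]
#' @param neural a [NeuralModel-class]
#' @param fs sampling rate (Hz); must be at least 400 so the analysis grid
#'   up to 200 Hz stays below Nyquist
#' @param seed integer seed
#' @return a [Recording-class] of channels x samples microvolt data
#' @examples
#' s <- generateSession(taskConfig(nTrials = 2), seed = 1)
#' r <- generateRecording(s, synthMontage(), neuralModel(), seed = 1)
#' r
#' @export
generateRecording <- function(session, montage, neural = neuralModel(),
                              fs = 500, seed) {
  stopifnot(is(session, "TaskSession"), is(neural, "NeuralModel"))
  validObject(neural)
  if (fs < 400)
    stop("fs must be >= 400 Hz: the 200-Hz top of the frequency grid ",
         "requires a Nyquist frequency of at least 200 Hz")
  set.seed(seed)
  n <- ceiling(session@durationS * fs)
  ev <- session@events
  tsamp <- function(ms) pmax(1L, pmin(n, as.integer(round(ms / 1000 * fs)) + 1L))
  memGain <- c(L = neural@leftMemoryGain, R = neural@rightMemoryGain)
  navGain <- c(L = neural@leftNavGain, R = neural@rightNavGain)

  dat <- matrix(0, nrow(montage), n)
  for (ch in seq_len(nrow(montage))) {
    h <- montage$hemisphere[ch]
    x <- .powerlawNoise(n, fs, neural@backgroundExponent, neural@noiseSd)
    if (neural@lineNoiseAmp > 0)
      x <- x + neural@lineNoiseAmp *
        sin(2 * pi * 60 * seq_len(n) / fs + runif(1, 0, 2 * pi))
    # stationary session-wide Poisson burst process; the amplitude of a
    # burst is set by the behavioral epoch containing its centre, so the
    # oscillatory background is homogeneous across epoch boundaries and
    # only the planted gains differentiate conditions
    durS <- n / fs
    nBursts <- rpois(1, neural@burstRate * durS)
    if (neural@burstAmp > 0 && nBursts > 0) {
      for (kk in seq_len(nBursts)) {
        cyc <- runif(1, 2, 6)
        bdur <- cyc / neural@oscFreqHz * 1000
        st <- runif(1, 0, durS * 1000 - bdur)
        ctr <- st + bdur / 2
        hit <- which(ev$onset_ms <= ctr & ev$offset_ms > ctr)
        gain <- if (length(hit)) {
          e <- hit[1]
          switch(ev$type[e],
                 encoding = if (isTRUE(ev$remembered[e])) memGain[[h]] else 1,
                 navigation = navGain[[h]],
                 1)
        } else 1
        i0 <- tsamp(st); i1 <- min(tsamp(st + bdur), n)
        L <- i1 - i0 + 1L
        if (L > 4) {
          tt <- (seq_len(L) - 1) / fs
          hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
          x[i0:i1] <- x[i0:i1] + neural@burstAmp * gain * hann *
            sin(2 * pi * neural@oscFreqHz * tt + runif(1, 0, 2 * pi))
        }
      }
    }
    for (e in which(ev$type %in% c("encoding", "no_item"))) {
      if (neural@hfaAmp <= 0) next
      i0 <- tsamp(ev$onset_ms[e]); i1 <- min(tsamp(ev$offset_ms[e]), n)
      hamp <- neural@hfaAmp * if (isTRUE(ev$item[e])) neural@hfaItemGain else 1
      x[i0:i1] <- x[i0:i1] + hamp * .hfaNoise(i1 - i0 + 1L, fs)
    }
    if (neural@artifactRate > 0) {
      na <- rpois(1, neural@artifactRate * n / fs / 60)
      hw <- max(2L, as.integer(round(0.025 * fs)))
      for (kk in seq_len(na)) {
        c0 <- sample.int(n, 1)
        idx <- max(1L, c0 - hw):min(n, c0 + hw)
        x[idx] <- x[idx] + sample(c(-1, 1), 1) * 400 *
          exp(-abs(idx - c0) / (0.008 * fs))
      }
    }
    dat[ch, ] <- x
  }
  new("Recording", data = dat, fs = fs, channels = montage)
}

#' Simulate one subject (session + recording + montage)
#'
#' Convenience wrapper used by the cohort pipeline: derives per-stage
#' seeds from \code{seed}, generates a session and its recording.
#'
#' @inheritParams generateSession
#' @inheritParams generateRecording
#' @param montage montage data.frame; default [synthMontage()]
#' @return list with elements \code{session}, \code{recording},
#'   \code{montage}
#' @export
simulateSubject <- function(task = taskConfig(), arena = arenaConfig(),
                            behavior = behaviorModel(),
                            neural = neuralModel(),
                            montage = synthMontage(), fs = 500, seed,
                            subject = "S01") {
  sess <- generateSession(task, arena, behavior, seed = seed,
                          subject = subject)
  rec <- generateRecording(sess, montage, neural, fs = fs,
                           seed = seed + 7919L)
  list(session = sess, recording = rec, montage = montage)
}

# ---- plain-text IO ---------------------------------------------------------

#' Write / read a session event table as TSV
#'
#' One row per event (type, trial, onset_ms, offset_ms, x, y, object_id)
#' with retrieval columns (confidence, response_x, response_y) joined onto
#' encoding rows.
#'
#' @param session a [TaskSession-class]
#' @param path output file
#' @return invisibly, the written data.frame
#' @export
writeSessionTSV <- function(session, path) {
  ev <- session@events
  rs <- session@responses[, c("object_id", "confidence",
                              "response_x", "response_y")]
  out <- merge(ev, rs, by = "object_id", all.x = TRUE, sort = FALSE)
  out <- out[order(out$onset_ms),
             c("type", "trial", "onset_ms", "offset_ms", "x", "y",
               "object_id", "confidence", "response_x", "response_y")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' @rdname writeSessionTSV
#' @export
readSessionTSV <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a montage table as TSV
#' @param montage montage data.frame (id, probe, contact, x, y, z,
#'   hemisphere, region, soz)
#' @param path file path
#' @return the montage data.frame (read) or invisibly (write)
#' @export
writeMontageTSV <- function(montage, path) {
  write.table(montage, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(montage)
}

#' @rdname writeMontageTSV
#' @export
readMontageTSV <- function(path) read.delim(path, stringsAsFactors = FALSE)
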