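# Shared fixtures, generated in code at test time.

# a short session + recording, small montage
tinySim <- function(seed = 1, nTrials = 2, neural = neuralModel(),
                    contactsPerProbe = 3) {
  simulateSubject(task = taskConfig(nTrials = nTrials), neural = neural,
                  montage = synthMontage(contactsPerProbe = contactsPerProbe),
                  seed = seed)
}

# recording wrapping a given channels x samples matrix
toyRecording <- function(dat, fs = 500, hemisphere = NULL) {
  nch <- nrow(dat)
  if (is.null(hemisphere)) hemisphere <- rep("L", nch)
  ch <- data.frame(id = sprintf("c%d", seq_len(nch)), probe = "P1",
                   contact = seq_len(nch), x = 0, y = seq_len(nch) * 10,
                   z = 0, hemisphere = hemisphere, region = "hippocampus",
                   soz = FALSE, stringsAsFactors = FALSE)
  new("Recording", data = dat, fs = fs, channels = ch)
}

# epoch set holding one fixed-window epoch built from a raw signal vector
toyEpochs <- function(x, fs = 500, windowMs = NULL, bufferMs = 0) {
  dat <- matrix(x, nrow = 1)
  if (is.null(windowMs))
    windowMs <- c(0, (length(x) - 2 * round(bufferMs / 1000 * fs)) / fs * 1000)
  ev <- data.frame(type = "encoding", trial = 1, onset_ms = 0,
                   offset_ms = windowMs[2], x = NA, y = NA,
                   object_id = "o1", item = TRUE, remembered = TRUE,
                   kept = TRUE)
  new("EpochSet", epochs = list(dat), events = ev,
      channels = toyRecording(dat)@channels[1, ], fs = fs,
      windowMs = windowMs, bufferMs = bufferMs,
      rejected = matrix(FALSE, 1, 1))
}

# z-scale power tensor with given values array (for classifier tests)
toyZTensor <- function(vals, grid, types = NULL, trials = NULL) {
  nev <- dim(vals)[1]; nch <- dim(vals)[2]
  ch <- toyRecording(matrix(0, nch, 4))@channels
  ev <- data.frame(type = if (is.null(types)) rep("encoding", nev) else types,
                   trial = if (is.null(trials)) rep(1:2, length.out = nev)
                           else trials,
                   session = "0", subject = "S01",
                   object_id = sprintf("o%d", seq_len(nev)))
  new("PowerTensor", values = vals, scale = "z", events = ev,
      channels = ch, grid = grid, timesMs = numeric(0), grouping = "test")
}
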