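# End-to-end orchestration: synthetic cohort -> behavioral scoring ->
# preprocessing -> spectral power -> statistics (-> decoding) -> report.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its default. The master
#' seed derives deterministic per-subject sub-seeds, so a configuration
#' fully determines the run.
#'
#' @param nSubjects cohort size
#' @param nTrials trials per simulated session (the full task design is
#'   40; the default keeps cohort runs at roughly 250-s sessions)
#' @param fs sampling rate (Hz)
#' @param seed master seed
#' @param grid analysis [FrequencyGrid-class]
#' @param bands named list of band intervals for the contrast battery
#' @param neural [NeuralModel-class] (planted effects)
#' @param behavior [BehaviorModel-class]
#' @param arena [ArenaConfig-class]
#' @param contactsPerProbe contacts per simulated probe (one probe per
#'   hemisphere)
#' @param windowMs item-presentation analysis window (ms)
#' @param bufferMs wavelet buffer (ms)
#' @param notch stop-band edges (Hz)
#' @param notchOrder Butterworth order
#' @param kurtosisThreshold artifact-rejection threshold
#' @param gridStep accuracy-score candidate grid step (virtual units)
#' @param lambda ridge penalty for decoding
#' @param decode run the per-subject decoder
#' @param alpha significance level for group tests
#' @return list of class "RunConfig"
#' @export
runConfig <- function(nSubjects = 12, nTrials = 6, fs = 500, seed = 42,
                      grid = frequencyGrid(), bands = bandDefs()[1:3],
                      neural = neuralModel(), behavior = behaviorModel(),
                      arena = arenaConfig(), contactsPerProbe = 5,
                      windowMs = c(0, 1500), bufferMs = 3000,
                      notch = c(58, 62), notchOrder = 4,
                      kurtosisThreshold = 5, gridStep = 1, lambda = 1,
                      decode = FALSE, alpha = 0.05) {
  structure(list(nSubjects = nSubjects, nTrials = nTrials, fs = fs,
                 seed = seed, grid = grid, bands = bands, neural = neural,
                 behavior = behavior, arena = arena,
                 contactsPerProbe = contactsPerProbe, windowMs = windowMs,
                 bufferMs = bufferMs, notch = notch,
                 notchOrder = notchOrder,
                 kurtosisThreshold = kurtosisThreshold,
                 gridStep = gridStep, lambda = lambda, decode = decode,
                 alpha = alpha),
            class = "RunConfig")
}

#' Analyse one simulated subject
#'
#' Behavioral scoring and labeling, bipolar referencing, notch
#' filtering, kurtosis rejection, Morlet power, z-scoring, band
#' contrasts (memory, navigation, item) per hemisphere, and mean 1-50-Hz
#' spectra by memory condition.
#'
#' @param sim list(session, recording, montage) from [simulateSubject()]
#' @param config a [runConfig()] list
#' @return list with the subject's effect-table rows, behavioral
#'   summary, rejection fraction, per-condition spectra and (optionally)
#'   decoding features
#' @export
analyzeSubject <- function(sim, config = runConfig()) {
  sess <- scoreSession(sim$session, config$gridStep)
  labs <- labelMemory(sessionResponses(sess))
  rec <- notchFilter(bipolarReference(sim$recording),
                     config$notch[1], config$notch[2], config$notchOrder)
  ev <- sessionEvents(sess)

  # kurtosis screening on the voltage epochs
  mask <- matrix(FALSE, nrow(ev), nrow(channelInfo(rec)))
  chest <- which(ev$type %in% c("encoding", "no_item"))
  long <- which(ev$type %in% c("navigation", "baseline"))
  esC <- kurtosisReject(suppressWarnings(
    extractEpochs(rec, ev[chest, ], config$windowMs, config$bufferMs)),
    config$kurtosisThreshold)
  esL <- kurtosisReject(suppressWarnings(
    extractEpochs(rec, ev[long, ], NULL, config$bufferMs)),
    config$kurtosisThreshold)
  mask[chest, ] <- rejectionMask(esC)
  mask[long, ] <- rejectionMask(esL)

  pt <- eventPower(rec, sess, config$grid, config$windowMs)
  z <- suppressWarnings(logAndZscore(pt))

  # per-event labels on encoding rows
  lab <- rep(NA_character_, nrow(ev))
  m <- match(ev$object_id, labs$object_id)
  lab[!is.na(m)] <- labs$label[m[!is.na(m)]]

  effects <- list()
  for (b in names(config$bands)) {
    bv <- bandPower(z, config$bands[[b]], config$windowMs)
    bv[mask] <- NA
    encIdx <- which(ev$type == "encoding" & !is.na(lab))
    effects[[length(effects) + 1L]] <- buildContrast(
      bv[encIdx, , drop = FALSE], lab[encIdx],
      c("remembered", "forgotten"), channelInfo(rec),
      subject = sess@subject, band = b, contrast = "memory")
    nbIdx <- which(ev$type %in% c("navigation", "baseline"))
    effects[[length(effects) + 1L]] <- buildContrast(
      bv[nbIdx, , drop = FALSE], ev$type[nbIdx],
      c("navigation", "baseline"), channelInfo(rec),
      subject = sess@subject, band = b, contrast = "navigation")
    itIdx <- which(ev$type %in% c("encoding", "no_item"))
    effects[[length(effects) + 1L]] <- buildContrast(
      bv[itIdx, , drop = FALSE], ev$type[itIdx],
      c("encoding", "no_item"), channelInfo(rec),
      subject = sess@subject, band = b, contrast = "item")
  }
  effects <- do.call(rbind, effects)
  # seizure-zone provenance per hemisphere (for subset filters)
  sozByHemi <- tapply(channelInfo(rec)$soz, channelInfo(rec)$hemisphere, any)
  effects$soz <- unname(sozByHemi[effects$hemisphere])

  specRange <- c(1, min(50, max(gridFrequencies(config$grid))))
  spec1 <- function(sel) tryCatch(meanSpectrum(pt, sel, specRange),
                                  error = function(e) NULL)
  spectra <- list(
    remembered = spec1(ev$type == "encoding" & !is.na(lab) &
                         lab == "remembered"),
    forgotten = spec1(ev$type == "encoding" & !is.na(lab) &
                        lab == "forgotten"))

  features <- NULL
  if (isTRUE(config$decode)) {
    cg <- classifierGrids()
    zl <- suppressWarnings(logAndZscore(
      eventPower(rec, sess, cg$low, config$windowMs)))
    zh <- suppressWarnings(logAndZscore(
      eventPower(rec, sess, cg$high, config$windowMs)))
    features <- buildFeatures(zl, zh, lab, "both")
    features$low <- buildFeatures(zl, NULL, lab, "low")
    features$high <- buildFeatures(NULL, zh, lab, "high")
  }
  list(subject = sess@subject, effects = effects,
       behavior = behavioralSummary(sess),
       rejectionFraction = mean(mask), spectra = spectra,
       channels = channelInfo(rec), features = features)
}

# Bonferroni-corrected group tests per contrast x band x hemisphere
.groupStats <- function(effects, alpha) {
  out <- list()
  mTests <- length(unique(effects$band)) * length(unique(effects$hemisphere))
  for (cc in unique(effects$contrast))
    for (b in unique(effects$band))
      for (h in unique(effects$hemisphere)) {
        v <- effects$value[effects$contrast == cc & effects$band == b &
                             effects$hemisphere == h]
        if (length(v) < 2) next
        tt <- groupTtest(v)
        out[[length(out) + 1L]] <- data.frame(
          contrast = cc, band = b, hemisphere = h, n = tt$n,
          mean = mean(v), t = tt$t, dof = tt$dof, p = tt$p,
          p_bonferroni = min(1, tt$p * mTests),
          significant = tt$p * mTests < alpha,
          stringsAsFactors = FALSE)
      }
  do.call(rbind, out)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates \code{nSubjects} subjects (session + recording), analyses
#' each ([analyzeSubject()]), then computes cohort statistics: group
#' t-tests per contrast x band x hemisphere (Bonferroni-corrected across
#' the bands x hemispheres family), the hemisphere x condition
#' lateralization ANOVA on the 1-3-Hz memory and navigation effects,
#' narrowband-oscillation detection rates on the per-condition spectra,
#' and (optionally) per-subject decoding. Re-running with an identical
#' configuration reproduces identical outputs.
#'
#' @param config a [runConfig()] list
#' @return object of class "RunReport"
#' @examples
#' \donttest{
#' rep <- runPipeline(runConfig(nSubjects = 5, nTrials = 3))
#' rep$groupTests
#' }
#' @export
runPipeline <- function(config = runConfig()) {
  subs <- vector("list", config$nSubjects)
  for (s in seq_len(config$nSubjects)) {
    sim <- simulateSubject(
      task = taskConfig(nTrials = config$nTrials), arena = config$arena,
      behavior = config$behavior, neural = config$neural,
      montage = synthMontage(contactsPerProbe = config$contactsPerProbe),
      fs = config$fs, seed = config$seed + 7919L * s,
      subject = sprintf("S%02d", s))
    subs[[s]] <- suppressWarnings(analyzeSubject(sim, config))
  }
  effects <- do.call(rbind, lapply(subs, `[[`, "effects"))
  groupTests <- .groupStats(effects, config$alpha)

  ltRows <- effects[effects$band == names(config$bands)[1] &
                      effects$contrast %in% c("memory", "navigation"), ]
  anova <- tryCatch(lateralityAnova(ltRows), error = function(e) NULL)

  # narrowband detection of the planted frequency, by memory condition
  # (needs at least 10 grid frequencies below 50 Hz for the 1/f fit)
  freqs <- attr(subs[[1]]$spectra$remembered, "frequencies")
  narrowband <- NULL
  if (!is.null(freqs) && length(freqs) >= 10) {
    oscF <- config$neural@oscFreqHz
    nbHits <- list(remembered = 0L, forgotten = 0L); nbTotal <- 0L
    nbExp <- c()
    for (sub in subs) {
      for (ch in seq_len(nrow(sub$channels))) {
        nbTotal <- nbTotal + 1L
        for (cond in c("remembered", "forgotten")) {
          sp <- sub$spectra[[cond]][ch, ]
          if (is.null(sp) || any(!is.finite(sp))) next
          det <- narrowbandDetect(sp, freqs)
          if (any(abs(det$flagged - oscF) / oscF < 0.35))
            nbHits[[cond]] <- nbHits[[cond]] + 1L
          if (cond == "remembered") nbExp <- c(nbExp, det$exponent)
        }
      }
    }
    narrowband <- list(nElectrodes = nbTotal,
                       detectionRate = lapply(nbHits, function(k) k / nbTotal),
                       meanExponent = mean(nbExp))
  }

  decoding <- NULL
  if (isTRUE(config$decode)) {
    decoding <- do.call(rbind, lapply(subs, function(sub) {
      auc <- tryCatch(suppressWarnings(
        crossvalAuc(sub$features, config$lambda)$auc),
        error = function(e) NA_real_)
      data.frame(subject = sub$subject, auc = auc)
    }))
  }

  structure(list(
    config = config,
    behavior = lapply(subs, `[[`, "behavior"),
    rejectionFractions = vapply(subs, `[[`, 0, "rejectionFraction"),
    effects = effects, groupTests = groupTests, anova = anova,
    narrowband = narrowband, decoding = decoding,
    groundTruth = list(
      leftMemoryGain = config$neural@leftMemoryGain,
      rightMemoryGain = config$neural@rightMemoryGain,
      leftNavGain = config$neural@leftNavGain,
      rightNavGain = config$neural@rightNavGain)),
    class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport:", length(x$behavior), "subjects, seed",
      x$config$seed, "\n")
  cat(sprintf("  mean accuracy %.3f; mean rejection %.1f%%\n",
              mean(vapply(x$behavior, `[[`, 0, "mean_accuracy")),
              100 * mean(x$rejectionFractions)))
  cat("  group tests:\n")
  gt <- x$groupTests
  for (i in seq_len(nrow(gt)))
    cat(sprintf("    %-10s %-9s %s: t(%d) = %6.2f, p = %.4g%s\n",
                gt$contrast[i], gt$band[i], gt$hemisphere[i], gt$dof[i],
                gt$t[i], gt$p[i], ifelse(gt$significant[i], " *", "")))
  if (!is.null(x$anova))
    cat(sprintf("  hemisphere x condition interaction: F(%d, %d) = %.2f, p = %.4g\n",
                x$anova$dof[1], x$anova$dof[2], x$anova$F_interaction,
                x$anova$p))
  if (!is.null(x$decoding))
    cat(sprintf("  decoding: mean AUC %.3f over %d subjects\n",
                mean(x$decoding$auc), nrow(x$decoding)))
  invisible(x)
}

#' Re-derive cohort statistics on a filtered subset
#'
#' Filters the subject-effect table of a report — excluding rows whose
#' hemisphere lies in the seizure-onset zone, restricting to subjects
#' with bilateral coverage, or applying an arbitrary row predicate — and
#' recomputes the group tests and lateralization ANOVA on the subset.
#'
#' @param report a "RunReport"
#' @param sozExclude drop hemisphere rows flagged as seizure-onset zone
#' @param bilateralOnly keep only subjects contributing both hemispheres
#' @param predicate optional function(effects_row_df) -> logical vector
#' @return the report with filtered effects and recomputed statistics
#' @export
subsetFilter <- function(report, sozExclude = FALSE, bilateralOnly = FALSE,
                         predicate = NULL) {
  ef <- report$effects
  keep <- rep(TRUE, nrow(ef))
  if (sozExclude) keep <- keep & !ef$soz
  if (bilateralOnly) {
    tab <- table(ef$subject, ef$hemisphere)
    bil <- rownames(tab)[rowSums(tab > 0) == 2]
    keep <- keep & ef$subject %in% bil
  }
  if (!is.null(predicate)) keep <- keep & predicate(ef)
  ef <- ef[keep, ]
  if (!nrow(ef)) stop("subset filter removed every row")
  report$effects <- ef
  report$groupTests <- .groupStats(ef, report$config$alpha)
  bands <- names(report$config$bands)
  ltRows <- ef[ef$band == bands[1] &
                 ef$contrast %in% c("memory", "navigation"), ]
  report$anova <- tryCatch(lateralityAnova(ltRows), error = function(e) NULL)
  report
}

#' Write a run report to disk
#'
#' JSON summary (group tests, ANOVA, narrowband, decoding, behavioral
#' means) plus the subject-effect table as TSV.
#'
#' @param report a "RunReport"
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonPath <- file.path(dir, "report.json")
  tsvPath <- file.path(dir, "subject_effects.tsv")
  summary <- list(
    seed = report$config$seed,
    nSubjects = length(report$behavior),
    meanAccuracy = mean(vapply(report$behavior, `[[`, 0, "mean_accuracy")),
    rejectionFractions = report$rejectionFractions,
    groupTests = report$groupTests,
    anova = if (!is.null(report$anova))
      list(F_interaction = report$anova$F_interaction,
           dof = report$anova$dof, p = report$anova$p),
    narrowband = report$narrowband,
    decoding = report$decoding,
    groundTruth = report$groundTruth)
  jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write.table(report$effects, tsvPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(jsonPath, tsvPath))
}
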