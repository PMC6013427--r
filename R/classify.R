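# Per-subject multivariate decoding of subsequent-memory success from
# spectral power features.

#' Classifier frequency sets
#'
#' The decoder uses 10 log-spaced frequencies between 1 and 10 Hz (low)
#' and 10 between 40 and 100 Hz (high), so both ranges contribute a
#' matched number of features.
#'
#' @return list of two [FrequencyGrid-class] objects, \code{low} and
#'   \code{high}
#' @export
classifierGrids <- function() {
  list(low = frequencyGrid(10, 1, 10), high = frequencyGrid(10, 40, 100))
}

#' Build the feature matrix for decoding
#'
#' Rows are labeled encoding events; columns are electrode x frequency
#' z-scored log power averaged over the item-presentation window. Events
#' with any missing (rejected) cell are dropped row-wise.
#'
#' @param lowPower,highPower z-scale 3-D [PowerTensor-class] objects on
#'   the classifier grids (either may be NULL if unused by
#'   \code{freqSet})
#' @param labels per-event labels aligned with the tensor's event rows
#'   ("remembered"/"forgotten"; NA rows are skipped)
#' @param freqSet "low", "high" or "both"
#' @return list(x = feature matrix, y = factor labels, fold = fold ids
#'   (session, or trial when only one session), electrode = electrode id
#'   per column)
#' @export
buildFeatures <- function(lowPower = NULL, highPower = NULL, labels,
                          freqSet = c("both", "low", "high")) {
  freqSet <- match.arg(freqSet)
  use <- list()
  if (freqSet %in% c("both", "low")) use$low <- lowPower
  if (freqSet %in% c("both", "high")) use$high <- highPower
  if (any(vapply(use, is.null, TRUE)))
    stop("freqSet '", freqSet, "' requires the corresponding tensor(s)")
  ref <- use[[1]]
  keep <- which(ref@events$type == "encoding" & !is.na(labels))
  if (!length(keep)) stop("no labeled encoding events")
  blocks <- list(); elec <- character(0)
  for (nm in names(use)) {
    pt <- use[[nm]]
    stopifnot(pt@scale == "z", length(dim(pt@values)) == 3)
    d <- dim(pt@values)
    # columns electrode-major: all freqs of electrode 1, then 2, ...
    m <- do.call(cbind, lapply(seq_len(d[2]), function(ch)
      pt@values[keep, ch, , drop = TRUE]))
    blocks[[nm]] <- m
    elec <- c(elec, rep(pt@channels$id, each = d[3]))
  }
  x <- do.call(cbind, blocks)
  y <- factor(labels[keep], levels = c("forgotten", "remembered"))
  ev <- ref@events[keep, ]
  fold <- if (length(unique(ev$session)) > 1) ev$session else ev$trial
  good <- rowSums(is.na(x)) == 0
  if (sum(good) == 0) stop("no retained events after dropping rejected rows")
  if (any(!good))
    message(sum(!good), " event(s) dropped due to rejected cells")
  list(x = x[good, , drop = FALSE], y = y[good], fold = fold[good],
       electrode = elec)
}

.aucOf <- function(y, p) {
  as.numeric(pROC::auc(response = y, predictor = p,
                       levels = c("forgotten", "remembered"),
                       direction = "<", quiet = TRUE))
}

.fitRidge <- function(x, y, lambda) {
  # small training folds are routine under leave-one-trial-out CV;
  # glmnet's small-class advisory is expected there
  withCallingHandlers(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                   standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Cross-validated decoding AUC
#'
#' Leave-one-fold-out cross-validation of an L2-regularized (ridge)
#' logistic regression: folds are sessions, or trials for single-session
#' subjects. Held-out predicted probabilities are pooled across folds
#' before computing the area under the ROC curve (chance = 0.5). Folds
#' whose training data contain a single class are skipped with a
#' warning.
#'
#' @param features list as returned by [buildFeatures()]
#' @param lambda ridge penalty (glmnet lambda); the model is fit at this
#'   single fixed value, no internal tuning
#' @return object of class "ClassifierResult": list(auc, predictions
#'   data.frame(fold, label, prob), nFolds)
#' @export
crossvalAuc <- function(features, lambda = 1) {
  x <- features$x; y <- features$y; fold <- features$fold
  folds <- unique(fold)
  if (length(folds) < 2) stop("need at least 2 cross-validation folds")
  if (length(unique(y)) < 2) stop("both classes must be present")
  preds <- list()
  for (f in folds) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) {
      warning("fold ", f, ": single-class training set; skipped")
      next
    }
    fit <- tryCatch(.fitRidge(x[tr, , drop = FALSE], y[tr], lambda),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("fold ", f, ": model fit failed; skipped")
      next
    }
    p <- predict(fit, x[!tr, , drop = FALSE], type = "response")[, 1]
    preds[[length(preds) + 1L]] <- data.frame(fold = f, label = y[!tr],
                                              prob = p)
  }
  if (!length(preds)) stop("all folds skipped")
  preds <- do.call(rbind, preds)
  structure(list(auc = .aucOf(preds$label, preds$prob), predictions = preds,
                 nFolds = length(folds)),
            class = "ClassifierResult")
}

#' @export
print.ClassifierResult <- function(x, ...) {
  cat(sprintf("ClassifierResult: AUC = %.3f over %d folds, %d events\n",
              x$auc, x$nFolds, nrow(x$predictions)))
  invisible(x)
}

#' Label-shuffle null distribution of the decoding AUC
#'
#' Re-runs the full cross-validation after permuting the subject's
#' remembered/forgotten labels (identity permutations are excluded by
#' redrawing), yielding a null AUC distribution of size
#' \code{nShuffles}.
#'
#' @inheritParams crossvalAuc
#' @param nShuffles number of label permutations
#' @param seed integer seed
#' @return list(nullAucs, trueAuc, p) where p = (1 + #null >= true) /
#'   (nShuffles + 1)
#' @export
shuffleNull <- function(features, lambda = 1, nShuffles = 100, seed = 1) {
  set.seed(seed)
  trueAuc <- crossvalAuc(features, lambda)$auc
  n <- length(features$y)
  nullAucs <- numeric(nShuffles)
  for (k in seq_len(nShuffles)) {
    repeat {
      perm <- sample.int(n)
      if (!all(perm == seq_len(n))) break
    }
    f2 <- features; f2$y <- features$y[perm]
    nullAucs[k] <- tryCatch(crossvalAuc(f2, lambda)$auc,
                            error = function(e) NA_real_,
                            warning = function(w) {
                              suppressWarnings(crossvalAuc(f2, lambda)$auc)
                            })
  }
  nullAucs <- nullAucs[!is.na(nullAucs)]
  list(nullAucs = nullAucs, trueAuc = trueAuc,
       p = (1 + sum(nullAucs >= trueAuc)) / (length(nullAucs) + 1))
}

#' Decoding performance as a function of electrode count
#'
#' Per repetition: split the encoding events into random halves; on the
#' training half compute a two-sample t between classes at every
#' feature, rank electrodes by their maximum absolute t across
#' frequencies, then for each N train the ridge logistic model on the
#' top-N electrodes and evaluate AUC on the held-out half. Mean AUC per
#' N over repetitions. Curves are truncated at the subject's electrode
#' count.
#'
#' @inheritParams crossvalAuc
#' @param nReps repetitions of the half-split procedure
#' @param nMax largest electrode count
#' @param seed integer seed
#' @return data.frame(N, meanAuc, nReps)
#' @export
electrodeSweep <- function(features, lambda = 1, nReps = 100, nMax = 50,
                           seed = 1) {
  set.seed(seed)
  x <- features$x; y <- features$y
  elec <- features$electrode
  uElec <- unique(elec)
  nMax <- min(nMax, length(uElec))
  if (length(uElec) < 2) stop("need at least 2 electrodes")
  n <- length(y)
  aucs <- matrix(NA_real_, nReps, nMax)
  for (r in seq_len(nReps)) {
    # stratified half split
    tr <- logical(n)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      tr[sample(idx, floor(length(idx) / 2))] <- TRUE
    }
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
    xa <- x[tr & y == "remembered", , drop = FALSE]
    xb <- x[tr & y == "forgotten", , drop = FALSE]
    na <- nrow(xa); nb <- nrow(xb)
    if (na < 2 || nb < 2) next
    va <- apply(xa, 2, var); vb <- apply(xb, 2, var)
    sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
    tstat <- (colMeans(xa) - colMeans(xb)) / (sp * sqrt(1 / na + 1 / nb))
    tstat[!is.finite(tstat)] <- 0
    score <- tapply(abs(tstat), elec, max)
    ranked <- names(sort(score, decreasing = TRUE))
    for (N in seq_len(nMax)) {
      cols <- which(elec %in% ranked[seq_len(N)])
      fit <- .fitRidge(x[tr, cols, drop = FALSE], y[tr], lambda)
      p <- predict(fit, x[!tr, cols, drop = FALSE], type = "response")[, 1]
      aucs[r, N] <- .aucOf(y[!tr], p)
    }
  }
  data.frame(N = seq_len(nMax), meanAuc = colMeans(aucs, na.rm = TRUE),
             nReps = colSums(!is.na(aucs)))
}
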