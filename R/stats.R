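# Contrast construction, group inference, permutation nulls,
# lateralization ANOVA, spatial aggregation, narrowband detection.

#' Build subject-level contrasts from band power
#'
#' For each electrode, computes the difference of condition means of
#' z-scored band power between the two condition levels (e.g. remembered
#' minus forgotten, navigation minus baseline, item minus no-item), then
#' averages over a subject's electrodes within hemisphere to one value
#' per subject x hemisphere row. Electrodes missing either condition are
#' skipped with a warning. Rejected event x channel cells should be NA'd
#' out before calling.
#'
#' @param values events x channels matrix of band power (one subject)
#' @param condition character/factor per event; contrast = mean(level1)
#'   minus mean(level2)
#' @param levels length-2 character: the two condition levels, in
#'   (positive, negative) order
#' @param channels channel metadata (needs \code{hemisphere})
#' @param subject subject id for the output rows
#' @param band,contrast labels carried to the output
#' @return data.frame rows: subject, hemisphere, band, contrast, value,
#'   n_electrodes (the subject-effect table schema)
#' @export
buildContrast <- function(values, condition, levels, channels,
                          subject = "S01", band = "low_theta",
                          contrast = "memory") {
  stopifnot(nrow(values) == length(condition),
            ncol(values) == nrow(channels))
  perElec <- rep(NA_real_, ncol(values))
  for (ch in seq_len(ncol(values))) {
    a <- values[condition == levels[1], ch]
    b <- values[condition == levels[2], ch]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) {
      warning("electrode ", channels$id[ch],
              ": a condition has no events; skipped")
      next
    }
    perElec[ch] <- mean(a) - mean(b)
  }
  out <- list()
  for (h in unique(channels$hemisphere)) {
    v <- perElec[channels$hemisphere == h]
    v <- v[!is.na(v)]
    if (!length(v)) next
    out[[length(out) + 1L]] <- data.frame(
      subject = subject, hemisphere = h, band = band, contrast = contrast,
      value = mean(v), n_electrodes = length(v), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Group-level t-tests
#'
#' One-sample (vs 0), paired, or two-sample t-test on subject-level
#' values; a thin wrapper returning statistic, dof and two-sided p.
#' Zero-variance inputs raise an informative error.
#'
#' @param x numeric values (differences for the one-sample test)
#' @param y second sample for paired/two-sample variants
#' @param type "one_sample", "paired" or "two_sample" (pooled variance)
#' @return list(t, dof, p, n)
#' @examples
#' groupTtest(c(0.1, 0.2, 0.3, 0.4, 0.5))  # t = 4.2426, dof = 4
#' @export
groupTtest <- function(x, y = NULL, type = c("one_sample", "paired",
                                             "two_sample")) {
  type <- match.arg(type)
  res <- tryCatch(switch(type,
    one_sample = t.test(x, mu = 0),
    paired = t.test(x, y, paired = TRUE),
    two_sample = t.test(x, y, var.equal = TRUE)),
    error = function(e) stop("t-test failed (zero variance?): ",
                             conditionMessage(e)))
  list(t = unname(res$statistic), dof = unname(res$parameter),
       p = res$p.value, n = length(x))
}

# per-bin one-sample t across subjects for an n_subj x n_bins matrix
.binT <- function(maps) {
  n <- nrow(maps)
  m <- colMeans(maps)
  v <- (colSums(maps^2) - n * m^2) / (n - 1)
  m / sqrt(v / n)
}

#' Cluster-based permutation test on subject maps
#'
#' Tests subject-level effect maps (frequency x time, or 1-D time traces)
#' against zero while controlling the family-wise error over bins. Per
#' bin a one-sample t across subjects is computed; bins exceeding the
#' two-sided parametric critical value at \code{clusterAlpha} form
#' same-sign clusters under 4-connectivity (1-D adjacency for traces);
#' each cluster's mass is the sum of its t values. The null flips each
#' subject's whole map sign at random per permutation and records the
#' maximum absolute cluster mass; cluster p-values are the fraction of
#' null maxima at or above the observed absolute mass, with the standard
#' (k+1)/(n+1) correction.
#'
#' @param maps subjects x bins matrix; for 2-D maps give \code{mapDim =
#'   c(nFreq, nTime)} with bins laid out column-major
#' @param mapDim c(rows, cols) of the map; default 1-D
#' @param clusterAlpha two-sided cluster-forming alpha
#' @param nPerm number of sign-flip permutations
#' @param seed integer seed
#' @return object of class "ClusterResult": list of clusters (bins, mass,
#'   p), the bin t map, threshold, and the null distribution
#' @export
clusterPermutation <- function(maps, mapDim = c(ncol(maps), 1L),
                               clusterAlpha = 0.05, nPerm = 1000, seed = 1) {
  n <- nrow(maps); nb <- ncol(maps)
  stopifnot(prod(mapDim) == nb, n >= 5)
  tcrit <- qt(1 - clusterAlpha / 2, n - 1)
  tobs <- .binT(maps)
  clusters <- list()
  if (any(is.finite(tobs) & abs(tobs) > tcrit)) {
    t0 <- tobs; t0[!is.finite(t0)] <- 0
    lab <- cpp_cluster_label(t0, mapDim[1], mapDim[2], tcrit)
    for (k in seq_len(max(lab))) {
      bins <- which(lab == k)
      clusters[[k]] <- list(bins = bins, mass = sum(t0[bins]))
    }
  }
  set.seed(seed)
  ss <- colSums(maps^2)  # invariant under sign flips
  S <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
  M <- (S %*% maps) / n
  V <- sweep(-n * M^2, 2, ss, `+`) / (n - 1)
  Tn <- M / sqrt(V / n)
  Tn[!is.finite(Tn)] <- 0
  nullMax <- cpp_max_cluster_mass(Tn, mapDim[1], mapDim[2], tcrit)
  for (k in seq_along(clusters))
    clusters[[k]]$p <- (1 + sum(nullMax >= abs(clusters[[k]]$mass))) /
      (nPerm + 1)
  structure(list(clusters = clusters, t = tobs, tCrit = tcrit,
                 mapDim = mapDim, nullMax = nullMax, nPerm = nPerm),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("ClusterResult:", length(x$clusters), "cluster(s),",
      x$nPerm, "permutations, |t| threshold", round(x$tCrit, 3), "\n")
  for (k in seq_along(x$clusters))
    cat(sprintf("  cluster %d: %d bins, mass %.2f, p = %.4g\n", k,
                length(x$clusters[[k]]$bins), x$clusters[[k]]$mass,
                x$clusters[[k]]$p))
  invisible(x)
}

#' Sign-flip null thresholds for spatial t maps
#'
#' For per-subject values at each spatial point, builds a null
#' distribution of group t statistics by flipping the sign of a uniformly
#' random half (floor(n/2)) of the subjects at each point and
#' recomputing the one-sample t, pooled over points and permutations.
#' Returns the 2.5th and 97.5th percentiles as the negative and positive
#' significance thresholds. Points with fewer than 5 subjects are
#' excluded.
#'
#' @param values subjects x points matrix (NA = subject absent at point)
#' @param nPerm permutations
#' @param seed integer seed
#' @return list(lower, upper, null (nPerm x points t matrix), excluded)
#' @export
signflipMapThreshold <- function(values, nPerm = 1000, seed = 1) {
  set.seed(seed)
  nsub <- colSums(!is.na(values))
  excluded <- which(nsub < 5)
  keep <- setdiff(seq_len(ncol(values)), excluded)
  if (!length(keep)) stop("no point has >= 5 subjects")
  nullT <- matrix(NA_real_, nPerm, length(keep))
  for (j in seq_along(keep)) {
    v <- values[!is.na(values[, keep[j]]), keep[j]]
    n <- length(v); nf <- floor(n / 2)
    for (p in seq_len(nPerm)) {
      s <- rep(1, n); s[sample.int(n, nf)] <- -1
      x <- s * v
      nullT[p, j] <- mean(x) / (sd(x) / sqrt(n))
    }
  }
  qs <- quantile(nullT, c(0.025, 0.975), na.rm = TRUE)
  list(lower = unname(qs[1]), upper = unname(qs[2]), null = nullT,
       excluded = excluded)
}

#' Aggregate electrode effects onto spatial target points
#'
#' Assigns to every target point the mean effect of a subject's
#' electrodes lying within \code{radius} mm (12.5 mm for cortical
#' surfaces, 3 mm for hippocampal voxel maps), optionally followed by
#' Gaussian smoothing (FWHM in mm) of the per-subject map across
#' assigned points. Points reached by fewer than \code{minSubjects}
#' subjects are flagged excluded.
#'
#' @param effects list (per subject) of per-electrode effect vectors
#' @param coords list (per subject) of electrodes x 3 coordinate matrices
#' @param targets points x 3 target coordinate matrix (mm)
#' @param radius assignment radius (mm)
#' @param smoothFwhm Gaussian smoothing FWHM in mm (0 = none)
#' @param minSubjects minimum contributing subjects per point
#' @return list(maps = subjects x points matrix, nSubjects, excluded)
#' @export
spatialAggregate <- function(effects, coords, targets, radius = 12.5,
                             smoothFwhm = 0, minSubjects = 5) {
  if (!nrow(targets)) stop("empty target set")
  nsub <- length(effects)
  maps <- matrix(NA_real_, nsub, nrow(targets))
  for (s in seq_len(nsub)) {
    xy <- coords[[s]]; ef <- effects[[s]]
    d <- sqrt(outer(rowSums(targets^2), rowSums(xy^2), `+`) -
                2 * targets %*% t(xy))
    for (p in seq_len(nrow(targets))) {
      hit <- which(d[p, ] <= radius)
      if (length(hit)) maps[s, p] <- mean(ef[hit])
    }
    if (smoothFwhm > 0) {
      sigma <- smoothFwhm / (2 * sqrt(2 * log(2)))
      dd <- as.matrix(dist(targets))
      w <- exp(-dd^2 / (2 * sigma^2))
      assigned <- which(!is.na(maps[s, ]))
      if (length(assigned) > 1) {
        sm <- maps[s, ]
        for (p in assigned) {
          wp <- w[p, assigned]
          sm[p] <- sum(wp * maps[s, assigned]) / sum(wp)
        }
        maps[s, ] <- sm
      }
    }
  }
  nSubjects <- colSums(!is.na(maps))
  list(maps = maps, nSubjects = nSubjects,
       excluded = which(nSubjects < minSubjects))
}

#' Hemisphere x condition lateralization ANOVA
#'
#' Two-way fixed-effects ANOVA with interaction on subject-level effect
#' values, factors hemisphere (L/R) and condition (e.g. memory vs
#' navigation contrast). Type-II sums of squares accommodate the
#' unbalanced hemisphere groups. Post-hoc cell tests are one-sample
#' t-tests of each hemisphere x condition cell against zero, plus pooled
#' two-sample t-tests comparing hemispheres within condition.
#'
#' @param effects data.frame with columns \code{value},
#'   \code{hemisphere}, \code{contrast} (the condition factor), as built
#'   by [buildContrast()]
#' @return list(F_interaction, dof, p, anova (car type-II table),
#'   posthoc)
#' @importFrom car Anova
#' @export
lateralityAnova <- function(effects) {
  effects$hemisphere <- factor(effects$hemisphere)
  effects$contrast <- factor(effects$contrast)
  tab <- table(effects$hemisphere, effects$contrast)
  if (any(tab < 2)) stop("need >= 2 observations per hemisphere x condition cell")
  fit <- lm(value ~ hemisphere * contrast, data = effects)
  an <- car::Anova(fit, type = 2)
  irow <- grep(":", rownames(an))
  posthoc <- list()
  for (h in levels(effects$hemisphere)) for (cc in levels(effects$contrast)) {
    v <- effects$value[effects$hemisphere == h & effects$contrast == cc]
    posthoc[[paste(h, cc, sep = ".")]] <- groupTtest(v)
  }
  for (cc in levels(effects$contrast)) {
    a <- effects$value[effects$hemisphere == levels(effects$hemisphere)[1] &
                         effects$contrast == cc]
    b <- effects$value[effects$hemisphere == levels(effects$hemisphere)[2] &
                         effects$contrast == cc]
    posthoc[[paste0("LvR.", cc)]] <- groupTtest(a, b, type = "two_sample")
  }
  list(F_interaction = an$`F value`[irow],
       dof = c(an$Df[irow], an$Df[rownames(an) == "Residuals"]),
       p = an$`Pr(>F)`[irow], anova = an, posthoc = posthoc)
}

#' Narrowband oscillation detection against the 1/f background
#'
#' Fits the aperiodic background of a mean log-power spectrum by robust
#' linear regression of log power on log frequency (iteratively
#' reweighted least squares with bisquare weights), then flags any
#' frequency whose residual exceeds one residual SD above the fit as
#' exhibiting narrowband oscillatory activity. The negated slope
#' estimates the background power-law exponent.
#'
#' @param spectrum mean log-power values at \code{freqs}
#' @param freqs frequencies (Hz), typically the 1-50-Hz portion of the
#'   analysis grid
#' @param sdCriterion residual threshold in residual-SD units
#' @return object of class "NarrowbandResult": list(slope, intercept,
#'   exponent = -slope, residSd, flagged (Hz), residuals)
#' @importFrom MASS rlm psi.bisquare
#' @export
narrowbandDetect <- function(spectrum, freqs, sdCriterion = 1) {
  if (length(spectrum) < 10) stop("need >= 10 frequencies")
  if (any(!is.finite(spectrum)) || any(!is.finite(freqs)))
    stop("non-finite spectrum or frequency values")
  lf <- log(freqs)
  # an exactly linear spectrum makes the IRLS weights degenerate; the
  # fit is already exact there, so the non-convergence advisory is moot
  fit <- withCallingHandlers(
    MASS::rlm(spectrum ~ lf, psi = MASS::psi.bisquare, maxit = 50,
              acc = 1e-8),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  res <- residuals(fit)
  rsd <- sd(res)
  flagged <- freqs[res > sdCriterion * rsd]
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 exponent = -unname(coef(fit)[2]),
                 residSd = rsd, flagged = flagged, residuals = res,
                 freqs = freqs),
            class = "NarrowbandResult")
}

#' @export
print.NarrowbandResult <- function(x, ...) {
  cat(sprintf("NarrowbandResult: exponent %.3f, residual SD %.3f\n",
              x$exponent, x$residSd))
  if (length(x$flagged))
    cat("  flagged:", paste(round(x$flagged, 2), collapse = ", "), "Hz\n")
  else cat("  no narrowband frequencies flagged\n")
  invisible(x)
}

#' Within-subject standard error of condition means
#'
#' Removes between-subject offsets before computing per-condition SEMs:
#' each subject's row is centred on its own mean and the grand mean is
#' restored, then the SEM of each condition column is computed across
#' subjects.
#'
#' @param mat complete subjects x conditions matrix of means
#' @return per-condition SEM vector
#' @examples
#' withinSubjectSem(rbind(c(1, 2), c(3, 4)))  # c(0, 0)
#' @export
withinSubjectSem <- function(mat) {
  if (any(is.na(mat))) stop("matrix must be complete (no missing cells)")
  if (nrow(mat) < 2) stop("need at least 2 subjects")
  cen <- mat - rowMeans(mat) + mean(mat)
  apply(cen, 2, sd) / sqrt(nrow(mat))
}
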