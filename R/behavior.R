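# Behavioral scoring: percentile-rank accuracy, memory labeling, spatial
# binning, and the in-task points economy.

#' Percentile-rank spatial accuracy score
#'
#' Transforms a raw placement error into a location-unbiased accuracy in
#' [0, 1]: the percentile rank of the observed Euclidean error among the
#' errors of all possible response locations, enumerated on a uniform grid
#' covering the arena. Because the set of achievable errors depends on how
#' close the target sits to the boundary, ranking against that set makes
#' the score distribution identical for every target location. 1 is a
#' perfect response, 0 the worst possible.
#'
#' Ties receive half weight, and a grid candidate coinciding with the
#' response itself is excluded, so a zero-error response scores exactly 1
#' and the unique worst response exactly 0.
#'
#' @param trueLocation,responseLocation length-2 numeric (x, y), inside
#'   the arena
#' @param arena an [ArenaConfig-class]
#' @param gridStep candidate grid spacing in virtual units (default 1,
#'   i.e. 101 x 71 = 7171 candidates for the default arena)
#' @return accuracy in [0, 1]
#' @examples
#' a <- arenaConfig()
#' accuracyScore(c(50, 35), c(50, 35), a)   # 1
#' accuracyScore(c(50, 35), c(0, 0), a)     # ~0 (corner = worst case)
#' @export
accuracyScore <- function(trueLocation, responseLocation,
                          arena = arenaConfig(), gridStep = 1) {
  .checkInArena(trueLocation, arena); .checkInArena(responseLocation, arena)
  if (gridStep <= 0) stop("gridStep must be positive")
  gx <- seq(0, arena@width, by = gridStep)
  gy <- seq(0, arena@height, by = gridStep)
  if (length(gx) * length(gy) < 2)
    stop("candidate grid must contain at least 2 locations")
  dx2 <- (gx - trueLocation[1])^2
  dy2 <- (gy - trueLocation[2])^2
  errs <- sqrt(outer(dx2, dy2, `+`))
  obs <- sqrt(sum((trueLocation - responseLocation)^2))
  # drop the candidate that *is* the response (if the response lies on
  # the grid) so the endpoints are exact
  ex2 <- outer((gx - responseLocation[1])^2, (gy - responseLocation[2])^2, `+`)
  self <- ex2 < 1e-12
  tol <- 1e-9
  greater <- sum(errs > obs + tol & !self)
  equal <- sum(abs(errs - obs) <= tol & !self)
  acc <- (greater + 0.5 * equal) / (length(errs) - 1)
  min(max(acc, 0), 1)
}

.checkInArena <- function(p, arena) {
  if (length(p) != 2 || any(!is.finite(p)))
    stop("location must be a finite (x, y) pair")
  if (p[1] < 0 || p[1] > arena@width || p[2] < 0 || p[2] > arena@height)
    stop(sprintf("location (%g, %g) lies outside the %g x %g arena",
                 p[1], p[2], arena@width, arena@height))
  invisible(TRUE)
}

#' Score all responses of a session
#'
#' Fills the \code{accuracy} column of a session's response table using
#' [accuracyScore()].
#'
#' @param session a [TaskSession-class]
#' @param gridStep candidate grid spacing (virtual units)
#' @return the session with accuracies filled in
#' @export
scoreSession <- function(session, gridStep = 1) {
  rs <- session@responses
  for (i in seq_len(nrow(rs)))
    rs$accuracy[i] <- accuracyScore(
      c(rs$true_x[i], rs$true_y[i]),
      c(rs$response_x[i], rs$response_y[i]),
      session@arena, gridStep)
  session@responses <- rs
  session
}

#' Median-split subsequent-memory labeling
#'
#' Splits a subject's responses into remembered and forgotten: a response
#' is labeled remembered iff its accuracy strictly exceeds the median
#' accuracy over all of the subject's responses (pooled across sessions)
#' and its confidence was "Yes" or "Maybe". This refined measure differs
#' deliberately from the in-task points feedback (see [scorePoints()]).
#'
#' @param responses data.frame with columns \code{accuracy} and
#'   \code{confidence} (one row per response; pool sessions before
#'   calling)
#' @return the input with columns \code{label} ("remembered"/"forgotten")
#'   and \code{median_accuracy} appended
#' @examples
#' r <- data.frame(accuracy = c(0.9, 0.8, 0.6, 0.4),
#'                 confidence = c("Yes", "No", "Yes", "Maybe"))
#' labelMemory(r)$label
#' @export
labelMemory <- function(responses) {
  if (nrow(responses) < 2) stop("need at least 2 responses to median-split")
  if (any(is.na(responses$confidence)) ||
      !all(responses$confidence %in% c("Yes", "Maybe", "No")))
    stop("every response needs a confidence in {Yes, Maybe, No}")
  if (any(is.na(responses$accuracy))) stop("every response needs an accuracy")
  med <- median(responses$accuracy)
  responses$median_accuracy <- med
  responses$label <- ifelse(
    responses$accuracy > med & responses$confidence %in% c("Yes", "Maybe"),
    "remembered", "forgotten")
  responses
}

#' Spatial binning of item locations
#'
#' Two binning schemes used for behavioral analyses: (i) inner vs
#' boundary region, where the inner region is a centred rectangle with the
#' arena's aspect ratio and exactly half its area (side scale 1/sqrt(2));
#' (ii) near vs far half of the arena relative to the trial's retrieval
#' viewpoint, split at the midline perpendicular to the long axis.
#'
#' @param location length-2 numeric (x, y) inside the arena
#' @param arena an [ArenaConfig-class]
#' @param testViewpoint viewpoint index (1 or 2, rows of
#'   \code{arena@viewpoints}) or a length-2 coordinate
#' @return list with elements \code{region} ("inner"/"boundary") and
#'   \code{half} ("near"/"far")
#' @examples
#' spatialBin(c(50, 35), arenaConfig(), 1)
#' @export
spatialBin <- function(location, arena = arenaConfig(), testViewpoint = 1) {
  .checkInArena(location, arena)
  s <- 1 / sqrt(2)
  hw <- arena@width * s / 2; hh <- arena@height * s / 2
  cx <- arena@width / 2; cy <- arena@height / 2
  inner <- abs(location[1] - cx) <= hw && abs(location[2] - cy) <= hh
  vp <- if (length(testViewpoint) == 2) testViewpoint
        else arena@viewpoints[testViewpoint, ]
  # near/far split along the long (viewpoint) axis
  near <- abs(location[1] - vp[1]) <= arena@width / 2
  list(region = if (inner) "inner" else "boundary",
       half = if (near) "near" else "far")
}

#' In-task points economy
#'
#' Points feedback given to the patient after each trial: a response is
#' "correct" when the response circle (radius 13 virtual units) contains
#' the object's true location. High confidence ("Yes") earns +200 when
#' correct and loses 350 otherwise; "Maybe" earns +100 / loses 50; "No"
#' earns +50 when correct and loses nothing.
#'
#' @param confidence "Yes", "Maybe" or "No" (vectorized)
#' @param correct logical: did the response circle contain the true
#'   location
#' @return signed points (vectorized)
#' @examples
#' scorePoints("Yes", TRUE)    # +200
#' scorePoints("No", FALSE)    # 0
#' @export
scorePoints <- function(confidence, correct) {
  if (any(!confidence %in% c("Yes", "Maybe", "No")))
    stop("confidence must be Yes, Maybe or No")
  tab <- matrix(c(200, -350, 100, -50, 50, 0), nrow = 3, byrow = TRUE,
                dimnames = list(c("Yes", "Maybe", "No"),
                                c("correct", "incorrect")))
  tab[cbind(confidence, ifelse(correct, "correct", "incorrect"))]
}

#' Per-subject behavioral summary
#'
#' Mean accuracy overall, by confidence, by inner/boundary region and by
#' near/far half, plus total points earned under the in-task economy.
#'
#' @param session a scored [TaskSession-class] (see [scoreSession()])
#' @return a list of summary statistics
#' @export
behavioralSummary <- function(session) {
  rs <- session@responses
  if (any(is.na(rs$accuracy))) stop("score the session first (scoreSession)")
  arena <- session@arena
  bins <- lapply(seq_len(nrow(rs)), function(i)
    spatialBin(c(rs$true_x[i], rs$true_y[i]), arena, rs$viewpoint[i]))
  region <- vapply(bins, `[[`, "", "region")
  half <- vapply(bins, `[[`, "", "half")
  correct <- rs$raw_error <= arena@responseCircleRadius
  list(
    n = nrow(rs),
    mean_accuracy = mean(rs$accuracy),
    accuracy_by_confidence = tapply(rs$accuracy, rs$confidence, mean),
    accuracy_by_region = tapply(rs$accuracy, region, mean),
    accuracy_by_half = tapply(rs$accuracy, half, mean),
    total_points = sum(scorePoints(rs$confidence, correct)))
}
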