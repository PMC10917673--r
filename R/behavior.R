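#' Rank-based memory performance from drop errors
#'
#' Transforms drop errors (Euclidean distance between response and correct
#' object location) into performance values in \code{[0, 1]} by ranking each
#' drop error within surrogate drop errors, computed as distances between the
#' trial-specific correct location and random locations drawn uniformly over
#' the circular arena. Performance is the fraction of surrogate drop errors
#' strictly greater than the observed one, so 1 is the best and 0 the worst
#' possible response given where the object sits: the same drop error maps to
#' a higher performance the closer the correct location is to the arena
#' boundary. For an object at the arena centre the transform has the closed
#' form \eqn{1 - (d/r)^2}.
#'
#' @param correct n x 2 matrix (or length-2 vector) of correct locations (vu).
#' @param response n x 2 matrix (or length-2 vector) of response locations.
#' @param arenaRadius arena radius in vu (default 5000, i.e. a ~10,000 vu
#'   diameter arena).
#' @param nSurrogates number of surrogate locations (default 1e7). Values
#'   below 1e4 trigger a warning (poor rank resolution).
#' @param seed optional integer seed for the surrogate draw.
#' @return numeric vector of performance values in \code{[0, 1]}.
#' @export
memoryPerformance <- function(correct, response, arenaRadius = 5000,
                              nSurrogates = 1e7, seed = NULL) {
  if (is.null(dim(correct))) correct <- matrix(correct, ncol = 2L)
  if (is.null(dim(response))) response <- matrix(response, ncol = 2L)
  stopifnot(nrow(correct) == nrow(response))
  if (any(rowSums(correct^2) > arenaRadius^2 + 1e-9) ||
      any(rowSums(response^2) > arenaRadius^2 + 1e-9))
    stop("locations must lie inside the arena")
  if (nSurrogates < 1e4)
    warning("fewer than 1e4 surrogate drop errors: coarse rank resolution")
  if (!is.null(seed)) set.seed(seed)
  ## uniform over the disk by inverse-CDF radius
  u <- runif(nSurrogates)
  th <- runif(nSurrogates, 0, 2 * pi)
  sx <- arenaRadius * sqrt(u) * cos(th)
  sy <- arenaRadius * sqrt(u) * sin(th)
  d <- sqrt(rowSums((correct - response)^2))
  vapply(seq_len(nrow(correct)), function(i) {
    sd2 <- (sx - correct[i, 1L])^2 + (sy - correct[i, 2L])^2
    mean(sd2 > d[i]^2)
  }, numeric(1))
}

#' Append memory-performance values to a trial table
#'
#' @param trials trial table with columns correct_x, correct_y, response_x,
#'   response_y.
#' @inheritParams memoryPerformance
#' @return the trial table with columns drop_error and performance
#'   added/replaced.
#' @export
addMemoryPerformance <- function(trials, arenaRadius = 5000,
                                 nSurrogates = 1e7, seed = NULL) {
  co <- cbind(trials$correct_x, trials$correct_y)
  re <- cbind(trials$response_x, trials$response_y)
  trials$drop_error <- sqrt(rowSums((co - re)^2))
  trials$performance <- memoryPerformance(co, re, arenaRadius, nSurrogates,
                                          seed)
  trials
}

#' Learning summaries: early/late split and normalized-time curve
#'
#' Early trials are trials 1 to n/2 (n = total trial count), late trials the
#' remainder. The normalized-time curve averages performance in 20 equal
#' bins of normalized trial index and reports the Pearson correlation of bin
#' index with the bin means.
#'
#' @param trials trial table containing a performance column.
#' @param nBins number of normalized-time bins (default 20).
#' @return list with earlyMean, lateMean, binMeans, r (NA when the curve is
#'   constant).
#' @export
learningSummaries <- function(trials, nBins = 20L) {
  perf <- trials$performance
  n <- length(perf)
  stopifnot(n >= 4L)
  half <- floor(n / 2)
  earlyMean <- mean(perf[seq_len(half)])
  lateMean <- mean(perf[(half + 1L):n])
  bin <- pmin(nBins, ceiling(seq_len(n) / n * nBins))
  binMeans <- as.numeric(tapply(perf, factor(bin, levels = seq_len(nBins)),
                                mean))
  ok <- !is.na(binMeans)
  r <- if (sum(ok) > 2L && sd(binMeans[ok]) > 0)
    cor(seq_len(nBins)[ok], binMeans[ok]) else NA_real_
  list(earlyMean = earlyMean, lateMean = lateMean, binMeans = binMeans,
       r = r)
}

#' Movement state and idle mask from a navigation trace
#'
#' Speed is computed from finite differences of the 50 Hz position trace.
#' Samples with speed above 0.001 vu/s count as movement. Idle episodes are
#' runs longer than 2 s in which the participant neither translated nor
#' turned; those samples form the idle mask excluded from rate maps.
#'
#' @param nav navigation data.frame with columns t, x, y, heading.
#' @param speedThreshold movement threshold in vu/s (default 0.001).
#' @param idleMinS minimum idle episode duration in seconds (default 2).
#' @return list with speed (vu/s), moving (logical) and idle (logical), all
#'   aligned to nav rows.
#' @export
movementState <- function(nav, speedThreshold = 0.001, idleMinS = 2) {
  n <- nrow(nav)
  dt <- diff(nav$t)
  step <- sqrt(diff(nav$x)^2 + diff(nav$y)^2)
  speed <- c(step / dt, 0)
  moving <- speed > speedThreshold
  dh <- c(abs((diff(nav$heading) + 180) %% 360 - 180), 0)
  still <- !moving & dh < 1e-9
  idle <- logical(n)
  runs <- runsFromLogical(still)
  if (nrow(runs)) {
    len <- nav$t[runs$end] - nav$t[runs$start]
    for (i in which(len > idleMinS))
      idle[runs$start[i]:runs$end[i]] <- TRUE
  }
  list(speed = speed, moving = moving, idle = idle)
}

#' Trial of strongest memory improvement for one object
#'
#' Smooths the per-trial performance values of one object with a running
#' average of three trials (centred, shrunk at the edges), then iteratively
#' computes a two-sample t-statistic between trials (i+1):n and 1:i for each
#' candidate split i, and returns the trial index with the largest t. The
#' first and last trials are excluded from candidacy; ties resolve to the
#' earliest index.
#'
#' @param performance numeric vector of per-trial performance values for the
#'   object's trials, in presentation order.
#' @return list with trial (index into performance, NA when undefined),
#'   tStat and the smoothed series.
#' @export
memoryFormationTrial <- function(performance) {
  n <- length(performance)
  stopifnot(n >= 4L)
  sm <- movingAverage(performance, 3L)
  cand <- 2:(n - 1L)
  ts <- vapply(cand, function(i)
    pooledT(sm[(i + 1L):n], sm[seq_len(i)]), numeric(1))
  if (all(is.na(ts)))
    return(list(trial = NA_integer_, tStat = NA_real_, smoothed = sm))
  best <- which.max(ts)
  list(trial = cand[best], tStat = ts[best], smoothed = sm)
}

#' Trial of strongest improvement for every object in a trial table
#'
#' @param trials trial table with object_id and performance columns.
#' @return data.frame with object_id, the session-level trial index of
#'   strongest improvement (formation_trial, NA when undefined) and tStat.
#' @export
memoryFormationByObject <- function(trials) {
  objs <- sort(unique(trials$object_id))
  res <- lapply(objs, function(o) {
    idx <- which(trials$object_id == o)
    if (length(idx) < 4L)
      return(data.frame(object_id = o, formation_trial = NA_integer_,
                        tStat = NA_real_))
    mf <- memoryFormationTrial(trials$performance[idx])
    data.frame(object_id = o,
               formation_trial = if (is.na(mf$trial)) NA_integer_ else
                 trials$trial_index[idx[mf$trial]],
               tStat = mf$tStat)
  })
  do.call(rbind, res)
}
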