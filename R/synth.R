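## Synthetic-session generator. Produces behaviour, LFP and spike trains
## with known ground truth (injected ripple/IED times, tuning, coactive
## pairs) so every downstream stage can be validated without patient data.

#' Simulate task behaviour: navigation trace and trial table
#'
#' Generates a 50 Hz position/heading trace and a trial table for the
#' associative object-location task. Each trial consists of an ITI
#' (uniform 3-5 s, stationary), a 2 s cue, a self-paced retrieval period
#' (log-normal, mean 13.415 s) during which the participant travels to the
#' response location, 1.5 s of feedback, and a self-paced re-encoding
#' period (log-normal, mean 7.685 s) travelling to the correct location.
#' Cue objects cycle over the eight objects in shuffled blocks. Response
#' locations are drawn around the correct location with a dispersion that
#' decays over presentations of the same object, producing a learning
#' curve; stationary ITIs provide the idle (> 2 s) episodes needed by the
#' movement-split analyses.
#'
#' @param nTrials number of test trials (>= 1).
#' @param nObjects number of objects (default 8).
#' @param arenaRadius arena radius in vu (default 5000).
#' @param seed integer seed.
#' @param errSd0,errSdFloor,errTau learning-curve parameters: response
#'   dispersion for presentation k of an object is
#'   \code{errSdFloor + (errSd0 - errSdFloor) * exp(-(k - 1) / errTau)} vu.
#' @param retrievalMeanS,reEncodingMeanS mean self-paced durations (s).
#' @param sdlog log-scale sd of the self-paced duration distributions.
#' @return list with nav (data.frame t, x, y, heading) and trials
#'   (data.frame with trial_index, object_id, phase windows *_start/*_end,
#'   response_x/y, correct_x/y, drop_error).
#' @export
simulateBehavior <- function(nTrials, nObjects = 8L, arenaRadius = 5000,
                             seed = 1L, errSd0 = 2400, errSdFloor = 300,
                             errTau = 2.5, retrievalMeanS = 13.415,
                             reEncodingMeanS = 7.685, sdlog = 0.25) {
  stopifnot(nTrials >= 1L, nObjects >= 2L)
  set.seed(seed)
  fs <- 50
  ## fixed correct locations: ring at 0.55 r with angular jitter
  ang <- seq(0, 2 * pi, length.out = nObjects + 1L)[seq_len(nObjects)] +
    runif(nObjects, -0.15, 0.15)
  rad <- arenaRadius * runif(nObjects, 0.45, 0.68)
  objXy <- cbind(rad * cos(ang), rad * sin(ang))

  snap <- function(d) max(1L, round(d * fs)) / fs
  rlnormMean <- function(m) rlnorm(1, log(m) - sdlog^2 / 2, sdlog)

  clipArena <- function(p) {
    r <- sqrt(sum(p^2))
    if (r > 0.985 * arenaRadius) p * (0.985 * arenaRadius / r) else p
  }
  ## constant-speed polyline from -> waypoint -> to, sampled at 50 Hz
  makePath <- function(from, to, durS) {
    n <- round(durS * fs)
    mid <- (from + to) / 2
    dirv <- to - from
    perp <- c(-dirv[2L], dirv[1L])
    nv <- sqrt(sum(perp^2))
    if (nv < 1e-9) perp <- c(1, 0) else perp <- perp / nv
    w <- clipArena(mid + perp * runif(1, -0.25, 0.25) *
                     max(sqrt(sum(dirv^2)), 500))
    l1 <- sqrt(sum((w - from)^2)); l2 <- sqrt(sum((to - w)^2))
    stot <- l1 + l2
    s <- seq_len(n) / n * stot
    xy <- matrix(0, n, 2L)
    seg1 <- s <= l1
    if (l1 > 0) {
      f <- s[seg1] / l1
      xy[seg1, ] <- cbind(from[1L] + f * (w[1L] - from[1L]),
                          from[2L] + f * (w[2L] - from[2L]))
    }
    if (l2 > 0) {
      f <- (s[!seg1] - l1) / l2
      xy[!seg1, ] <- cbind(w[1L] + f * (to[1L] - w[1L]),
                           w[2L] + f * (to[2L] - w[2L]))
    } else xy[!seg1, ] <- matrix(rep(to, sum(!seg1)), ncol = 2L,
                                 byrow = TRUE)
    xy
  }

  presCount <- integer(nObjects)
  ## cue order: shuffled blocks over objects
  order0 <- unlist(lapply(seq_len(ceiling(nTrials / nObjects)),
                          function(b) sample.int(nObjects)))
  cueObj <- order0[seq_len(nTrials)] - 1L   # 0-based object ids

  pos <- c(0, 0); headingCur <- 0
  navX <- navY <- navH <- list()
  rows <- vector("list", nTrials)
  tCur <- 0; iSeg <- 0L

  addStill <- function(durS) {
    n <- round(durS * fs)
    iSeg <<- iSeg + 1L
    navX[[iSeg]] <<- rep(pos[1L], n); navY[[iSeg]] <<- rep(pos[2L], n)
    navH[[iSeg]] <<- rep(headingCur, n)
    tCur <<- tCur + durS
  }
  addPath <- function(to, durS) {
    xy <- makePath(pos, to, durS)
    h <- atan2(diff(c(pos[2L], xy[, 2L])), diff(c(pos[1L], xy[, 1L]))) *
      180 / pi
    h[!is.finite(h)] <- headingCur
    iSeg <<- iSeg + 1L
    navX[[iSeg]] <<- xy[, 1L]; navY[[iSeg]] <<- xy[, 2L]
    navH[[iSeg]] <<- h
    pos <<- xy[nrow(xy), ]; headingCur <<- h[length(h)]
    tCur <<- tCur + durS
  }

  for (k in seq_len(nTrials)) {
    obj <- cueObj[k] + 1L
    presCount[obj] <- presCount[obj] + 1L
    sdk <- errSdFloor + (errSd0 - errSdFloor) *
      exp(-(presCount[obj] - 1L) / errTau)
    resp <- clipArena(objXy[obj, ] + rnorm(2L, 0, sdk))

    itiDur <- snap(runif(1, 3, 5))
    itiStart <- tCur; addStill(itiDur)
    cueStart <- tCur; addStill(2)
    retStart <- tCur
    addPath(resp, snap(max(4, rlnormMean(retrievalMeanS))))
    retEnd <- tCur
    addStill(1.5)
    reStart <- tCur
    addPath(objXy[obj, ], snap(max(2, rlnormMean(reEncodingMeanS))))
    reEnd <- tCur

    rows[[k]] <- data.frame(
      trial_index = k, object_id = cueObj[k],
      iti_start = itiStart, iti_end = cueStart,
      cue_start = cueStart, cue_end = retStart,
      retrieval_start = retStart, retrieval_end = retEnd,
      feedback_start = retEnd, feedback_end = reStart,
      re_encoding_start = reStart, re_encoding_end = reEnd,
      response_x = resp[1L], response_y = resp[2L],
      correct_x = objXy[obj, 1L], correct_y = objXy[obj, 2L])
  }
  trials <- do.call(rbind, rows)
  trials$drop_error <- sqrt((trials$response_x - trials$correct_x)^2 +
                            (trials$response_y - trials$correct_y)^2)
  x <- unlist(navX); y <- unlist(navY); h <- unlist(navH)
  nav <- data.frame(t = (seq_along(x) - 1L) / fs, x = x, y = y, heading = h)
  list(nav = nav, trials = trials,
       objects = data.frame(object_id = seq_len(nObjects) - 1L,
                            x = objXy[, 1L], y = objXy[, 2L]))
}

#' Sample ripple times, optionally coupled to a delta phase
#'
#' Candidate times are drawn uniformly over the session (respecting an edge
#' margin) and, when a coupling phase is requested, snapped to the nearest
#' time at which a delta oscillation \code{cos(2 pi fDelta t)} attains that
#' Hilbert phase, plus Gaussian phase jitter. Times closer than
#' \code{minGap} are thinned.
#'
#' @param durationS session duration (s).
#' @param n requested number of events.
#' @param couplingPhaseDeg target delta phase in degrees, or NULL for
#'   uniform timing.
#' @param phaseJitterDeg sd of the phase jitter (degrees).
#' @param fDelta delta frequency (Hz, default 1).
#' @param minGap minimum separation between events (s).
#' @param marginS margin kept free at both session edges (s).
#' @param seed integer seed.
#' @return sorted numeric vector of event times (may be shorter than n when
#'   the gap constraint bites).
#' @export
sampleRippleTimes <- function(durationS, n, couplingPhaseDeg = NULL,
                              phaseJitterDeg = 10, fDelta = 1,
                              minGap = 0.5, marginS = 2, seed = 1L) {
  set.seed(seed)
  t <- sort(runif(3L * n, marginS, durationS - marginS))
  if (!is.null(couplingPhaseDeg)) {
    phi <- couplingPhaseDeg * pi / 180
    per <- 1 / fDelta
    base <- phi / (2 * pi) * per
    k <- round((t - base) / per)
    t <- base + k * per + rnorm(length(t), 0, phaseJitterDeg / 360 * per)
  }
  t <- sort(t[t > marginS & t < durationS - marginS])
  keep <- c(TRUE, diff(t) >= minGap)
  while (!all(keep)) { t <- t[keep]; keep <- c(TRUE, diff(t) >= minGap) }
  if (length(t) > n) t <- sort(sample(t, n))
  t
}

#' Simulate a multichannel LFP with injected ripples and IEDs
#'
#' Each channel is 1/f background noise (spectral power slope -1) plus a
#' delta oscillation \code{deltaAmp * cos(2 pi fDelta t)} plus
#' Gaussian-windowed 80-140 Hz ripple bursts at the requested times plus
#' sharp biphasic IED-like transients. Burst amplitudes are calibrated
#' against the channel's own smoothed ripple-band envelope so that the
#' burst peak sits at approximately \code{rippleAmpSd} envelope standard
#' deviations above the envelope mean. Because ripple times generated by
#' \code{\link{sampleRippleTimes}} lie at a fixed phase of the
#' deterministic delta oscillation, the injected bursts are delta
#' phase-coupled.
#'
#' @param durationS session duration (s).
#' @param rippleTimes list (per channel) of burst centre times (s).
#' @param iedTimes list (per channel) of IED times (s); default none.
#' @param fs sampling rate (default 2000 Hz).
#' @param channels,regions channel and region labels.
#' @param rippleFreq burst carrier frequency (Hz, default 100).
#' @param rippleAmpSd burst peak height in envelope SD units (default 5).
#' @param burstSigmaS Gaussian envelope sd of the burst (s, default 0.02).
#' @param deltaAmp delta amplitude in background-SD units (default 2).
#' @param fDelta delta frequency (Hz, default 1).
#' @param iedAmp IED amplitude in background-IQR units (default 10).
#' @param seed integer seed.
#' @return an \linkS4class{LfpRecording}.
#' @export
simulateLfp <- function(durationS, rippleTimes, iedTimes = NULL, fs = 2000,
                        channels = NULL, regions = NULL, rippleFreq = 100,
                        rippleAmpSd = 5, burstSigmaS = 0.02, deltaAmp = 2,
                        fDelta = 1, iedAmp = 10, seed = 1L) {
  if (!is.list(rippleTimes)) rippleTimes <- list(rippleTimes)
  nCh <- length(rippleTimes)
  if (is.null(iedTimes)) iedTimes <- rep(list(numeric(0)), nCh)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nCh))
  if (is.null(regions)) regions <- rep("HC", nCh)
  n <- round(durationS * fs)
  tAx <- (seq_len(n) - 1L) / fs
  set.seed(seed)
  bp <- signal::butter(4, c(80, 140) / (fs / 2), type = "pass")
  dat <- matrix(0, nCh, n)
  for (c in seq_len(nCh)) {
    ev <- sort(c(rippleTimes[[c]], iedTimes[[c]]))
    if (length(ev) > 1L && min(diff(ev)) < 0.5)
      stop("injected events closer than 0.5 s on one channel; reject configuration")
    ## 1/f background via spectral shaping of white noise
    wn <- rnorm(n)
    W <- fft(wn)
    f <- c(0, seq_len(n - 1L)) * fs / n
    f <- pmin(f, fs - f)
    g <- 1 / sqrt(pmax(f, 0.5))
    x <- Re(fft(W * g, inverse = TRUE) / n)
    x <- x / sd(x)
    x <- x + deltaAmp * cos(2 * pi * fDelta * tAx)
    ## calibrate burst amplitude on this channel's smoothed envelope
    env <- Mod(hilbertAnalytic(filtfiltPad(bp, x, fs)))
    env <- movingAverage(env, max(3L, round(0.02 * fs)))
    ampl <- mean(env) + rippleAmpSd * sd(env)
    half <- round(4 * burstSigmaS * fs)
    bt <- (-half:half) / fs
    burst <- ampl * exp(-bt^2 / (2 * burstSigmaS^2)) *
      cos(2 * pi * rippleFreq * bt)
    for (t0 in rippleTimes[[c]]) {
      i0 <- round(t0 * fs) + 1L
      idx <- (i0 - half):(i0 + half)
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + burst[ok]
    }
    if (length(iedTimes[[c]])) {
      sg <- 0.015
      ihalf <- round(4 * sg * fs)
      it <- (-ihalf:ihalf) / fs
      iedShape <- (it / sg) * exp(-it^2 / (2 * sg^2))
      iedShape <- iedShape / max(abs(iedShape))
      iAmp <- iedAmp * stats::IQR(x)
      for (t0 in iedTimes[[c]]) {
        i0 <- round(t0 * fs) + 1L
        idx <- (i0 - ihalf):(i0 + ihalf)
        ok <- idx >= 1L & idx <= n
        x[idx[ok]] <- x[idx[ok]] + iAmp * iedShape[ok]
      }
    }
    dat[c, ] <- x
  }
  LfpRecording(dat, fs, channels, regions, referenceScheme = "bipolar")
}

#' Simulate spike trains with object, place and ripple-locked tuning
#'
#' Units fire as inhomogeneous Poisson processes on a 20 ms rate grid.
#' Object-tuned units multiply their baseline rate by a gain during cue
#' periods of their preferred object; place-tuned units by a 2D Gaussian of
#' the participant's position. Coactive pairs additionally receive joint
#' spikes around selected ripple peaks: with probability
#' \code{min(0.9, jointP * gain)} per ripple, unit A spikes near the peak
#' and unit B at the pair's lag. A gain of 0 or 1 injects nothing
#' (independent pair). Rates that fall below zero are clipped at zero.
#'
#' @param nav navigation trace (50 Hz).
#' @param trials trial table.
#' @param units list of per-unit tuning descriptions: list(baseRate,
#'   preferredObject = id or NA, objectGain, placeCenter = c(x, y) or NULL,
#'   fieldWidth (vu), placeGain, region).
#' @param durationS session duration (s).
#' @param coactivePairs optional data.frame(unit_a, unit_b, gain, lag_s).
#' @param ripplePeaks ripple peak times used for coactive injection.
#' @param jointP baseline joint-activation probability per ripple.
#' @param seed integer seed.
#' @return list of \linkS4class{SpikeTrain} objects.
#' @export
simulateSpikes <- function(nav, trials, units, durationS,
                           coactivePairs = NULL, ripplePeaks = numeric(0),
                           jointP = 0.15, seed = 1L) {
  set.seed(seed)
  binW <- 0.02
  nb <- floor(durationS / binW)
  tb <- (seq_len(nb) - 0.5) * binW
  navIdx <- pmin(nrow(nav), pmax(1L, round(tb * 50) + 1L))
  bx <- nav$x[navIdx]; by <- nav$y[navIdx]
  cueObjAt <- rep(NA_integer_, nb)
  for (k in seq_len(nrow(trials))) {
    sel <- tb >= trials$cue_start[k] & tb < trials$cue_end[k]
    cueObjAt[sel] <- trials$object_id[k]
  }
  out <- vector("list", length(units))
  for (u in seq_along(units)) {
    spec <- units[[u]]
    rate <- rep(spec$baseRate, nb)
    if (!is.null(spec$preferredObject) && !is.na(spec$preferredObject) &&
        !is.null(spec$objectGain)) {
      sel <- !is.na(cueObjAt) & cueObjAt == spec$preferredObject
      rate[sel] <- rate[sel] * spec$objectGain
    }
    if (!is.null(spec$placeCenter)) {
      d2 <- (bx - spec$placeCenter[1L])^2 + (by - spec$placeCenter[2L])^2
      rate <- rate * (1 + (spec$placeGain - 1) *
                        exp(-d2 / (2 * spec$fieldWidth^2)))
    }
    rate <- pmax(rate, 0)
    cnt <- rpois(nb, rate * binW)
    tot <- sum(cnt)
    st <- rep((seq_len(nb) - 1L) * binW, cnt) + runif(tot, 0, binW)
    out[[u]] <- sort(st)
  }
  if (!is.null(coactivePairs) && nrow(coactivePairs) &&
      length(ripplePeaks)) {
    for (r in seq_len(nrow(coactivePairs))) {
      g <- coactivePairs$gain[r]
      if (g <= 1) next
      p <- min(0.9, jointP * g)
      hit <- runif(length(ripplePeaks)) < p
      ta <- ripplePeaks[hit] + rnorm(sum(hit), 0, 0.012)
      tbv <- ta + coactivePairs$lag_s[r] + rnorm(sum(hit), 0, 0.012)
      a <- coactivePairs$unit_a[r]; b <- coactivePairs$unit_b[r]
      out[[a]] <- sort(c(out[[a]], ta[ta > 0 & ta < durationS]))
      out[[b]] <- sort(c(out[[b]], tbv[tbv > 0 & tbv < durationS]))
    }
  }
  lapply(seq_along(units), function(u)
    SpikeTrain(out[[u]], unitId = sprintf("unit%03d", u),
               region = if (is.null(units[[u]]$region)) "HC" else
                 units[[u]]$region))
}

#' Simulate a complete session bundle
#'
#' Convenience wrapper that chains \code{\link{simulateBehavior}},
#' \code{\link{sampleRippleTimes}}, \code{\link{simulateLfp}} and
#' \code{\link{simulateSpikes}} and assembles a
#' \linkS4class{SessionBundle} with the full ground truth recorded in its
#' truth slot. All randomness derives from the single seed.
#'
#' @param nTrials number of trials.
#' @param nObjects number of objects.
#' @param units unit tuning list (see \code{\link{simulateSpikes}}); NULL
#'   for no units.
#' @param nRipples ripples to inject on the hippocampal channel.
#' @param nIeds IED-like transients to inject.
#' @param couplingPhaseDeg delta phase of the injected ripples (degrees).
#' @param coactivePairs optional coactive-pair table.
#' @param withLfp set FALSE to skip LFP synthesis (behaviour/spikes only).
#' @param seed integer seed.
#' @param ... passed on to \code{\link{simulateLfp}}.
#' @return a \linkS4class{SessionBundle}.
#' @export
simulateSession <- function(nTrials = 20L, nObjects = 8L, units = NULL,
                            nRipples = 60L, nIeds = 0L,
                            couplingPhaseDeg = 30, coactivePairs = NULL,
                            withLfp = TRUE, seed = 1L, ...) {
  beh <- simulateBehavior(nTrials, nObjects, seed = seed)
  durationS <- ceiling(max(beh$nav$t) + 1)
  ripT <- sampleRippleTimes(durationS, nRipples,
                            couplingPhaseDeg = couplingPhaseDeg,
                            seed = seed + 1L)
  iedT <- if (nIeds > 0L)
    sampleRippleTimes(durationS, nIeds, couplingPhaseDeg = NULL,
                      minGap = 3, seed = seed + 2L) else numeric(0)
  ## keep injected ripples clear of IED exclusion zones
  if (length(iedT))
    ripT <- ripT[vapply(ripT, function(t0)
      all(abs(t0 - iedT) > 1.6), logical(1))]
  lfp <- NULL
  if (withLfp)
    lfp <- simulateLfp(durationS, rippleTimes = list(ripT),
                       iedTimes = list(iedT), seed = seed + 3L, ...)
  spikes <- list()
  if (!is.null(units))
    spikes <- simulateSpikes(beh$nav, beh$trials, units, durationS,
                             coactivePairs = coactivePairs,
                             ripplePeaks = ripT, seed = seed + 4L)
  truth <- list(rippleTimes = list(ripT), iedTimes = list(iedT),
                couplingPhaseDeg = couplingPhaseDeg, units = units,
                coactivePairs = coactivePairs, objects = beh$objects,
                seed = seed)
  dur <- if (withLfp) ncol(lfpData(lfp)) / samplingRate(lfp) else durationS
  new("SessionBundle", lfp = lfp, spikes = spikes, nav = beh$nav,
      trials = beh$trials, truth = truth, duration = dur)
}

#' Write / read a session bundle as plain-text files
#'
#' Sessions serialize to a directory of CSV files (LFP matrix, navigation
#' trace, trial table, spike times) plus a JSON sidecar holding sampling
#' metadata and the ground truth.
#'
#' @param bundle a \linkS4class{SessionBundle}.
#' @param dir target directory (created if needed).
#' @return \code{writeSession} returns dir invisibly; \code{readSession}
#'   returns the reconstructed \linkS4class{SessionBundle}.
#' @export
writeSession <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle@nav, file.path(dir, "nav.csv"), row.names = FALSE)
  write.csv(bundle@trials, file.path(dir, "trials.csv"), row.names = FALSE)
  if (length(bundle@spikes)) {
    sp <- do.call(rbind, lapply(bundle@spikes, function(s)
      data.frame(unit = s@unitId, region = s@region, time = s@times)))
    write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  }
  meta <- list(duration = bundle@duration, truth = bundle@truth)
  if (!is.null(bundle@lfp)) {
    lf <- bundle@lfp
    write.csv(as.data.frame(t(lfpData(lf))), file.path(dir, "lfp.csv"),
              row.names = FALSE)
    meta$fs <- samplingRate(lf)
    meta$channels <- channelLabels(lf)
    meta$regions <- channelRegions(lf)
    meta$referenceScheme <- referenceScheme(lf)
  }
  write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
             digits = NA, null = "null")
  invisible(dir)
}

#' @rdname writeSession
#' @export
readSession <- function(dir) {
  meta <- read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  nav <- read.csv(file.path(dir, "nav.csv"))
  trials <- read.csv(file.path(dir, "trials.csv"))
  spikes <- list()
  spPath <- file.path(dir, "spikes.csv")
  if (file.exists(spPath)) {
    sp <- read.csv(spPath)
    spikes <- lapply(split(sp, sp$unit), function(d)
      SpikeTrain(sort(d$time), unitId = d$unit[1L], region = d$region[1L]))
    spikes <- spikes[order(names(spikes))]
    names(spikes) <- NULL
  }
  lfp <- NULL
  lfPath <- file.path(dir, "lfp.csv")
  if (file.exists(lfPath)) {
    m <- t(as.matrix(read.csv(lfPath)))
    dimnames(m) <- NULL
    lfp <- LfpRecording(m, meta$fs, meta$channels, meta$regions,
                        meta$referenceScheme)
  }
  truth <- if (is.null(meta$truth)) list() else meta$truth
  new("SessionBundle", lfp = lfp, spikes = spikes, nav = nav,
      trials = trials, truth = truth, duration = meta$duration)
}
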