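## Ripple detection: 80-140 Hz band-pass -> Hilbert envelope -> 20 ms
## smoothing -> candidate runs above mean + 2 SD -> acceptance criteria
## (3 SD peak, 20-500 ms duration, >= 3 peaks and troughs, spectral global
## peak in 80-140 Hz relative to the whole-recording spectrum).

rippleBandpass <- function(x, fs, band = c(80, 140)) {
  flt <- signal::butter(4, band / (fs / 2), type = "pass")
  filtfiltPad(flt, x, fs)
}

## Smoothed analytic amplitude of the ripple band (centred 20 ms moving
## average; the smoother shape is a documented choice).
rippleEnvelope <- function(x, fs, band = c(80, 140), smoothS = 0.02) {
  bp <- rippleBandpass(x, fs, band)
  env <- Mod(hilbertAnalytic(bp))
  movingAverage(env, max(1L, round(smoothS * fs)))
}

#' Detect hippocampal ripples on one channel
#'
#' Implements the full envelope-based detector. Masked (artifactual)
#' samples are set invalid in the smoothed envelope before the mean/SD
#' statistics are computed, cannot seed candidates, and break candidate
#' runs. A candidate is the maximal run of samples with envelope above
#' mean + 2 SD; it is kept as a putatively physiological ripple iff
#' (1) its envelope peak exceeds mean + 3 SD, (2) its duration lies in
#' (0.02, 0.5) s, (3) the band-pass trace inside the event has at least
#' three strict local maxima and three strict local minima, and (4) the
#' event's power spectrum (30-190 Hz in steps of 2 Hz, Morlet wavelets
#' with 7 cycles, divided by the whole-recording mean power per frequency)
#' has its global maximum between 80 and 140 Hz. The peak time is the time
#' of the band-pass maximum; ripple frequency is 1 / (2 x mean adjacent
#' peak-trough delay).
#'
#' @param x single-channel LFP (bipolar, line-noise removed).
#' @param fs sampling rate (Hz).
#' @param mask optional logical vector, TRUE = excluded sample.
#' @param band ripple band (Hz).
#' @param channel channel label stored in the output.
#' @return data.frame of ripple events: channel, t_start, t_peak, t_end,
#'   duration, frequency, envelope_peak_sd.
#' @export
detectRipples <- function(x, fs, mask = NULL, band = c(80, 140),
                          channel = "ch1") {
  n <- length(x)
  if (is.null(mask)) mask <- logical(n)
  if (sum(!mask) < 10 * fs)
    stop("fewer than 10 s of valid data: envelope statistics unstable")
  bp <- rippleBandpass(x, fs, band)
  env <- rippleEnvelope(x, fs, band)
  env[mask] <- NA_real_
  mu <- mean(env, na.rm = TRUE); sdv <- sd(env, na.rm = TRUE)
  empty <- data.frame(channel = character(0), t_start = numeric(0),
                      t_peak = numeric(0), t_end = numeric(0),
                      duration = numeric(0), frequency = numeric(0),
                      envelope_peak_sd = numeric(0))
  if (!is.finite(sdv) || sdv == 0) return(empty)
  cand <- runsFromLogical(!is.na(env) & env > mu + 2 * sdv)
  if (!nrow(cand)) return(empty)

  relPow <- NULL; sfreqs <- NULL
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    idx <- cand$start[i]:cand$end[i]
    dur <- (length(idx) - 1L) / fs
    if (dur <= 0.02 || dur >= 0.5) next
    if (max(env[idx]) <= mu + 3 * sdv) next
    ext <- localExtrema(bp[idx])
    if (length(ext$peaks) < 3L || length(ext$troughs) < 3L) next
    ## lazy whole-recording spectrum: computed once, only if needed
    if (is.null(relPow)) {
      sfreqs <- seq(30, 190, by = 2)
      pw <- morletPower(x, fs, sfreqs)
      meanPow <- rowMeans(pw, na.rm = TRUE)
      relPow <- pw / meanPow
    }
    evSpec <- rowMeans(relPow[, idx, drop = FALSE], na.rm = TRUE)
    if (all(is.na(evSpec))) next
    fPeak <- sfreqs[which.max(evSpec)]
    if (fPeak < band[1L] || fPeak > band[2L]) next
    props <- rippleProperties(bp[idx], fs)
    tPeak <- (idx[which.max(bp[idx])] - 1L) / fs
    rows[[i]] <- data.frame(
      channel = channel,
      t_start = (idx[1L] - 1L) / fs, t_peak = tPeak,
      t_end = (idx[length(idx)] - 1L) / fs, duration = dur,
      frequency = props$frequency,
      envelope_peak_sd = (max(env[idx]) - mu) / sdv)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## strict local extrema of a series
localExtrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(list(peaks = integer(0), troughs = integer(0)))
  mid <- 2:(n - 1L)
  list(peaks = mid[v[mid] > v[mid - 1L] & v[mid] > v[mid + 1L]],
       troughs = mid[v[mid] < v[mid - 1L] & v[mid] < v[mid + 1L]])
}

#' Duration and frequency of a ripple from its band-pass segment
#'
#' Frequency is estimated as the reciprocal of twice the average temporal
#' delay between adjacent peaks and troughs of the band-pass signal.
#'
#' @param bpSegment band-pass signal inside the event.
#' @param fs sampling rate (Hz).
#' @return list with duration (s) and frequency (Hz).
#' @export
rippleProperties <- function(bpSegment, fs) {
  ext <- localExtrema(bpSegment)
  pts <- sort(c(ext$peaks, ext$troughs))
  freq <- if (length(pts) >= 2L)
    1 / (2 * mean(diff(pts)) / fs) else NA_real_
  list(duration = (length(bpSegment) - 1L) / fs, frequency = freq)
}

#' Surrogate ripple peak times
#'
#' For each ripple, draws one surrogate peak uniformly over the valid
#' (unmasked, in-session) samples within +-60 s of the true peak. When a
#' window holds no valid sample, the draw widens to the whole valid
#' session with a warning.
#'
#' @param peaks ripple peak times (s).
#' @param nSamples session length in samples.
#' @param fs sampling rate (Hz).
#' @param mask optional logical exclusion vector.
#' @param windowS half width of the surrogate window (s, default 60).
#' @param seed integer seed.
#' @return numeric vector of surrogate peak times, one per ripple.
#' @export
makeSurrogateRipples <- function(peaks, nSamples, fs, mask = NULL,
                                 windowS = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mask)) mask <- logical(nSamples)
  validIdx <- which(!mask)
  if (!length(validIdx)) stop("no valid samples")
  vapply(peaks, function(tp) {
    i0 <- round(tp * fs) + 1L
    lo <- max(1L, i0 - round(windowS * fs))
    hi <- min(nSamples, i0 + round(windowS * fs))
    pool <- validIdx[validIdx >= lo & validIdx <= hi]
    if (!length(pool)) {
      warning("no valid sample in surrogate window; using whole session")
      pool <- validIdx
    }
    (pool[sample.int(length(pool), 1L)] - 1L) / fs
  }, numeric(1))
}

#' Ripple rates per trial phase, behaviour correlations and PSTHs
#'
#' For each trial and phase (ITI, cue, retrieval, feedback, re-encoding)
#' the ripple rate is the number of ripple peaks in the phase window
#' divided by its duration. Across trials, partial correlations relate the
#' phase-wise rates to memory performance (controlling for trial index and
#' the interaction) and to trial index (controlling for performance and
#' the interaction), Bonferroni-corrected over the five phases.
#' Time-resolved rates are locked to the phase onset for cue and feedback
#' and to the phase offset for ITI, retrieval and re-encoding (window -3
#' to +1 s around offsets, -1 to +3 s around onsets); trials are split by
#' a median split of performance into good and bad and contrasted with a
#' two-sided cluster-based permutation test.
#'
#' @param ripples ripple event data.frame from \code{\link{detectRipples}}.
#' @param trials trial table with a performance column.
#' @param binS PSTH bin width (s, default 0.1).
#' @param nSurrogates surrogates for the good/bad cluster test.
#' @param seed integer seed for the cluster tests.
#' @return list with rates (trials x phases matrix), correlations
#'   (data.frame), psth (per phase: time axis, trials x bins matrix, good
#'   logical, clusterResult).
#' @export
rippleRatesByPhase <- function(ripples, trials, binS = 0.1,
                               nSurrogates = 1001L, seed = 1L) {
  phases <- c("iti", "cue", "retrieval", "feedback", "re_encoding")
  n <- nrow(trials)
  pk <- ripples$t_peak
  rates <- sapply(phases, function(ph) {
    s <- trials[[paste0(ph, "_start")]]; e <- trials[[paste0(ph, "_end")]]
    vapply(seq_len(n), function(k)
      sum(pk >= s[k] & pk < e[k]) / (e[k] - s[k]), numeric(1))
  })
  perf <- trials$performance
  idx <- trials$trial_index
  inter <- perf * idx
  correlations <- do.call(rbind, lapply(seq_along(phases), function(j) {
    r1 <- partialCor(rates[, j], perf, cbind(idx, inter))
    r2 <- partialCor(rates[, j], idx, cbind(perf, inter))
    corP <- function(r) {
      if (is.na(r) || n < 5L) return(NA_real_)
      df <- n - 4L
      tv <- r * sqrt(df / (1 - r^2))
      min(1, 2 * pt(-abs(tv), df) * length(phases))
    }
    data.frame(phase = phases[j], rPerformance = r1,
               pPerformance = corP(r1), rTrialIndex = r2,
               pTrialIndex = corP(r2))
  }))
  good <- perf > median(perf)
  psth <- lapply(phases, function(ph) {
    onsetLocked <- ph %in% c("cue", "feedback")
    ref <- if (onsetLocked) trials[[paste0(ph, "_start")]] else
      trials[[paste0(ph, "_end")]]
    win <- if (onsetLocked) c(-1, 3) else c(-3, 1)
    edges <- seq(win[1L], win[2L], by = binS)
    ctrs <- edges[-length(edges)] + binS / 2
    counts <- t(vapply(seq_len(n), function(k) {
      rel <- pk - ref[k]
      rel <- rel[rel >= win[1L] & rel < win[2L]]
      tabulate(findInterval(rel, edges), nbins = length(ctrs)) / binS
    }, numeric(length(ctrs))))
    clu <- NULL
    if (sum(good) >= 5L && sum(!good) >= 5L)
      clu <- clusterTest(counts[good, , drop = FALSE],
                         counts[!good, , drop = FALSE],
                         test = "two_sample", alternative = "two_sided",
                         scheme = "label_reassign",
                         nSurrogates = nSurrogates, seed = seed)
    list(phase = ph, time = ctrs, rate = counts, good = good,
         cluster = clu)
  })
  names(psth) <- phases
  list(rates = rates, correlations = correlations, psth = psth)
}
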