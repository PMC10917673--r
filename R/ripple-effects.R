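#' Delta phase locking of ripples
#'
#' The channel is filtered into the delta band (0.5-2 Hz) with a two-pass
#' FIR filter of order 8000, phases are taken from the Hilbert transform
#' at the ripple peak times, and their circular mean and Rayleigh
#' statistics are computed. Significance of the phase concentration is
#' assessed against surrogate ripples obtained by randomly shuffling the
#' inter-ripple intervals (keeping the first peak): the empirical p value
#' is \code{1 - rank}, the fraction of surrogate Rayleigh z values
#' smaller than the empirical one, over \code{nSurrogates} rounds; a
#' two-sample Kuiper test compares the empirical phases with the pooled
#' surrogate phases.
#'
#' @param x single-channel LFP.
#' @param peaks ripple peak times (s), at least 10.
#' @param fs sampling rate (Hz).
#' @param band delta band (Hz, default c(0.5, 2)).
#' @param filterOrder FIR order (default 8000).
#' @param nSurrogates surrogate rounds (default 1001).
#' @param seed integer seed.
#' @return list with phases (radians per ripple), meanPhaseDeg, rayleighZ,
#'   rayleighP (analytic), surrogateZ, pEmpirical (1 - rank), kuiper.
#' @export
deltaPhaseLocking <- function(x, peaks, fs, band = c(0.5, 2),
                              filterOrder = 8000, nSurrogates = 1001L,
                              seed = 1L) {
  stopifnot(length(peaks) >= 1L)
  if (length(x) <= filterOrder)
    stop("session shorter than the delta filter transient")
  if (length(peaks) < 10L)
    warning("fewer than 10 ripples: phase-locking statistics unstable")
  xf <- firBandpass(x, fs, band[1L], band[2L], order = filterOrder)
  phase <- Arg(hilbertAnalytic(xf))
  atTime <- function(tt) {
    i <- pmin(length(phase), pmax(1L, round(tt * fs) + 1L))
    phase[i]
  }
  ph <- atTime(peaks)
  ray <- if (length(ph) >= 3L) rayleighTest(ph) else
    list(z = NA_real_, p = NA_real_)
  set.seed(seed)
  dur <- length(x) / fs
  peaks <- sort(peaks)
  iri <- diff(peaks)
  surZ <- rep(NA_real_, nSurrogates)
  surPh <- vector("list", nSurrogates)
  if (length(peaks) >= 3L) {
    for (i in seq_len(nSurrogates)) {
      sp <- peaks[1L] + cumsum(c(0, sample(iri)))
      sp <- sp[sp < dur]
      phs <- atTime(sp)
      surPh[[i]] <- phs
      surZ[i] <- rayleighTest(phs)$z
    }
  }
  pEmp <- if (all(is.na(surZ))) NA_real_ else
    1 - mean(surZ < ray$z, na.rm = TRUE)
  ku <- if (length(ph) >= 3L && length(surPh) && length(surPh[[1L]]) >= 3L)
    kuiperTwoSample(ph, unlist(surPh)) else NULL
  list(phases = ph,
       meanPhaseDeg = circMean(ph) * 180 / pi,
       rayleighZ = ray$z, rayleighP = ray$p, surrogateZ = surZ,
       pEmpirical = pEmp, kuiper = ku)
}

#' Cross-correlation between hippocampal and extra-hippocampal ripples
#'
#' Both event lists are expanded into binary sample trains (1 during the
#' ripple extents). The unbiased cross-correlation (raw lag sums divided
#' by n - |lag|) is computed for lags up to +-5 s, smoothed with a 0.2 s
#' Gaussian kernel and z-scored across lags. Positive lags mean the other
#' region's ripples follow the hippocampal ripples.
#'
#' @param ripplesHc,ripplesOther ripple event data.frames (t_start,
#'   t_end), hippocampal reference first.
#' @param durationS session duration (s).
#' @param fs train sampling rate (Hz, default 500; results are
#'   insensitive to this resolution).
#' @param maxLagS maximum lag (s, default 5).
#' @param smoothS Gaussian kernel length (s, default 0.2).
#' @return list with lag (s) and z (z-scored smoothed cross-correlation).
#' @export
rippleCrossCorrelation <- function(ripplesHc, ripplesOther, durationS,
                                   fs = 500, maxLagS = 5, smoothS = 0.2) {
  n <- round(durationS * fs)
  train <- function(ev) {
    v <- numeric(n)
    for (i in seq_len(nrow(ev))) {
      a <- max(1L, round(ev$t_start[i] * fs) + 1L)
      b <- min(n, round(ev$t_end[i] * fs) + 1L)
      v[a:b] <- 1
    }
    v
  }
  xh <- train(ripplesHc); xo <- train(ripplesOther)
  L <- nextFastLen(2L * n)
  X <- fft(c(xh, rep(0, L - n)))
  Y <- fft(c(xo, rep(0, L - n)))
  cc <- Re(fft(Conj(X) * Y, inverse = TRUE)) / L
  maxLag <- round(maxLagS * fs)
  lags <- -maxLag:maxLag
  raw <- cc[ifelse(lags >= 0, lags + 1L, L + lags + 1L)]
  unb <- raw / (n - abs(lags))
  k <- gaussKernel(smoothS, fs)
  sm <- fftConvSame(unb, k)
  list(lag = lags / fs, z = zscoreVec(sm))
}

#' Ripple-locked LFP power
#'
#' Computes the whole-recording Morlet spectrogram (7 cycles, 50
#' log-spaced frequencies 1-200 Hz), sets masked samples invalid,
#' z-scores power per frequency across time, extracts +-3 s around each
#' ripple peak, averages across ripples, smooths across time with a 0.2 s
#' Gaussian kernel and truncates to +-0.5 s around the peak.
#'
#' @param x single-channel LFP.
#' @param peaks ripple peak times (s).
#' @param fs sampling rate (Hz).
#' @param mask optional logical exclusion vector (IED samples).
#' @param freqs frequency grid (default 50 log-spaced 1-200 Hz).
#' @param extractS extraction half window (s, default 3).
#' @param truncS output half window (s, default 0.5).
#' @param smoothS Gaussian kernel length (s, default 0.2).
#' @param decimate temporal decimation factor of the output grid (default
#'   10, i.e. 200 Hz time resolution at fs = 2000).
#' @return a \linkS4class{RippleTriggeredAverage}.
#' @export
rippleLockedPower <- function(x, peaks, fs, mask = NULL,
                              freqs = exp(seq(log(1), log(200),
                                              length.out = 50L)),
                              extractS = 3, truncS = 0.5, smoothS = 0.2,
                              decimate = 10L) {
  pw <- morletPower(x, fs, freqs)
  if (!is.null(mask)) pw[, mask] <- NA_real_
  z <- t(apply(log(pmax(pw, .Machine$double.xmin)), 1L, zscoreVec))
  half <- round(extractS * fs)
  n <- ncol(z)
  acc <- matrix(0, length(freqs), 2L * half + 1L)
  cnt <- matrix(0, length(freqs), 2L * half + 1L)
  used <- 0L
  for (tp in peaks) {
    i0 <- round(tp * fs) + 1L
    if (i0 - half < 1L || i0 + half > n) next
    seg <- z[, (i0 - half):(i0 + half)]
    ok <- !is.na(seg)
    seg[!ok] <- 0
    acc <- acc + seg
    cnt <- cnt + ok
    used <- used + 1L
  }
  avg <- acc / cnt
  avg[cnt == 0] <- NA_real_
  avg <- t(apply(avg, 1L, smoothGaussian, lengthS = smoothS, fs = fs))
  tAx <- (-half:half) / fs
  keep <- abs(tAx) <= truncS
  avg <- avg[, keep, drop = FALSE]
  tAx <- tAx[keep]
  if (decimate > 1L) {
    sel <- seq(1L, length(tAx), by = decimate)
    avg <- avg[, sel, drop = FALSE]
    tAx <- tAx[sel]
  }
  new("RippleTriggeredAverage", time = tAx, freq = freqs, values = avg,
      n = used)
}

#' Ripple-locked single-unit firing rate
#'
#' Instantaneous firing rates are computed over the entire session
#' (1 ms bins), smoothed with a 0.2 s Gaussian kernel, z-scored across
#' time, and averaged in +-3 s windows around the ripple peaks.
#'
#' @param spikes a \linkS4class{SpikeTrain} or numeric spike times.
#' @param peaks ripple peak times (s).
#' @param durationS session duration (s).
#' @param binS rate resolution (s, default 0.001).
#' @param smoothS Gaussian kernel length (s, default 0.2).
#' @param winS half window (s, default 3).
#' @param decimate output decimation factor (default 10).
#' @return a \linkS4class{RippleTriggeredAverage} (1 x time values).
#' @export
rippleLockedFiring <- function(spikes, peaks, durationS, binS = 0.001,
                               smoothS = 0.2, winS = 3, decimate = 10L) {
  st <- if (is(spikes, "SpikeTrain")) spikeTimes(spikes) else spikes
  if (length(st) < 50L)
    warning("fewer than 50 spikes: z-scored rate unstable")
  fsr <- 1 / binS
  n <- floor(durationS * fsr)
  cnt <- tabulate(pmin(n, floor(st * fsr) + 1L), nbins = n) * fsr
  z <- zscoreVec(smoothGaussian(cnt, smoothS, fsr))
  half <- round(winS * fsr)
  acc <- numeric(2L * half + 1L); used <- 0L
  for (tp in peaks) {
    i0 <- round(tp * fsr) + 1L
    if (i0 - half < 1L || i0 + half > n) next
    acc <- acc + z[(i0 - half):(i0 + half)]
    used <- used + 1L
  }
  avg <- if (used) acc / used else acc * NA_real_
  tAx <- (-half:half) / fsr
  if (decimate > 1L) {
    sel <- seq(1L, length(tAx), by = decimate)
    avg <- avg[sel]; tAx <- tAx[sel]
  }
  new("RippleTriggeredAverage", time = tAx, freq = NULL,
      values = matrix(avg, nrow = 1L), n = used)
}

#' Unit recording-quality metrics
#'
#' ISI refractoriness is the percentage of inter-spike intervals shorter
#' than 3 ms; the waveform peak SNR is the absolute peak amplitude of the
#' mean waveform divided by the standard deviation of the (300-3000 Hz
#' filtered) noise trace.
#'
#' @param spikes a \linkS4class{SpikeTrain} or sorted spike times (s).
#' @param meanWaveform optional mean spike waveform (microvolts).
#' @param noiseSd optional noise standard deviation (microvolts).
#' @return list with isiShortPct and snr (NA when waveform/noise absent).
#' @export
unitQuality <- function(spikes, meanWaveform = NULL, noiseSd = NULL) {
  st <- if (is(spikes, "SpikeTrain")) spikeTimes(spikes) else spikes
  isi <- diff(st)
  isiShortPct <- if (length(isi)) 100 * mean(isi < 0.003) else NA_real_
  snr <- if (!is.null(meanWaveform) && !is.null(noiseSd) && noiseSd > 0)
    max(abs(meanWaveform)) / noiseSd else NA_real_
  list(isiShortPct = isiShortPct, snr = snr)
}
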