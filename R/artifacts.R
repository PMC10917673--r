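#' Detect interictal epileptiform discharges (IEDs) on one channel
#'
#' The channel is first high-pass filtered at 0.5 Hz (two-pass 5th-order
#' Butterworth) and low-pass filtered at 150 Hz (two-pass 6th-order). A
#' sample is flagged as belonging to an IED if any of three criteria fires:
#' (1) its amplitude deviates more than four interquartile ranges (IQR)
#' from the median amplitude; (2) the sample-to-sample gradient deviates
#' more than 4 IQR from the median gradient; (3) the sum over 1-60 Hz (30
#' log-spaced frequencies, Morlet wavelets with 7 cycles, natural-log
#' power, frequency-wise z-scored across time) exceeds the median of that
#' sum series by more than 4 IQR (one-sided, since discharges raise
#' power). Contiguous flagged samples (merge gap 50 ms) form one event.
#' IQRs replace standard deviations to resist outliers.
#'
#' @param x single-channel voltage series.
#' @param fs sampling rate (Hz).
#' @param mergeGapS maximum gap merged into one event (s, default 0.05).
#' @return list with events (data.frame start_s, end_s, peak_s) and flags
#'   (logical per sample).
#' @export
detectIeds <- function(x, fs, mergeGapS = 0.05) {
  n <- length(x)
  if (stats::IQR(x) == 0) {
    warning("constant signal: IQR = 0, no IEDs flagged")
    return(list(events = data.frame(start_s = numeric(0),
                                    end_s = numeric(0),
                                    peak_s = numeric(0)),
                flags = logical(n)))
  }
  hp <- signal::butter(5, 0.5 / (fs / 2), type = "high")
  lp <- signal::butter(6, min(150, 0.45 * fs) / (fs / 2), type = "low")
  xf <- filtfiltPad(lp, filtfiltPad(hp, x, fs), fs)

  iqrFlag <- function(v, oneSided = FALSE) {
    m <- median(v, na.rm = TRUE); q <- stats::IQR(v, na.rm = TRUE)
    if (q == 0) return(rep(FALSE, length(v)))
    if (oneSided) v > m + 4 * q else abs(v - m) > 4 * q
  }
  f1 <- iqrFlag(xf)
  grad <- c(diff(xf), 0)
  f2 <- iqrFlag(grad)
  freqs <- exp(seq(log(1), log(60), length.out = 30L))
  pw <- morletPower(xf, fs, freqs)
  lp2 <- log(pmax(pw, .Machine$double.xmin))
  zs <- t(apply(lp2, 1L, zscoreVec))
  sumPow <- colSums(zs)
  f3 <- iqrFlag(sumPow, oneSided = TRUE)
  f3[is.na(f3)] <- FALSE
  flags <- f1 | f2 | f3

  ir <- IRanges(start = which(flags), width = 1L)
  ir <- reduce(ir, min.gapwidth = max(1L, round(mergeGapS * fs)))
  flags2 <- flags
  ev <- data.frame(start_s = numeric(0), end_s = numeric(0),
                   peak_s = numeric(0))
  if (length(ir)) {
    ev <- data.frame(
      start_s = (start(ir) - 1L) / fs,
      end_s = (end(ir) - 1L) / fs,
      peak_s = vapply(seq_along(ir), function(i) {
        idx <- start(ir)[i]:end(ir)[i]
        (idx[which.max(abs(xf[idx]))] - 1L) / fs
      }, numeric(1)))
    for (i in seq_along(ir)) flags2[start(ir)[i]:end(ir)[i]] <- TRUE
  }
  list(events = ev, flags = flags2)
}

#' Detect ripple-like events in the grand-average signal
#'
#' Applies the ripple candidate-envelope procedure (80-140 Hz band-pass,
#' Hilbert envelope, 20 ms smoothing, candidate runs above mean + 2 SD with
#' a peak above mean + 3 SD) to the grand-average trace. Events detected
#' here occur on the majority of channels simultaneously and are treated as
#' artifacts, not physiological ripples, so no duration/cycle/spectrum
#' criteria are applied.
#'
#' @param ga grand-average series from \code{\link{grandAverageSignal}}.
#' @param fs sampling rate (Hz).
#' @return data.frame with start_s, end_s, peak_s (empty when none).
#' @export
detectGrandAverageEvents <- function(ga, fs) {
  env <- rippleEnvelope(ga, fs)
  mu <- mean(env); sdv <- sd(env)
  if (!is.finite(sdv) || sdv == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_s = numeric(0)))
  runs <- runsFromLogical(env > mu + 2 * sdv)
  if (!nrow(runs))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_s = numeric(0)))
  keep <- vapply(seq_len(nrow(runs)), function(i)
    max(env[runs$start[i]:runs$end[i]]) > mu + 3 * sdv, logical(1))
  runs <- runs[keep, , drop = FALSE]
  data.frame(start_s = (runs$start - 1L) / fs,
             end_s = (runs$end - 1L) / fs,
             peak_s = vapply(seq_len(nrow(runs)), function(i) {
               idx <- runs$start[i]:runs$end[i]
               (idx[which.max(env[idx])] - 1L) / fs
             }, numeric(1)))
}

#' Build the artifact exclusion mask
#'
#' The mask is the union of +-1 s dilations around each IED and the exact
#' extents of grand-average ripple-like events (which apply to every
#' channel). Overlapping intervals merge. Adding events never unmasks
#' samples.
#'
#' @param ieds named list (per channel) of IED event data.frames (columns
#'   start_s, end_s), or a single data.frame for one channel.
#' @param gaEvents data.frame of grand-average events (may be empty/NULL).
#' @param nSamples LFP sample count.
#' @param fs sampling rate (Hz).
#' @param channels channel labels (defaults to names of ieds).
#' @param dilateS half width of the IED dilation (s, default 1).
#' @return an \linkS4class{ArtifactMask}.
#' @export
buildArtifactMask <- function(ieds, gaEvents = NULL, nSamples, fs,
                              channels = NULL, dilateS = 1) {
  if (is.data.frame(ieds)) ieds <- list(ieds)
  nCh <- length(ieds)
  if (is.null(channels))
    channels <- if (!is.null(names(ieds))) names(ieds) else
      paste0("ch", seq_len(nCh))
  mask <- matrix(FALSE, nCh, nSamples)
  evRows <- list()
  toRange <- function(df, pad) {
    if (is.null(df) || !nrow(df)) return(IRanges())
    s <- pmax(1L, round(df$start_s * fs) + 1L - round(pad * fs))
    e <- pmin(nSamples, round(df$end_s * fs) + 1L + round(pad * fs))
    reduce(IRanges(start = s, end = e))
  }
  gaR <- toRange(gaEvents, 0)
  for (c in seq_len(nCh)) {
    ir <- reduce(c(toRange(ieds[[c]], dilateS), gaR))
    if (length(ir)) {
      for (i in seq_along(ir))
        mask[c, start(ir)[i]:end(ir)[i]] <- TRUE
    }
    if (!is.null(ieds[[c]]) && nrow(ieds[[c]]))
      evRows[[length(evRows) + 1L]] <- data.frame(
        channel = channels[c], start_s = ieds[[c]]$start_s,
        end_s = ieds[[c]]$end_s, source = "ied")
  }
  if (!is.null(gaEvents) && nrow(gaEvents))
    evRows[[length(evRows) + 1L]] <- data.frame(
      channel = "*", start_s = gaEvents$start_s, end_s = gaEvents$end_s,
      source = "grand_average_event")
  events <- if (length(evRows)) do.call(rbind, evRows) else
    data.frame(channel = character(0), start_s = numeric(0),
               end_s = numeric(0), source = character(0))
  new("ArtifactMask", mask = mask, events = events, fs = fs)
}

#' IED prevalence per trial phase and partial correlations with behaviour
#'
#' Computes the IED rate (events per second) in each trial phase of each
#' trial, then, per phase, the across-trial partial correlation between IED
#' prevalence and memory performance (controlling for trial index and the
#' performance x trial-index interaction) and between prevalence and trial
#' index (controlling for performance and the interaction). P values are
#' Bonferroni-corrected for the five phases. Constant prevalence yields NA.
#'
#' @param iedEvents IED event data.frame (start_s, end_s) of one channel.
#' @param trials trial table with phase windows and a performance column
#'   (>= 10 trials).
#' @return data.frame with one row per phase: rate mean, partial r and
#'   Bonferroni-corrected p for performance and trial index.
#' @export
iedBehaviorStats <- function(iedEvents, trials) {
  stopifnot(nrow(trials) >= 10L)
  phases <- c("iti", "cue", "retrieval", "feedback", "re_encoding")
  mid <- (iedEvents$start_s + iedEvents$end_s) / 2
  n <- nrow(trials)
  out <- lapply(phases, function(ph) {
    s <- trials[[paste0(ph, "_start")]]
    e <- trials[[paste0(ph, "_end")]]
    cnt <- vapply(seq_len(n), function(k)
      sum(mid >= s[k] & mid < e[k]), numeric(1))
    rate <- cnt / (e - s)
    perf <- trials$performance
    idx <- trials$trial_index
    inter <- perf * idx
    rPerf <- partialCor(rate, perf, cbind(idx, inter))
    rIdx <- partialCor(rate, idx, cbind(perf, inter))
    corP <- function(r) {
      if (is.na(r)) return(NA_real_)
      df <- n - 4L
      tv <- r * sqrt(df / (1 - r^2))
      min(1, 2 * pt(-abs(tv), df) * length(phases))
    }
    data.frame(phase = ph, meanRate = mean(rate), rPerformance = rPerf,
               pPerformance = corP(rPerf), rTrialIndex = rIdx,
               pTrialIndex = corP(rIdx))
  })
  do.call(rbind, out)
}
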