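#' Bipolar re-referencing between neighbouring contacts
#'
#' Subtracts neighbouring electrode contacts (first minus second member of
#' each pair) to reject common-mode/far-field signal and sense local field
#' potentials. Pairs default to adjacent contact indices on the same
#' electrode shaft (labels are parsed as an alphabetic shaft prefix plus a
#' contact number, e.g. "A1", "A2"), ordered inner minus outer. Members of
#' a pair must share one electrode and one region.
#'
#' @param rec an \linkS4class{LfpRecording} with common reference.
#' @param pairs optional list of c(labelA, labelB) character pairs; when
#'   NULL all neighbouring same-shaft pairs are formed.
#' @return a bipolar \linkS4class{LfpRecording} with labels "A1-A2", ...
#' @export
bipolarRereference <- function(rec, pairs = NULL) {
  stopifnot(is(rec, "LfpRecording"))
  if (referenceScheme(rec) != "common")
    stop("input must be in the common reference scheme")
  labs <- channelLabels(rec)
  if (is.null(pairs)) {
    shaft <- sub("[0-9]+$", "", labs)
    num <- suppressWarnings(as.integer(sub("^[^0-9]*", "", labs)))
    if (anyNA(num)) stop("cannot parse contact numbers from channel labels")
    pairs <- list()
    for (s in unique(shaft)) {
      idx <- which(shaft == s)
      idx <- idx[order(num[idx])]
      if (length(idx) >= 2L)
        for (i in seq_len(length(idx) - 1L))
          pairs[[length(pairs) + 1L]] <- c(labs[idx[i]], labs[idx[i + 1L]])
    }
  }
  if (!length(pairs)) stop("no neighbouring pairs available")
  dat <- lfpData(rec); regs <- channelRegions(rec)
  out <- matrix(0, length(pairs), ncol(dat))
  labsOut <- regsOut <- character(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    ia <- match(p[1L], labs); ib <- match(p[2L], labs)
    if (is.na(ia) || is.na(ib)) stop("pair member not found: ",
                                     paste(p, collapse = ", "))
    if (sub("[0-9]+$", "", p[1L]) != sub("[0-9]+$", "", p[2L]))
      stop("pair spans different electrodes: ", paste(p, collapse = "-"))
    if (regs[ia] != regs[ib])
      stop("pair spans different regions: ", paste(p, collapse = "-"))
    out[i, ] <- dat[ia, ] - dat[ib, ]
    labsOut[i] <- paste0(p[1L], "-", p[2L])
    regsOut[i] <- regs[ia]
  }
  LfpRecording(out, samplingRate(rec), labsOut, regsOut,
               referenceScheme = "bipolar")
}

#' Line-noise removal with band-stop filters
#'
#' Applies zero-phase (two-pass 4th-order Butterworth) band-stop filters at
#' 50, 100, 150 and 200 Hz (+-2 Hz) to every channel, with 1 s of
#' reflect-padding to suppress edge transients.
#'
#' @param rec an \linkS4class{LfpRecording} (fs >= 500).
#' @param centers band-stop centre frequencies (Hz).
#' @param halfWidth half width of each stop band (Hz).
#' @return the filtered \linkS4class{LfpRecording}.
#' @export
removeLineNoise <- function(rec, centers = c(50, 100, 150, 200),
                            halfWidth = 2) {
  stopifnot(is(rec, "LfpRecording"), samplingRate(rec) >= 500)
  fs <- samplingRate(rec)
  centers <- centers[centers + halfWidth < fs / 2]
  dat <- lfpData(rec)
  for (f0 in centers) {
    flt <- signal::butter(4, c(f0 - halfWidth, f0 + halfWidth) / (fs / 2),
                          type = "stop")
    for (c in seq_len(nrow(dat)))
      dat[c, ] <- filtfiltPad(flt, dat[c, ], fs)
  }
  methods::initialize(rec, data = dat)
}

#' Grand-average signal across all channels
#'
#' Sample-wise mean over all channels followed by the same four band-stop
#' line-noise filters. Ripple-like events detected in this trace mark time
#' periods in which high-frequency activity is present on the majority of
#' channels (global artifacts) and are excluded from ripple detection.
#'
#' @inheritParams removeLineNoise
#' @return numeric vector (one sample per LFP sample).
#' @export
grandAverageSignal <- function(rec, centers = c(50, 100, 150, 200),
                               halfWidth = 2) {
  stopifnot(is(rec, "LfpRecording"), nrow(lfpData(rec)) >= 2L)
  ga <- colMeans(lfpData(rec))
  fs <- samplingRate(rec)
  centers <- centers[centers + halfWidth < fs / 2]
  for (f0 in centers) {
    flt <- signal::butter(4, c(f0 - halfWidth, f0 + halfWidth) / (fs / 2),
                          type = "stop")
    ga <- filtfiltPad(flt, ga, fs)
  }
  ga
}

#' Flag channels with implausible signals
#'
#' Simple automatic surrogate for visual channel rejection: channels whose
#' variance is zero (flat line) or more than \code{madFactor} median
#' absolute deviations from the median log-variance across channels are
#' flagged. An override list forces inclusion/exclusion.
#'
#' @param rec an \linkS4class{LfpRecording}.
#' @param madFactor robust outlier threshold (default 5).
#' @param keep,drop optional character vectors of channel labels that are
#'   always kept / always dropped.
#' @return logical vector, TRUE = keep channel.
#' @export
flagBadChannels <- function(rec, madFactor = 5, keep = character(0),
                            drop = character(0)) {
  v <- apply(lfpData(rec), 1L, var)
  lv <- log(pmax(v, .Machine$double.eps))
  med <- median(lv); md <- stats::mad(lv)
  good <- v > 0 & (md == 0 | abs(lv - med) <= madFactor * md)
  good[channelLabels(rec) %in% keep] <- TRUE
  good[channelLabels(rec) %in% drop] <- FALSE
  good
}
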