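## S4 containers for the pipeline. Trial tables, navigation traces and event
## tables are ordinary data.frames with documented columns; the S4 classes
## hold the signal-level objects whose invariants are worth enforcing.

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' LfpRecording: multichannel local field potential
#'
#' Holds a channels x samples voltage matrix (microvolts) with its sampling
#' rate, channel labels, per-channel anatomical region labels (e.g. "HC",
#' "EC", "AMY", "PHC", "TP") and the referencing scheme ("common" for the
#' original recording montage, "bipolar" after neighbouring-contact
#' subtraction).
#'
#' @slot data numeric matrix, channels in rows, samples in columns.
#' @slot fs sampling rate in Hz.
#' @slot channels character vector of channel labels.
#' @slot regions character vector of region labels aligned to channels.
#' @slot referenceScheme "common" or "bipolar".
#' @exportClass LfpRecording
setClass("LfpRecording",
  representation(data = "matrix", fs = "numeric", channels = "character",
                 regions = "character", referenceScheme = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@fs) != 1L || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (nrow(object@data) != length(object@channels))
      msg <- c(msg, "one label per channel row required")
    if (length(object@regions) != length(object@channels))
      msg <- c(msg, "regions must align with channels")
    if (!object@referenceScheme %in% c("common", "bipolar"))
      msg <- c(msg, "referenceScheme must be 'common' or 'bipolar'")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an LfpRecording
#'
#' @param data channels x samples numeric matrix (a vector is treated as one
#'   channel).
#' @param fs sampling rate (Hz).
#' @param channels channel labels; defaults to "ch1", "ch2", ...
#' @param regions region labels; defaults to "HC" for every channel.
#' @param referenceScheme "common" (default) or "bipolar".
#' @return an \linkS4class{LfpRecording}.
#' @export
LfpRecording <- function(data, fs, channels = NULL, regions = NULL,
                         referenceScheme = "common") {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  if (is.null(regions)) regions <- rep("HC", nrow(data))
  new("LfpRecording", data = data, fs = fs, channels = channels,
      regions = regions, referenceScheme = referenceScheme)
}

#' @describeIn LfpRecording-class number of samples
#' @param object,x an LfpRecording
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname LfpRecording-class
#' @export
setMethod("nSamples", "LfpRecording", function(x) ncol(x@data))

#' @rdname LfpRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname LfpRecording-class
#' @export
setMethod("samplingRate", "LfpRecording", function(x) x@fs)

#' @rdname LfpRecording-class
#' @export
setGeneric("lfpData", function(x) standardGeneric("lfpData"))
#' @rdname LfpRecording-class
#' @export
setMethod("lfpData", "LfpRecording", function(x) x@data)

#' @rdname LfpRecording-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname LfpRecording-class
#' @export
setMethod("channelLabels", "LfpRecording", function(x) x@channels)

#' @rdname LfpRecording-class
#' @export
setGeneric("channelRegions", function(x) standardGeneric("channelRegions"))
#' @rdname LfpRecording-class
#' @export
setMethod("channelRegions", "LfpRecording", function(x) x@regions)

#' @rdname LfpRecording-class
#' @export
setGeneric("referenceScheme", function(x) standardGeneric("referenceScheme"))
#' @rdname LfpRecording-class
#' @export
setMethod("referenceScheme", "LfpRecording", function(x) x@referenceScheme)

setMethod("show", "LfpRecording", function(object) {
  cat("LfpRecording:", nrow(object@data), "channel(s) x",
      ncol(object@data), "samples @", object@fs, "Hz (",
      object@referenceScheme, "reference )\n")
  cat("  channels:", paste(head(object@channels, 6L), collapse = ", "),
      if (length(object@channels) > 6L) "..." else "", "\n")
})

#' SpikeTrain: sorted spike times of one unit
#'
#' @slot times spike times in seconds, sorted ascending, relative to session
#'   start (t = 0).
#' @slot unitId unit identifier.
#' @slot region anatomical region label.
#' @exportClass SpikeTrain
setClass("SpikeTrain",
  representation(times = "numeric", unitId = "character",
                 region = "character"),
  validity = function(object) {
    if (is.unsorted(object@times)) return("spike times must be sorted")
    if (any(object@times < 0)) return("spike times must be nonnegative")
    TRUE
  })

#' Construct a SpikeTrain
#' @param times sorted spike times (s).
#' @param unitId unit label.
#' @param region region label.
#' @return a \linkS4class{SpikeTrain}.
#' @export
SpikeTrain <- function(times, unitId = "unit1", region = "HC")
  new("SpikeTrain", times = as.numeric(times), unitId = unitId,
      region = region)

#' @rdname SpikeTrain-class
#' @param x a SpikeTrain
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname SpikeTrain-class
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)

setMethod("show", "SpikeTrain", function(object) {
  cat("SpikeTrain", object@unitId, "(", object@region, "):",
      length(object@times), "spikes\n")
})

#' ArtifactMask: per-sample exclusion mask for ripple analyses
#'
#' The mask is the union of +-1 s dilations around detected interictal
#' epileptiform discharges (IEDs) and the exact extents of ripple-like events
#' in the grand-average signal.
#'
#' @slot mask logical channels x samples matrix; TRUE marks excluded samples.
#' @slot events data.frame with columns channel, start_s, end_s, source
#'   ("ied" or "grand_average_event").
#' @slot fs sampling rate (Hz).
#' @exportClass ArtifactMask
setClass("ArtifactMask",
  representation(mask = "matrix", events = "data.frame", fs = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    TRUE
  })

#' @rdname ArtifactMask-class
#' @param x an ArtifactMask
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname ArtifactMask-class
#' @export
setMethod("maskMatrix", "ArtifactMask", function(x) x@mask)

setMethod("show", "ArtifactMask", function(object) {
  cat("ArtifactMask:", nrow(object@mask), "channel(s) x", ncol(object@mask),
      "samples;", sum(object@mask), "samples masked (",
      round(100 * mean(object@mask), 2), "% )\n")
})

#' RateMap: occupancy-normalised spatial firing-rate map
#'
#' A 25 x 25 grid (bin edge 400 vu by default) over the circular arena.
#' Bins are valid when they were occupied and traversed at least twice;
#' smoothing (Gaussian, kernel size 5, sd 1.5 bins) is applied over valid
#' bins only, invalid bins carry NA.
#'
#' @slot rate smoothed firing rate (Hz) per bin; NA for invalid bins.
#' @slot rawRate unsmoothed rate per bin.
#' @slot occupancy seconds per bin.
#' @slot traversals number of entries into each bin.
#' @slot valid logical validity per bin.
#' @slot binSize bin edge length (vu).
#' @slot xEdges,yEdges bin edges (vu).
#' @exportClass RateMap
setClass("RateMap",
  representation(rate = "matrix", rawRate = "matrix", occupancy = "matrix",
                 traversals = "matrix", valid = "matrix", binSize = "numeric",
                 xEdges = "numeric", yEdges = "numeric"),
  validity = function(object) {
    d <- dim(object@rate)
    for (s in c("rawRate", "occupancy", "traversals", "valid"))
      if (!identical(dim(slot(object, s)), d))
        return("all map slots must share one grid")
    if (any(!is.na(object@rate[!object@valid])))
      return("invalid bins must carry NA rates")
    TRUE
  })

#' @rdname RateMap-class
#' @param x a RateMap
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))
#' @rdname RateMap-class
#' @export
setMethod("rateMatrix", "RateMap", function(x) x@rate)

#' @rdname RateMap-class
#' @export
setGeneric("validBins", function(x) standardGeneric("validBins"))
#' @rdname RateMap-class
#' @export
setMethod("validBins", "RateMap", function(x) x@valid)

setMethod("show", "RateMap", function(object) {
  cat("RateMap:", nrow(object@rate), "x", ncol(object@rate), "bins (edge",
      object@binSize, "vu);", sum(object@valid), "valid bins; peak rate",
      round(max(object@rate, na.rm = TRUE), 2), "Hz\n")
})

#' CoactivityMap: 2D ripple-locked coactivity z-scores of one cell pair
#'
#' Coactivity z-scores on a grid of (object-cell time bin, place-cell time
#' bin) combinations relative to the ripple peaks. The central map spans
#' +-0.25 s with 101 bin centres per axis (0.1 s bins, 0.005 s step, 95%
#' overlap). Bins whose margins are degenerate (a cell active in none or all
#' ripples) are NA.
#'
#' @slot z numeric matrix of coactivity z-scores (rows: cell A bins).
#' @slot binCentersA,binCentersB bin centres (s) relative to ripple peak.
#' @slot nRipples number of ripples entering the map.
#' @slot condition free-form condition tag.
#' @exportClass CoactivityMap
setClass("CoactivityMap",
  representation(z = "matrix", binCentersA = "numeric",
                 binCentersB = "numeric", nRipples = "numeric",
                 condition = "character"),
  validity = function(object) {
    if (nrow(object@z) != length(object@binCentersA) ||
        ncol(object@z) != length(object@binCentersB))
      return("z grid must match bin centres")
    TRUE
  })

#' @rdname CoactivityMap-class
#' @param x a CoactivityMap
#' @export
setGeneric("coactivityMatrix", function(x) standardGeneric("coactivityMatrix"))
#' @rdname CoactivityMap-class
#' @export
setMethod("coactivityMatrix", "CoactivityMap", function(x) x@z)

setMethod("show", "CoactivityMap", function(object) {
  cat("CoactivityMap (", object@condition, "): ", nrow(object@z), " x ",
      ncol(object@z), " bins over ", object@nRipples, " ripples; max z = ",
      round(suppressWarnings(max(object@z, na.rm = TRUE)), 3), "\n", sep = "")
})

#' RippleTriggeredAverage: ripple-locked average of a z-scored signal
#'
#' @slot time time axis (s) relative to ripple peaks.
#' @slot freq frequency axis (Hz) for spectrograms, NULL for rate traces.
#' @slot values freq x time matrix (or 1 x time for firing rates).
#' @slot n number of contributing ripples.
#' @exportClass RippleTriggeredAverage
setClass("RippleTriggeredAverage",
  representation(time = "numeric", freq = "numericOrNULL", values = "matrix",
                 n = "numeric"))

setMethod("show", "RippleTriggeredAverage", function(object) {
  cat("RippleTriggeredAverage:", nrow(object@values), "x",
      ncol(object@values), "(freq x time), n =", object@n, "ripples\n")
})

#' SessionBundle: one complete (synthetic or recorded) session
#'
#' All components share one time axis with t = 0 at session start.
#'
#' @slot lfp an \linkS4class{LfpRecording} or NULL.
#' @slot spikes list of \linkS4class{SpikeTrain} objects.
#' @slot nav navigation trace data.frame: t (s, 50 Hz), x, y (vu), heading
#'   (deg).
#' @slot trials trial table data.frame (see \code{\link{simulateBehavior}}).
#' @slot truth ground-truth list for synthetic sessions (empty otherwise).
#' @slot duration session duration (s).
#' @exportClass SessionBundle
setClass("SessionBundle",
  representation(lfp = "ANY", spikes = "list", nav = "data.frame",
                 trials = "data.frame", truth = "list", duration = "numeric"),
  validity = function(object) {
    if (!is.null(object@lfp)) {
      if (!is(object@lfp, "LfpRecording")) return("lfp must be LfpRecording")
      n <- ncol(object@lfp@data)
      if (abs(n - object@duration * object@lfp@fs) > 1)
        return("LFP sample count must equal duration x fs")
    }
    if (length(object@spikes) &&
        !all(vapply(object@spikes, is, TRUE, "SpikeTrain")))
      return("spikes must be SpikeTrain objects")
    TRUE
  })

setMethod("show", "SessionBundle", function(object) {
  cat("SessionBundle:", round(object@duration, 1), "s,",
      nrow(object@trials), "trials,", length(object@spikes), "units,",
      if (is.null(object@lfp)) "no LFP" else
        paste(nrow(object@lfp@data), "LFP channel(s)"), "\n")
})
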