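#' Default pipeline parameters
#'
#' All numeric defaults follow the analysis conventions used throughout
#' the package (detector thresholds, surrogate counts, bin geometries).
#' Surrogate counts can be lowered for smoke tests.
#'
#' @param nSurrogatesTuning surrogates for cell classification.
#' @param nSurrogatesPhase surrogates for delta phase locking.
#' @param nSurrogatesContrast surrogates for coactivity contrasts.
#' @param nSurrogatesPerformance surrogate drop errors per trial.
#' @param arenaRadius arena radius (vu).
#' @return named list of parameters.
#' @export
pipelineDefaults <- function(nSurrogatesTuning = 1001L,
                             nSurrogatesPhase = 1001L,
                             nSurrogatesContrast = 2001L,
                             nSurrogatesPerformance = 1e5,
                             arenaRadius = 5000) {
  list(nSurrogatesTuning = nSurrogatesTuning,
       nSurrogatesPhase = nSurrogatesPhase,
       nSurrogatesContrast = nSurrogatesContrast,
       nSurrogatesPerformance = nSurrogatesPerformance,
       arenaRadius = arenaRadius)
}

#' Run the full analysis pipeline on a session
#'
#' Executes preprocessing (line-noise removal; bipolar re-referencing if
#' the LFP still carries a common reference), artifact detection (IEDs
#' per channel, grand-average ripple-like events when two or more
#' channels exist), ripple detection per channel, behavioural scoring,
#' delta phase locking, object-cell and place-cell classification, pair
#' labelling and the coactivity contrasts. Stages that lack their inputs
#' (e.g. no LFP, too few units) are skipped and noted in the manifest.
#'
#' @param session a \linkS4class{SessionBundle}.
#' @param params parameter list from \code{\link{pipelineDefaults}}.
#' @param seed master seed for all stochastic stages.
#' @return list with per-stage results and a manifest recording seeds,
#'   parameters and stage status.
#' @export
runPipeline <- function(session, params = pipelineDefaults(), seed = 1L) {
  stopifnot(is(session, "SessionBundle"))
  status <- list()
  res <- list()

  ## behaviour
  trials <- addMemoryPerformance(session@trials, params$arenaRadius,
                                 params$nSurrogatesPerformance,
                                 seed = seed)
  ms <- movementState(session@nav)
  res$trials <- trials
  res$learning <- learningSummaries(trials)
  res$formation <- memoryFormationByObject(trials)
  status$behavior <- "ok"

  ## preprocessing + artifacts + ripples
  ripples <- NULL
  mask <- NULL
  if (!is.null(session@lfp)) {
    lfp <- session@lfp
    if (referenceScheme(lfp) == "common") lfp <- bipolarRereference(lfp)
    lfp <- removeLineNoise(lfp)
    fs <- samplingRate(lfp)
    nCh <- nrow(lfpData(lfp))
    ieds <- lapply(seq_len(nCh), function(c)
      detectIeds(lfpData(lfp)[c, ], fs)$events)
    names(ieds) <- channelLabels(lfp)
    gaEv <- if (nCh >= 2L)
      detectGrandAverageEvents(grandAverageSignal(lfp), fs) else NULL
    mask <- buildArtifactMask(ieds, gaEv, nSamples(lfp), fs,
                              channels = channelLabels(lfp))
    ripples <- do.call(rbind, lapply(seq_len(nCh), function(c)
      detectRipples(lfpData(lfp)[c, ], fs, maskMatrix(mask)[c, ],
                    channel = channelLabels(lfp)[c])))
    res$ieds <- ieds
    res$mask <- mask
    res$ripples <- ripples
    status$ripples <- sprintf("ok (%d events)", nrow(ripples))
    hc <- which(channelRegions(lfp) == "HC")
    if (length(hc) && nrow(ripples)) {
      ch1 <- hc[1L]
      pk <- ripples$t_peak[ripples$channel == channelLabels(lfp)[ch1]]
      if (length(pk) >= 10L) {
        res$phaseLocking <- deltaPhaseLocking(
          lfpData(lfp)[ch1, ], pk, fs,
          nSurrogates = params$nSurrogatesPhase, seed = seed + 1L)
        status$phaseLocking <- "ok"
      }
      res$rateByPhase <- rippleRatesByPhase(ripples, trials,
                                            seed = seed + 2L)
      status$rateByPhase <- "ok"
    }
  } else status$ripples <- "skipped (no LFP)"

  ## tuning
  objectCells <- list(); placeCells <- list()
  if (length(session@spikes)) {
    for (u in seq_along(session@spikes)) {
      sp <- session@spikes[[u]]
      oc <- classifyObjectCell(sp, trials,
                               nSurrogates = params$nSurrogatesTuning,
                               seed = seed + 10L + u)
      pc <- classifyPlaceCell(sp, session@nav, ms$idle,
                              nSurrogates = params$nSurrogatesTuning,
                              seed = seed + 10L + u,
                              arenaRadius = params$arenaRadius)
      objectCells[[u]] <- oc
      placeCells[[u]] <- pc
    }
    res$objectCells <- objectCells
    res$placeCells <- placeCells
    status$tuning <- sprintf("ok (%d object, %d place)",
                             sum(vapply(objectCells, `[[`, TRUE,
                                        "isObjectCell")),
                             sum(vapply(placeCells, `[[`, TRUE,
                                        "significant")))
  } else status$tuning <- "skipped (no units)"

  ## coactivity
  if (!is.null(ripples) && nrow(ripples) && length(session@spikes)) {
    ocIdx <- which(vapply(objectCells, `[[`, TRUE, "isObjectCell"))
    pcIdx <- which(vapply(placeCells, `[[`, TRUE, "significant"))
    if (length(ocIdx) && length(pcIdx)) {
      ocDf <- data.frame(
        unit = ocIdx,
        preferred_object = vapply(objectCells[ocIdx], `[[`, 1,
                                  "preferredObject"))
      pcList <- lapply(pcIdx, function(u)
        list(unit = u, fieldBins = placeCells[[u]]$fieldBins,
             gridN = placeCells[[u]]$gridN))
      res$coactivity <- list()
      for (ctx in c("retrieval", "re_encoding")) {
        pairs <- labelPairs(ocDf, pcList, trials, ctx,
                            params$arenaRadius)
        keep <- selectRipples(ripples, trials, phase = ctx)
        pk <- ripples$t_peak[keep]
        if (length(pk) < 5L) next
        maps <- lapply(pairs, function(p) {
          aA <- rippleLockedActivity(session@spikes[[p$objectUnit]], pk)
          aB <- rippleLockedActivity(session@spikes[[p$placeUnit]], pk)
          list(pair = p,
               map = buildCoactivityMap(aA, aB, condition = ctx),
               baseline = baselineCoactivityMap(aA, aB))
        })
        assoc <- vapply(maps, function(m) m$pair$associative, logical(1))
        out <- list(pairs = pairs, maps = maps)
        if (sum(assoc) >= 5L) {
          mA <- lapply(maps[assoc], `[[`, "map")
          out$vsChance <- groupContrast(
            mA, mode = "vs_chance",
            nSurrogates = params$nSurrogatesContrast, seed = seed + 20L)
          out$vsBaseline <- groupContrast(
            mA, lapply(maps[assoc], `[[`, "baseline"),
            mode = "vs_baseline",
            nSurrogates = params$nSurrogatesContrast, seed = seed + 21L)
          if (sum(!assoc) >= 5L)
            out$vsNonAssociative <- groupContrast(
              mA, lapply(maps[!assoc], `[[`, "map"),
              mode = "vs_nonassociative",
              nSurrogates = params$nSurrogatesContrast,
              seed = seed + 22L)
        }
        res$coactivity[[ctx]] <- out
      }
      status$coactivity <- "ok"
    } else status$coactivity <- "skipped (no classified pairs)"
  } else status$coactivity <- "skipped (missing ripples or units)"

  res$manifest <- list(
    package = "ripplecoact",
    version = as.character(utils::packageVersion("ripplecoact")),
    seed = seed, params = params, status = status,
    rVersion = R.version.string)
  res
}
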