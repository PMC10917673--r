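## Ripple-locked coactivity of object-cell / place-cell pairs: binary
## ripple-locked activity grids, the coactivity z-score, 2D time-by-time
## coactivity maps, condition splits, pair labelling and the group-level
## permutation contrasts.

#' Bin centres of the ripple-locked activity grid
#'
#' With the defaults (half window 0.75 s, step 0.005 s) the activity grid
#' has 301 centres; the central coactivity map (half window 0.25 s) has
#' 101 centres per axis. Neighbouring 0.1 s bins at 0.005 s step overlap
#' by 95%.
#'
#' @param halfWindowS half width of the grid (s).
#' @param stepS step between bin centres (s).
#' @return numeric vector of bin centres (s).
#' @export
activityBinCenters <- function(halfWindowS = 0.75, stepS = 0.005)
  seq(-halfWindowS, halfWindowS, by = stepS)

#' Binary ripple-locked activity of one unit
#'
#' For each ripple and each bin centre c the entry is 1 iff the unit
#' spiked within [c - binWidth/2, c + binWidth/2] seconds of that
#' ripple's peak.
#'
#' @param spikes a \linkS4class{SpikeTrain} or numeric spike times.
#' @param peaks ripple peak times (s).
#' @param halfWindowS grid half width (s, default 0.75).
#' @param binWidthS bin width (s, default 0.1).
#' @param stepS bin step (s, default 0.005).
#' @return list with act (nRipples x nBins 0/1 matrix) and centers (s).
#' @export
rippleLockedActivity <- function(spikes, peaks, halfWindowS = 0.75,
                                 binWidthS = 0.1, stepS = 0.005) {
  st <- sort(if (is(spikes, "SpikeTrain")) spikeTimes(spikes) else spikes)
  centers <- activityBinCenters(halfWindowS, stepS)
  tm <- outer(peaks, centers, "+")
  hi <- findInterval(tm + binWidthS / 2, st)
  lo <- findInterval(tm - binWidthS / 2, st)
  act <- matrix(as.numeric(hi > lo), nrow = length(peaks))
  list(act = act, centers = centers)
}

#' Pairwise coactivity z-score
#'
#' Across N ripples, with cell A active in nA, cell B in nB and both in
#' nAB, the coactivity z-score is
#' \deqn{z = \frac{n_{AB} - n_A n_B / N}
#'   {\sqrt{n_A n_B (N - n_A)(N - n_B) / (N^2 (N - 1))}}}
#' which equals the Pearson correlation of the two binary activity
#' vectors multiplied by \eqn{\sqrt{N - 1}}. The score is undefined (NA)
#' when a margin is degenerate (a cell active in none or all ripples).
#'
#' @param nAB joint active-ripple count (vectorised).
#' @param nA,nB per-cell active-ripple counts.
#' @param N total ripple count (>= 2).
#' @return numeric coactivity z-score(s); NA where undefined.
#' @export
coactivityZ <- function(nAB, nA, nB, N) {
  stopifnot(all(N >= 2))
  num <- nAB - nA * nB / N
  den <- sqrt(nA * nB * (N - nA) * (N - nB) / (N^2 * (N - 1)))
  z <- num / den
  z[nA <= 0 | nA >= N | nB <= 0 | nB >= N] <- NA_real_
  z
}

## core: z matrix over all (binA, binB) combinations for given columns
coactivityGrid <- function(A, B, N) {
  nA <- colSums(A); nB <- colSums(B)
  nAB <- crossprod(A, B)                  # bins(A) x bins(B)
  num <- nAB - outer(nA, nB) / N
  den <- sqrt(outer(nA * (N - nA), nB * (N - nB)) / (N^2 * (N - 1)))
  z <- num / den
  bad <- outer(nA <= 0 | nA >= N, nB <= 0 | nB >= N, "|")
  z[bad] <- NA_real_
  z
}

#' 2D time-by-time coactivity map of one cell pair
#'
#' For every combination of a ripple-locked time bin of cell A (the
#' object cell) and one of cell B (the place cell) within
#' +-\code{mapHalfWindowS} of the ripple peaks, the coactivity z-score is
#' computed across the chosen ripple subset, yielding the central
#' 101 x 101 map.
#'
#' @param actA,actB activity lists from \code{\link{rippleLockedActivity}}
#'   built on the same ripples.
#' @param rippleSubset optional logical/integer subset of ripples.
#' @param mapHalfWindowS central map half width (s, default 0.25).
#' @param condition condition tag stored in the map.
#' @return a \linkS4class{CoactivityMap}.
#' @export
buildCoactivityMap <- function(actA, actB, rippleSubset = NULL,
                               mapHalfWindowS = 0.25, condition = "all") {
  stopifnot(identical(actA$centers, actB$centers))
  A <- actA$act; B <- actB$act
  if (!is.null(rippleSubset)) {
    A <- A[rippleSubset, , drop = FALSE]
    B <- B[rippleSubset, , drop = FALSE]
  }
  N <- nrow(A)
  sel <- which(abs(actA$centers) <= mapHalfWindowS + 1e-9)
  z <- coactivityGrid(A[, sel, drop = FALSE], B[, sel, drop = FALSE], N)
  new("CoactivityMap", z = unname(as.matrix(z)),
      binCentersA = actA$centers[sel], binCentersB = actB$centers[sel],
      nRipples = N, condition = condition)
}

#' Baseline coactivity map of one cell pair
#'
#' The baseline is the element-wise mean of the two diagonal 101 x 101
#' sub-blocks of the full 301-bin grid whose bin centres lie entirely in
#' [-0.75, -0.25] s and [0.25, 0.75] s around the ripple peaks.
#'
#' @inheritParams buildCoactivityMap
#' @return a \linkS4class{CoactivityMap} tagged "baseline".
#' @export
baselineCoactivityMap <- function(actA, actB, rippleSubset = NULL,
                                  mapHalfWindowS = 0.25) {
  stopifnot(identical(actA$centers, actB$centers))
  A <- actA$act; B <- actB$act
  if (!is.null(rippleSubset)) {
    A <- A[rippleSubset, , drop = FALSE]
    B <- B[rippleSubset, , drop = FALSE]
  }
  N <- nrow(A)
  ctr <- actA$centers
  pre <- which(ctr >= -0.75 - 1e-9 & ctr <= -0.25 + 1e-9)
  post <- which(ctr >= 0.25 - 1e-9 & ctr <= 0.75 + 1e-9)
  z1 <- coactivityGrid(A[, pre, drop = FALSE], B[, pre, drop = FALSE], N)
  z2 <- coactivityGrid(A[, post, drop = FALSE], B[, post, drop = FALSE], N)
  z <- matrix(rowMeans(cbind(as.vector(z1), as.vector(z2)), na.rm = TRUE),
              nrow(z1), ncol(z1))
  z[is.nan(z)] <- NA_real_
  ctrSel <- which(abs(ctr) <= mapHalfWindowS + 1e-9)
  new("CoactivityMap", z = unname(z), binCentersA = ctr[ctrSel],
      binCentersB = ctr[ctrSel], nRipples = N, condition = "baseline")
}

#' Pearson-correlation variant of the coactivity map
#'
#' Computes, per bin pair, the Pearson correlation of the binary
#' across-ripple activity vectors. Wherever defined this equals the
#' coactivity z-score divided by sqrt(N - 1).
#'
#' @inheritParams buildCoactivityMap
#' @return a \linkS4class{CoactivityMap} holding correlations.
#' @export
coactivityPearsonMap <- function(actA, actB, rippleSubset = NULL,
                                 mapHalfWindowS = 0.25,
                                 condition = "pearson") {
  stopifnot(identical(actA$centers, actB$centers))
  A <- actA$act; B <- actB$act
  if (!is.null(rippleSubset)) {
    A <- A[rippleSubset, , drop = FALSE]
    B <- B[rippleSubset, , drop = FALSE]
  }
  N <- nrow(A)
  sel <- which(abs(actA$centers) <= mapHalfWindowS + 1e-9)
  As <- A[, sel, drop = FALSE]; Bs <- B[, sel, drop = FALSE]
  nA <- colSums(As); nB <- colSums(Bs)
  nAB <- crossprod(As, Bs)
  num <- N * nAB - outer(nA, nB)
  den <- sqrt(outer(nA * (N - nA), nB * (N - nB)))
  r <- num / den
  bad <- outer(nA <= 0 | nA >= N, nB <= 0 | nB >= N, "|")
  r[bad] <- NA_real_
  new("CoactivityMap", z = unname(as.matrix(r)),
      binCentersA = actA$centers[sel], binCentersB = actA$centers[sel],
      nRipples = N, condition = condition)
}

#' Circular-shift surrogate coactivity map
#'
#' Circularly shifts the ripple-locked activity of the object cell along
#' its time-bin axis by a random lag (at least \code{minShiftSteps} bins,
#' wrap-around) before building the map; used by the shift-surrogate
#' variant of the chance contrast.
#'
#' @inheritParams buildCoactivityMap
#' @param minShiftSteps minimum shift in bin steps (default 20, i.e.
#'   0.1 s).
#' @param seed integer seed.
#' @return a \linkS4class{CoactivityMap} tagged "shift_surrogate".
#' @export
shiftSurrogateMap <- function(actA, actB, rippleSubset = NULL,
                              mapHalfWindowS = 0.25, minShiftSteps = 20L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- length(actA$centers)
  lag <- sample(minShiftSteps:(nb - minShiftSteps), 1L)
  shifted <- actA
  shifted$act <- actA$act[, ((seq_len(nb) - 1L + lag) %% nb) + 1L,
                          drop = FALSE]
  buildCoactivityMap(shifted, actB, rippleSubset, mapHalfWindowS,
                     condition = "shift_surrogate")
}

#' Select ripples by trial phase and condition split
#'
#' Retrieval ripples occur between retrieval onset and feedback onset;
#' re-encoding ripples between re-encoding onset and the next trial's ITI
#' onset (or session end for the last trial). Splits: "early"/"late" are
#' the first/last n/2 of ALL session ripples (ordered per channel by peak
#' time), intersected with the phase; "before_formation"/
#' "after_formation" partition the phase ripples by whether their trial
#' lies at/before or after the trial of strongest memory improvement of
#' that trial's object; "moving"/"resting" split by the movement state at
#' the ripple peak.
#'
#' @param ripples ripple event data.frame.
#' @param trials trial table (needs performance for formation splits).
#' @param phase "retrieval" or "re_encoding".
#' @param split one of "all", "early", "late", "before_formation",
#'   "after_formation", "moving", "resting".
#' @param nav navigation trace (required for movement splits).
#' @param formation optional precomputed result of
#'   \code{\link{memoryFormationByObject}}.
#' @return logical vector over ripple rows.
#' @export
selectRipples <- function(ripples, trials,
                          phase = c("retrieval", "re_encoding"),
                          split = "all", nav = NULL, formation = NULL) {
  phase <- match.arg(phase)
  split <- match.arg(split, c("all", "early", "late", "before_formation",
                              "after_formation", "moving", "resting"))
  pk <- ripples$t_peak
  n <- nrow(trials)
  if (phase == "retrieval") {
    ws <- trials$retrieval_start; we <- trials$feedback_start
  } else {
    ws <- trials$re_encoding_start
    we <- c(trials$iti_start[-1L], Inf)
  }
  trialOf <- rep(NA_integer_, length(pk))
  inPhase <- logical(length(pk))
  for (k in seq_len(n)) {
    sel <- pk >= ws[k] & pk < we[k]
    inPhase <- inPhase | sel
    trialOf[sel] <- k
  }
  keep <- inPhase
  if (split %in% c("early", "late")) {
    rank <- stats::ave(pk, ripples$channel, FUN = rank)
    tot <- stats::ave(pk, ripples$channel, FUN = length)
    early <- rank <= floor(tot / 2)
    keep <- keep & if (split == "early") early else !early
  } else if (split %in% c("before_formation", "after_formation")) {
    if (is.null(formation)) formation <- memoryFormationByObject(trials)
    ft <- formation$formation_trial[match(trials$object_id[trialOf],
                                          formation$object_id)]
    before <- !is.na(trialOf) & !is.na(ft) &
      trials$trial_index[trialOf] <= ft
    keep <- keep & if (split == "before_formation") before else
      (!is.na(trialOf) & !is.na(ft) & !before)
  } else if (split %in% c("moving", "resting")) {
    stopifnot(!is.null(nav))
    ms <- movementState(nav)
    idx <- pmin(nrow(nav), pmax(1L, round(pk * 50) + 1L))
    moving <- ms$moving[idx]
    keep <- keep & if (split == "moving") moving else !moving
  }
  keep
}

#' Label object cell-place cell pairs as associative or non-associative
#'
#' For each pair and context, the analysis considers only the trials in
#' which the cue object is the object cell's preferred object. A trial
#' carries associative information when the relevant location (the
#' participant's response location during retrieval, the object's
#' correct location during re-encoding) falls inside the place cell's
#' place field; otherwise it is non-associative. The pair is labelled
#' associative when at least one preferred-object trial is associative.
#'
#' @param objectCells data.frame with columns unit and preferred_object.
#' @param placeCells list of entries list(unit, fieldBins, gridN).
#' @param trials trial table.
#' @param context "retrieval" or "re_encoding".
#' @param arenaRadius arena radius (vu).
#' @return list of pair entries: objectUnit, placeUnit, context,
#'   associative (logical), associativeTrials, nonAssociativeTrials
#'   (trial indices).
#' @export
labelPairs <- function(objectCells, placeCells, trials,
                       context = c("retrieval", "re_encoding"),
                       arenaRadius = 5000) {
  context <- match.arg(context)
  out <- list()
  for (i in seq_len(nrow(objectCells))) {
    pref <- objectCells$preferred_object[i]
    sel <- which(trials$object_id == pref)
    if (!length(sel)) next
    lx <- if (context == "retrieval") trials$response_x[sel] else
      trials$correct_x[sel]
    ly <- if (context == "retrieval") trials$response_y[sel] else
      trials$correct_y[sel]
    for (pcEntry in placeCells) {
      gridN <- pcEntry$gridN
      binSize <- 2 * arenaRadius / gridN
      ix <- pmin(gridN, pmax(1L, floor((lx + arenaRadius) / binSize) + 1L))
      iy <- pmin(gridN, pmax(1L, floor((ly + arenaRadius) / binSize) + 1L))
      inField <- (ix + gridN * (iy - 1L)) %in% pcEntry$fieldBins
      out[[length(out) + 1L]] <- list(
        objectUnit = objectCells$unit[i], placeUnit = pcEntry$unit,
        context = context, associative = any(inField),
        associativeTrials = trials$trial_index[sel[inField]],
        nonAssociativeTrials = trials$trial_index[sel[!inField]])
    }
  }
  out
}

#' Group-level permutation contrast on coactivity maps
#'
#' Stacks one coactivity map per object cell-place cell-ripple channel
#' combination and runs a one-sided cluster-based permutation test.
#' Modes: "vs_chance" tests the maps against zero (sign-flip
#' surrogates); "vs_baseline" compares the maps with their paired
#' baseline maps (random subset swapping); "vs_nonassociative" compares
#' associative against non-associative maps (random set reassignment);
#' "vs_shift_surrogate" subtracts a paired circular-shift surrogate map
#' from each empirical map and tests the differences against zero. P
#' values may be Bonferroni-corrected (e.g. factor 2 when both early and
#' late ripples are analysed).
#'
#' @param mapsA list of \linkS4class{CoactivityMap} (set A).
#' @param mapsB list of maps for the paired/second set (required for all
#'   modes except "vs_chance").
#' @param mode contrast mode (see above).
#' @param nSurrogates surrogate count (default 2001).
#' @param seed integer seed.
#' @param bonferroniFactor multiplies the cluster p values (default 1).
#' @param connectivity cluster connectivity (default 4).
#' @param minValid minimum valid maps per bin (default 5).
#' @return a cluster test result (see \code{\link{clusterTest}}) with an
#'   extra column pCorr in clusters.
#' @export
groupContrast <- function(mapsA, mapsB = NULL,
                          mode = c("vs_chance", "vs_baseline",
                                   "vs_nonassociative",
                                   "vs_shift_surrogate"),
                          nSurrogates = 2001L, seed = 1L,
                          bonferroniFactor = 1, connectivity = 4,
                          minValid = 5L) {
  mode <- match.arg(mode)
  stack <- function(maps) {
    do.call(rbind, lapply(maps, function(m) as.vector(coactivityMatrix(m))))
  }
  dims <- dim(coactivityMatrix(mapsA[[1L]]))
  X <- stack(mapsA)
  res <- switch(mode,
    vs_chance = clusterTest(X, test = "one_sample",
                            alternative = "greater", scheme = "sign_flip",
                            nSurrogates = nSurrogates, dims = dims,
                            connectivity = connectivity,
                            minValid = minValid, seed = seed),
    vs_baseline = {
      stopifnot(length(mapsB) == length(mapsA))
      clusterTest(X, stack(mapsB), test = "two_sample",
                  alternative = "greater", scheme = "set_swap",
                  nSurrogates = nSurrogates, dims = dims,
                  connectivity = connectivity, minValid = minValid,
                  seed = seed)
    },
    vs_nonassociative = {
      stopifnot(length(mapsB) >= 1L)
      clusterTest(X, stack(mapsB), test = "two_sample",
                  alternative = "greater", scheme = "label_reassign",
                  nSurrogates = nSurrogates, dims = dims,
                  connectivity = connectivity, minValid = minValid,
                  seed = seed)
    },
    vs_shift_surrogate = {
      stopifnot(length(mapsB) == length(mapsA))
      clusterTest(X - stack(mapsB), test = "one_sample",
                  alternative = "greater", scheme = "sign_flip",
                  nSurrogates = nSurrogates, dims = dims,
                  connectivity = connectivity, minValid = minValid,
                  seed = seed)
    })
  if (nrow(res$clusters))
    res$clusters$pCorr <- pmin(1, res$clusters$pPlusOne * bonferroniFactor)
  res
}
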