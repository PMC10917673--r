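## Object-cell, place-cell and conjunctive-cell classification with
## surrogate nulls. The place-cell machinery is built around a reusable
## "spatial context" (10 Hz resampled behaviour, bin assignments, sparse
## aggregation and smoothing operators) so that the 1,001 circular-shift
## surrogates, each re-running the full candidate-field procedure, stay
## cheap.

## 5 x 5 Gaussian kernel, sd 1.5 bins (as a matrix, unnormalised)
fieldSmoothKernel <- function(size = 5L, sigma = 1.5) {
  half <- (size - 1L) / 2
  g <- outer(-half:half, -half:half,
             function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  g / sum(g)
}

## Build the spatial context: 10 Hz samples, bin index, occupancy,
## traversals, validity, aggregation matrix M (bins x samples) and
## normalised smoothing operator S (bins x bins over valid bins).
spatialContext <- function(nav, idle = NULL, arenaRadius = 5000,
                           gridN = 25L, windows = NULL) {
  fsNav <- 1 / median(diff(nav$t))
  dec <- max(1L, round(fsNav / 10))
  nBlocks <- floor(nrow(nav) / dec)
  grp <- rep(seq_len(nBlocks), each = dec)[seq_len(nBlocks * dec)]
  x10 <- as.numeric(rowsum(nav$x[seq_along(grp)], grp)) / dec
  y10 <- as.numeric(rowsum(nav$y[seq_along(grp)], grp)) / dec
  t10 <- (seq_len(nBlocks) - 0.5) * dec / fsNav
  keep <- rep(TRUE, nBlocks)
  if (!is.null(idle)) {
    idle10 <- as.numeric(rowsum(as.numeric(idle[seq_along(grp)]), grp)) /
      dec > 0.5
    keep <- keep & !idle10
  }
  if (!is.null(windows) && nrow(windows)) {
    inWin <- rep(FALSE, nBlocks)
    for (i in seq_len(nrow(windows)))
      inWin <- inWin | (t10 >= windows[i, 1L] & t10 < windows[i, 2L])
    keep <- keep & inWin
  }
  x10 <- x10[keep]; y10 <- y10[keep]; t10 <- t10[keep]
  nS <- length(t10)
  binSize <- 2 * arenaRadius / gridN
  ix <- pmin(gridN, pmax(1L, floor((x10 + arenaRadius) / binSize) + 1L))
  iy <- pmin(gridN, pmax(1L, floor((y10 + arenaRadius) / binSize) + 1L))
  binIdx <- ix + gridN * (iy - 1L)
  nBins <- gridN * gridN
  occCnt <- tabulate(binIdx, nbins = nBins)
  newRun <- c(TRUE, binIdx[-1L] != binIdx[-nS])
  traversals <- tabulate(binIdx[newRun], nbins = nBins)
  valid <- occCnt > 0L & traversals >= 2L
  M <- sparseMatrix(i = binIdx, j = seq_len(nS), x = 1,
                    dims = c(nBins, nS))
  ## normalised smoothing operator over valid bins
  K <- fieldSmoothKernel()
  half <- 2L
  ii <- jj <- integer(0); vv <- numeric(0)
  vIdx <- which(valid)
  vx <- (vIdx - 1L) %% gridN + 1L
  vy <- (vIdx - 1L) %/% gridN + 1L
  isValid <- valid
  for (dx in -half:half) for (dy in -half:half) {
    sx <- vx + dx; sy <- vy + dy
    ok <- sx >= 1L & sx <= gridN & sy >= 1L & sy <= gridN
    src <- sx + gridN * (sy - 1L)
    ok[ok] <- isValid[src[ok]]
    w <- K[dx + half + 1L, dy + half + 1L]
    ii <- c(ii, vIdx[ok]); jj <- c(jj, src[ok])
    vv <- c(vv, rep(w, sum(ok)))
  }
  S <- sparseMatrix(i = ii, j = jj, x = vv, dims = c(nBins, nBins))
  rs <- Matrix::rowSums(S)
  rs[rs == 0] <- 1
  S <- S / rs
  list(t10 = t10, x10 = x10, y10 = y10, binIdx = binIdx, nS = nS,
       occCnt = occCnt, traversals = traversals, valid = valid,
       M = M, S = S, gridN = gridN, binSize = binSize, dt = 0.1,
       arenaRadius = arenaRadius)
}

## spike counts on the context's 10 Hz sample grid
spikeCounts10 <- function(st, ctx) {
  lo <- ctx$t10 - ctx$dt / 2
  hi <- ctx$t10 + ctx$dt / 2
  findInterval(hi, sort(st)) - findInterval(lo, sort(st))
}

## one pass of the candidate-field procedure; rate10 in Hz per sample
placeFieldOnce <- function(rate10, ctx, connectivity = 4) {
  mapRaw <- as.numeric(ctx$M %*% rate10)
  mapRaw[ctx$occCnt > 0L] <- mapRaw[ctx$occCnt > 0L] /
    ctx$occCnt[ctx$occCnt > 0L]
  sm <- as.numeric(ctx$S %*% (mapRaw * ctx$valid))
  sm[!ctx$valid] <- NA_real_
  thr <- quantile(sm[ctx$valid], 0.75, names = FALSE)
  mask <- matrix(!is.na(sm) & sm > thr, ctx$gridN, ctx$gridN)
  lab <- labelComponents(mask, connectivity)
  if (!any(lab > 0L))
    return(list(t = NA_real_, bins = integer(0), sm = sm))
  sums <- rowsum(sm[lab > 0L], lab[lab > 0L])
  best <- as.integer(rownames(sums))[which.max(sums)]
  bins <- which(as.vector(lab) == best)
  fieldFlag <- logical(ctx$gridN^2)
  fieldFlag[bins] <- TRUE
  inField <- fieldFlag[ctx$binIdx]
  okSample <- ctx$valid[ctx$binIdx]
  xin <- rate10[inField & okSample]
  xout <- rate10[!inField & okSample]
  t <- if (length(xin) >= 2L && length(xout) >= 2L)
    pooledT(xin, xout) else NA_real_
  list(t = t, bins = bins, sm = sm)
}

#' Occupancy-normalised spatial firing-rate map
#'
#' Behavioural samples are resampled to 10 Hz, idle periods (no
#' translation and no turning for more than 2 s) are excluded, and spike
#' counts are binned on a 25 x 25 grid (bin edge 400 vu). Bins traversed
#' fewer than two times are invalid. The rate map is smoothed with a
#' 5 x 5 Gaussian kernel (sd 1.5 bins) normalised over valid bins.
#'
#' @param spikes a \linkS4class{SpikeTrain} or numeric spike times.
#' @param nav navigation trace (50 Hz data.frame t, x, y, heading).
#' @param idle optional logical idle mask aligned to nav rows (from
#'   \code{\link{movementState}}); NULL computes it internally.
#' @param arenaRadius arena radius (vu).
#' @param gridN grid size per axis (default 25).
#' @return a \linkS4class{RateMap}.
#' @export
computeRateMap <- function(spikes, nav, idle = NULL, arenaRadius = 5000,
                           gridN = 25L) {
  st <- if (is(spikes, "SpikeTrain")) spikeTimes(spikes) else spikes
  if (is.null(idle)) idle <- movementState(nav)$idle
  ctx <- spatialContext(nav, idle, arenaRadius, gridN)
  rate10 <- spikeCounts10(st, ctx) / ctx$dt
  mapRaw <- as.numeric(ctx$M %*% rate10)
  mapRaw[ctx$occCnt > 0L] <- mapRaw[ctx$occCnt > 0L] /
    ctx$occCnt[ctx$occCnt > 0L]
  mapRaw[!ctx$valid] <- NA_real_
  sm <- as.numeric(ctx$S %*% ifelse(ctx$valid, mapRaw, 0))
  sm[!ctx$valid] <- NA_real_
  edges <- seq(-arenaRadius, arenaRadius, length.out = gridN + 1L)
  new("RateMap",
      rate = matrix(sm, gridN, gridN),
      rawRate = matrix(mapRaw, gridN, gridN),
      occupancy = matrix(ctx$occCnt * ctx$dt, gridN, gridN),
      traversals = matrix(ctx$traversals, gridN, gridN),
      valid = matrix(ctx$valid, gridN, gridN),
      binSize = ctx$binSize, xEdges = edges, yEdges = edges)
}

#' Classify a place cell with circular-shift surrogates
#'
#' The smoothed rate map is thresholded at the 75th percentile of its
#' valid bins; contiguous suprathreshold bins form candidate place
#' fields, of which the one with the highest summed firing rate is kept.
#' Field strength is the pooled two-sample t statistic comparing 10 Hz
#' firing rates inside versus outside the field. The cell is a place
#' cell iff the empirical t exceeds the \code{1 - alpha} quantile of
#' \code{nSurrogates} surrogate t statistics, each obtained by circularly
#' shifting the firing rates relative to the behaviour by a random lag
#' (uniform over [30 s, session - 30 s]) and re-running the entire
#' candidate procedure.
#'
#' @inheritParams computeRateMap
#' @param nSurrogates number of circular-shift surrogates (default 1001).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param windows optional matrix of time windows (start, end) restricting
#'   the behavioural samples (used by the conjunctive-cell analysis).
#' @param ctx optional precomputed spatial context (internal reuse).
#' @param connectivity candidate-field connectivity (default 4).
#' @return list with significant, tStat, pRank, fieldBins (grid indices),
#'   centroid (vu), surrogateT, map (\linkS4class{RateMap}), nSpikes.
#' @export
classifyPlaceCell <- function(spikes, nav, idle = NULL, nSurrogates = 1001L,
                              alpha = 0.05, seed = 1L, arenaRadius = 5000,
                              gridN = 25L, windows = NULL, ctx = NULL,
                              connectivity = 4) {
  st <- if (is(spikes, "SpikeTrain")) spikeTimes(spikes) else spikes
  if (is.null(ctx)) {
    if (is.null(idle)) idle <- movementState(nav)$idle
    ctx <- spatialContext(nav, idle, arenaRadius, gridN, windows)
  }
  rate10 <- spikeCounts10(st, ctx) / ctx$dt
  emp <- placeFieldOnce(rate10, ctx, connectivity)
  set.seed(seed)
  minLag <- min(round(30 / ctx$dt), floor(ctx$nS / 4))
  lagPool <- minLag:(ctx$nS - minLag)
  surT <- rep(NA_real_, nSurrogates)
  idx0 <- seq_len(ctx$nS)
  for (i in seq_len(nSurrogates)) {
    lag <- lagPool[sample.int(length(lagPool), 1L)]
    shifted <- rate10[((idx0 - 1L + lag) %% ctx$nS) + 1L]
    surT[i] <- placeFieldOnce(shifted, ctx, connectivity)$t
  }
  okSur <- surT[!is.na(surT)]
  sig <- !is.na(emp$t) && length(okSur) > 10L &&
    emp$t > quantile(okSur, 1 - alpha, names = FALSE)
  pRank <- if (is.na(emp$t)) NA_real_ else mean(okSur >= emp$t)
  centroid <- if (length(emp$bins)) {
    bx <- ((emp$bins - 1L) %% gridN + 0.5) * ctx$binSize - arenaRadius
    by <- ((emp$bins - 1L) %/% gridN + 0.5) * ctx$binSize - arenaRadius
    w <- emp$sm[emp$bins]
    c(sum(bx * w) / sum(w), sum(by * w) / sum(w))
  } else c(NA_real_, NA_real_)
  list(significant = sig, tStat = emp$t, pRank = pRank,
       fieldBins = emp$bins, centroid = centroid, surrogateT = surT,
       smoothedMap = matrix(emp$sm, gridN, gridN), nSpikes = length(st),
       gridN = gridN)
}

#' Classify an object cell
#'
#' Criterion 1: the object with the highest grand-average cue-period
#' firing rate is the preferred object; a two-sample t-test compares
#' average rates from preferred versus unpreferred cue periods, and the
#' empirical t must exceed the 95th percentile of \code{nSurrogates}
#' surrogate t statistics obtained by shuffling the average rates across
#' trials (re-identifying the preferred object each time). Criterion 2:
#' the time-resolved cue-period firing rates (0.01 s resolution, 0.5 s
#' Gaussian kernel, baseline-corrected against the 1 s before cue onset)
#' must contain a significant positive cluster (one-sided cluster-based
#' permutation test, alpha 0.05) for preferred versus unpreferred
#' trials. Criterion 2 is only evaluated when criterion 1 holds.
#'
#' @param spikes a \linkS4class{SpikeTrain} or numeric spike times.
#' @param trials trial table with cue windows and object_id.
#' @param nSurrogates surrogates for both criteria (default 1001).
#' @param alpha significance level for criterion 1 (default 0.05).
#' @param seed integer seed.
#' @param binS time-resolved resolution (s, default 0.01).
#' @param smoothS Gaussian kernel length (s, default 0.5).
#' @param baselineS baseline period before cue onset (s, default 1).
#' @return list with isObjectCell, preferredObject, tStat, pRank,
#'   criterion1, criterion2, cluster (cluster test result or NULL),
#'   windows (data.frame of significant time intervals).
#' @export
classifyObjectCell <- function(spikes, trials, nSurrogates = 1001L,
                               alpha = 0.05, seed = 1L, binS = 0.01,
                               smoothS = 0.5, baselineS = 1) {
  st <- sort(if (is(spikes, "SpikeTrain")) spikeTimes(spikes) else spikes)
  n <- nrow(trials)
  objIds <- sort(unique(trials$object_id))
  cueDur <- trials$cue_end - trials$cue_start
  avgRate <- vapply(seq_len(n), function(k)
    (findInterval(trials$cue_end[k], st) -
       findInterval(trials$cue_start[k], st)) / cueDur[k], numeric(1))
  empty <- list(isObjectCell = FALSE, preferredObject = NA_integer_,
                tStat = NA_real_, pRank = NA_real_, criterion1 = FALSE,
                criterion2 = FALSE, cluster = NULL,
                windows = data.frame(start_s = numeric(0),
                                     end_s = numeric(0)))
  if (all(avgRate == 0)) return(empty)

  prefAndT <- function(rates) {
    mns <- vapply(objIds, function(o)
      mean(rates[trials$object_id == o]), numeric(1))
    pref <- objIds[which.max(mns)]          # ties: lowest object id
    sel <- trials$object_id == pref
    list(pref = pref, t = pooledT(rates[sel], rates[!sel]))
  }
  emp <- prefAndT(avgRate)
  set.seed(seed)
  surT <- vapply(seq_len(nSurrogates), function(i)
    prefAndT(sample(avgRate))$t, numeric(1))
  okSur <- surT[!is.na(surT)]
  crit1 <- !is.na(emp$t) && length(okSur) > 10L &&
    emp$t > quantile(okSur, 1 - alpha, names = FALSE)
  pRank <- if (is.na(emp$t)) NA_real_ else mean(okSur >= emp$t)
  res <- empty
  res$preferredObject <- emp$pref
  res$tStat <- emp$t
  res$pRank <- pRank
  res$criterion1 <- crit1
  if (!crit1) return(res)

  ## criterion 2: time-resolved baseline-corrected rates
  minCue <- min(cueDur)
  edges <- seq(0, minCue, by = binS)
  ctrs <- edges[-length(edges)] + binS / 2
  rateMat <- t(vapply(seq_len(n), function(k) {
    rel <- st - trials$cue_start[k]
    rel <- rel[rel >= -baselineS - smoothS & rel < minCue + smoothS]
    cnt <- tabulate(findInterval(rel, seq(-baselineS - smoothS,
                                          minCue + smoothS, by = binS)),
                    nbins = round((minCue + baselineS + 2 * smoothS) /
                                    binS)) / binS
    smooth <- smoothGaussian(cnt, smoothS, 1 / binS)
    nBase <- round(baselineS / binS)
    off <- round(smoothS / binS)
    base <- mean(smooth[(off + 1L):(off + nBase)])
    smooth[(off + nBase + 1L):(off + nBase + length(ctrs))] - base
  }, numeric(length(ctrs))))
  sel <- trials$object_id == emp$pref
  if (sum(sel) >= 5L && sum(!sel) >= 5L) {
    clu <- clusterTest(rateMat[sel, , drop = FALSE],
                       rateMat[!sel, , drop = FALSE],
                       test = "two_sample", alternative = "greater",
                       scheme = "label_reassign",
                       nSurrogates = nSurrogates, seed = seed + 1L)
    res$cluster <- clu
    sigCl <- clu$clusters[clu$clusters$significant &
                            clu$clusters$sign > 0, , drop = FALSE]
    res$criterion2 <- nrow(sigCl) > 0L
    if (res$criterion2) {
      wins <- lapply(sigCl$id, function(id) {
        b <- range(which(clu$labels == id))
        data.frame(start_s = ctrs[b[1L]] - binS / 2,
                   end_s = ctrs[b[2L]] + binS / 2)
      })
      res$windows <- do.call(rbind, wins)
    }
  }
  res$isObjectCell <- res$criterion1 && res$criterion2
  res
}

#' Characterise a significant place field
#'
#' Reports the field size as a percentage of valid map bins, the
#' peripherality (percentage of field bins at the edge of the rate map,
#' i.e. touching the grid border or an invalid bin), the number of object
#' locations inside the field together with a surrogate p value from
#' \code{nSurrogates} same-size surrogate fields grown elsewhere on the
#' valid map, and the split-half stability (Pearson correlation between
#' rate maps from the first and second half of the session).
#'
#' @param place result of \code{\link{classifyPlaceCell}}.
#' @param spikes,nav,idle as in \code{\link{classifyPlaceCell}}.
#' @param objects data.frame with object locations (x, y).
#' @param nSurrogates surrogate fields (default 1001).
#' @param seed integer seed.
#' @param arenaRadius arena radius (vu).
#' @return list with sizePct, peripheralityPct, nObjectsInField,
#'   pObjects, stabilityR.
#' @export
fieldCharacteristics <- function(place, spikes, nav, objects, idle = NULL,
                                 nSurrogates = 1001L, seed = 1L,
                                 arenaRadius = 5000) {
  st <- if (is(spikes, "SpikeTrain")) spikeTimes(spikes) else spikes
  gridN <- place$gridN
  if (is.null(idle)) idle <- movementState(nav)$idle
  ctx <- spatialContext(nav, idle, arenaRadius, gridN)
  bins <- place$fieldBins
  stopifnot(length(bins) > 0L)
  nValid <- sum(ctx$valid)
  sizePct <- 100 * length(bins) / nValid
  ## edge bins: touch grid border or an invalid bin
  isEdge <- vapply(bins, function(b) {
    bx <- (b - 1L) %% gridN + 1L; by <- (b - 1L) %/% gridN + 1L
    if (bx == 1L || bx == gridN || by == 1L || by == gridN) return(TRUE)
    nb <- c(b - 1L, b + 1L, b - gridN, b + gridN)
    any(!ctx$valid[nb])
  }, logical(1))
  peripheralityPct <- 100 * mean(isEdge)
  binOf <- function(x, y) {
    ix <- pmin(gridN, pmax(1L, floor((x + arenaRadius) / ctx$binSize) + 1L))
    iy <- pmin(gridN, pmax(1L, floor((y + arenaRadius) / ctx$binSize) + 1L))
    ix + gridN * (iy - 1L)
  }
  objBins <- binOf(objects$x, objects$y)
  nObj <- sum(objBins %in% bins)
  ## surrogate same-size fields: random connected growth on valid bins
  set.seed(seed)
  adj <- function(b) {
    bx <- (b - 1L) %% gridN + 1L; by <- (b - 1L) %/% gridN + 1L
    nb <- c(if (bx > 1L) b - 1L, if (bx < gridN) b + 1L,
            if (by > 1L) b - gridN, if (by < gridN) b + gridN)
    nb[ctx$valid[nb]]
  }
  vIdx <- which(ctx$valid)
  surCounts <- vapply(seq_len(nSurrogates), function(i) {
    seedBin <- vIdx[sample.int(length(vIdx), 1L)]
    fld <- seedBin
    frontier <- adj(seedBin)
    while (length(fld) < length(bins) && length(frontier)) {
      nxt <- frontier[sample.int(length(frontier), 1L)]
      fld <- c(fld, nxt)
      frontier <- setdiff(unique(c(frontier, adj(nxt))), fld)
    }
    sum(objBins %in% fld)
  }, numeric(1))
  pObjects <- mean(surCounts >= nObj)
  ## split-half stability
  halfT <- max(ctx$t10) / 2
  mapHalf <- function(w) {
    c2 <- spatialContext(nav, idle, arenaRadius, gridN, windows = w)
    r <- spikeCounts10(st, c2) / c2$dt
    m <- as.numeric(c2$M %*% r)
    m[c2$occCnt > 0L] <- m[c2$occCnt > 0L] / c2$occCnt[c2$occCnt > 0L]
    sm <- as.numeric(c2$S %*% ifelse(c2$valid, m, 0))
    sm[!c2$valid] <- NA_real_
    sm
  }
  m1 <- mapHalf(matrix(c(0, halfT), 1L))
  m2 <- mapHalf(matrix(c(halfT, Inf), 1L))
  ok <- !is.na(m1) & !is.na(m2)
  stabilityR <- if (sum(ok) > 3L && sd(m1[ok]) > 0 && sd(m2[ok]) > 0)
    cor(m1[ok], m2[ok]) else NA_real_
  list(sizePct = sizePct, peripheralityPct = peripheralityPct,
       nObjectsInField = nObj, pObjects = pObjects,
       stabilityR = stabilityR)
}

#' Classify a conjunctive object-place cell
#'
#' Runs the place-cell analysis once per object, each time restricted to
#' the trials with that object, at the Bonferroni-corrected level
#' alpha / nObjects. The cell is conjunctive iff place tuning is
#' significant for exactly one object. Also reports the mean pairwise
#' Pearson similarity of the per-object rate maps.
#'
#' @inheritParams classifyPlaceCell
#' @param trials trial table.
#' @param alpha family-wise level before Bonferroni division (default
#'   0.05).
#' @return list with isConjunctive, object (id or NA), perObject
#'   (data.frame object_id, tStat, pRank, significant), mapSimilarity.
#' @export
classifyConjunctiveCell <- function(spikes, nav, trials, idle = NULL,
                                    nSurrogates = 1001L, alpha = 0.05,
                                    seed = 1L, arenaRadius = 5000,
                                    gridN = 25L) {
  if (is.null(idle)) idle <- movementState(nav)$idle
  objIds <- sort(unique(trials$object_id))
  alphaB <- alpha / length(objIds)
  maps <- list(); rows <- list()
  for (o in objIds) {
    sel <- trials$object_id == o
    w <- cbind(trials$iti_start[sel], trials$re_encoding_end[sel])
    pc <- tryCatch(
      classifyPlaceCell(spikes, nav, idle, nSurrogates, alphaB,
                        seed = seed + o, arenaRadius = arenaRadius,
                        gridN = gridN, windows = w),
      error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      object_id = o,
      tStat = if (is.null(pc)) NA_real_ else pc$tStat,
      pRank = if (is.null(pc)) NA_real_ else pc$pRank,
      significant = !is.null(pc) && isTRUE(pc$significant))
    maps[[length(maps) + 1L]] <- if (is.null(pc)) NULL else
      as.vector(pc$smoothedMap)
  }
  perObject <- do.call(rbind, rows)
  nSig <- sum(perObject$significant)
  sims <- c()
  for (i in seq_along(maps)) for (j in seq_len(i - 1L)) {
    if (is.null(maps[[i]]) || is.null(maps[[j]])) next
    ok <- !is.na(maps[[i]]) & !is.na(maps[[j]])
    if (sum(ok) > 3L && sd(maps[[i]][ok]) > 0 && sd(maps[[j]][ok]) > 0)
      sims <- c(sims, cor(maps[[i]][ok], maps[[j]][ok]))
  }
  list(isConjunctive = nSig == 1L,
       object = if (nSig == 1L)
         perObject$object_id[perObject$significant] else NA_integer_,
       perObject = perObject,
       mapSimilarity = if (length(sims)) mean(sims) else NA_real_)
}
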