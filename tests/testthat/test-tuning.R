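test_that("rate maps respect occupancy, validity and smoothing", {
  fx <- behFixture()
  rm0 <- computeRateMap(fx$spikes$untuned, fx$nav, fx$idle)
  v <- validBins(rm0)
  ## unvisited corner bins are invalid (circular arena on a square grid)
  expect_false(v[1, 1]); expect_false(v[25, 25])
  expect_false(v[1, 25]); expect_false(v[25, 1])
  ## invalid bins carry NA rates
  expect_true(all(is.na(rateMatrix(rm0)[!v])))
  ## homogeneous unit: smoothed map is flat-ish
  r <- rateMatrix(rm0)[v]
  expect_lt(sd(r) / mean(r), 0.5)
  ## occupancy accounts in seconds
  expect_equal(sum(rm0@occupancy), sum(!fx$idle) / 50, tolerance = 0.05)
})

test_that("a planted Gaussian place field is recovered within one bin", {
  fx <- behFixture()
  pc <- classifyPlaceCell(fx$spikes$placeTuned, fx$nav, fx$idle,
                          nSurrogates = 201, seed = 1)
  expect_true(pc$significant)
  truth <- fx$units$placeTuned$placeCenter
  expect_lt(abs(pc$centroid[1] - truth[1]), 400)
  expect_lt(abs(pc$centroid[2] - truth[2]), 400)
})

test_that("untuned units are not classified and surrogate shifts preserve totals", {
  fx <- behFixture()
  pc0 <- classifyPlaceCell(fx$spikes$untuned, fx$nav, fx$idle,
                           nSurrogates = 201, seed = 2)
  expect_false(pc0$significant)
  ## circular shifts only re-pair rates and positions
  ctx <- ripplecoact:::spatialContext(fx$nav, fx$idle)
  r <- ripplecoact:::spikeCounts10(spikeTimes(fx$spikes$untuned), ctx)
  lag <- 500
  shifted <- r[((seq_along(r) - 1 + lag) %% length(r)) + 1]
  expect_equal(sum(shifted), sum(r))
  expect_equal(sort(shifted), sort(r))
})

test_that("object cells are identified with the correct preferred object", {
  fx <- behFixture()
  oc <- classifyObjectCell(fx$spikes$objectTuned, fx$trials,
                           nSurrogates = 201, seed = 1)
  expect_true(oc$isObjectCell)
  expect_equal(oc$preferredObject, 3)
  expect_gt(nrow(oc$windows), 0L)
  ## untuned unit fails
  oc0 <- classifyObjectCell(fx$spikes$untuned, fx$trials,
                            nSurrogates = 201, seed = 2)
  expect_false(oc0$isObjectCell)
  ## identical rates for all objects: deterministic lowest-id argmax,
  ## never significant
  st <- seq(0.05, fx$duration, by = 0.5)
  tied <- classifyObjectCell(st, fx$trials, nSurrogates = 201, seed = 3)
  expect_equal(tied$preferredObject, 0)
  expect_false(tied$isObjectCell)
})

test_that("field characteristics quantify size, edges, objects and stability", {
  fx <- behFixture()
  pc <- classifyPlaceCell(fx$spikes$placeTuned, fx$nav, fx$idle,
                          nSurrogates = 101, seed = 1)
  ch <- fieldCharacteristics(pc, fx$spikes$placeTuned, fx$nav,
                             fx$objects, fx$idle, nSurrogates = 101,
                             seed = 2)
  expect_gt(ch$sizePct, 0); expect_lte(ch$sizePct, 100)
  expect_gte(ch$peripheralityPct, 0); expect_lte(ch$peripheralityPct, 100)
  expect_gte(ch$pObjects, 0); expect_lte(ch$pObjects, 1)
  ## a stationary tuned cell is stable across halves
  expect_gt(ch$stabilityR, 0)
})

test_that("conjunctive cells require object-specific place tuning", {
  beh <- simulateBehavior(64, seed = 21)
  dur <- ceiling(max(beh$nav$t) + 1)
  idle <- movementState(beh$nav)$idle
  nav <- beh$nav
  ## rate grids on the 50 Hz navigation samples
  poissonTrain <- function(rate50, seed) {
    set.seed(seed)
    cnt <- rpois(length(rate50), rate50 * 0.02)
    sort(rep(nav$t, cnt) + runif(sum(cnt), 0, 0.02))
  }
  near <- (nav$x - 1500)^2 + (nav$y + 1000)^2 < 1100^2
  ## place tuning only during object-3 trials
  sel <- beh$trials$object_id == 3
  inWin <- rep(FALSE, nrow(nav))
  for (i in which(sel))
    inWin <- inWin | (nav$t >= beh$trials$iti_start[i] &
                        nav$t < beh$trials$re_encoding_end[i])
  stConj <- poissonTrain(ifelse(inWin & near, 16, 1.5), seed = 22)
  cj <- classifyConjunctiveCell(stConj, nav, beh$trials, idle,
                                nSurrogates = 1001, seed = 3)
  expect_true(cj$isConjunctive)
  expect_equal(cj$object, 3)
  ## an ordinary place cell (tuned in all trials) is significant for
  ## several objects -> not conjunctive
  stPlace <- poissonTrain(ifelse(near, 16, 1.5), seed = 23)
  cjP <- classifyConjunctiveCell(stPlace, nav, beh$trials, idle,
                                 nSurrogates = 1001, seed = 4)
  expect_false(cjP$isConjunctive)
  expect_gt(sum(cjP$perObject$significant), 1L)
  expect_gt(cjP$mapSimilarity, 0)
  ## an untuned cell is conjunctive for no object
  st0 <- poissonTrain(rep(2.5, nrow(nav)), seed = 24)
  cj0 <- classifyConjunctiveCell(st0, nav, beh$trials, idle,
                                 nSurrogates = 1001, seed = 5)
  expect_false(cj0$isConjunctive)
})
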