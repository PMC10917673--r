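test_that("the coactivity z-score matches its closed-form reference points", {
  ## nAB equal to the independence expectation: z = 0
  expect_equal(coactivityZ(2, 5, 4, 10), 0)
  ## perfect association: z = sqrt(N - 1)
  expect_equal(coactivityZ(5, 5, 5, 10), 3)
  ## partial association, checked against the Pearson identity
  a <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  b <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(coactivityZ(4, 5, 4, 10), cor(a, b) * sqrt(9))
  expect_equal(coactivityZ(4, 5, 4, 10), 2.449, tolerance = 1e-3)
  ## degenerate margins are undefined
  expect_true(is.na(coactivityZ(5, 10, 5, 10)))
  expect_true(is.na(coactivityZ(0, 0, 5, 10)))
})

test_that("bin geometry gives 301 activity and 101 map centres with 95% overlap", {
  act <- activityBinCenters()
  expect_equal(length(act), 301L)
  expect_equal(range(act), c(-0.75, 0.75))
  map <- activityBinCenters(0.25)
  expect_equal(length(map), 101L)
  ## neighbouring 0.1 s bins at 0.005 s step share 95% of their extent
  overlap <- (0.1 - diff(act)[1]) / 0.1
  expect_equal(overlap, 0.95)
})

test_that("ripple-locked activity marks spikes within the 0.1 s bins", {
  peaks <- c(10, 20, 30)
  sp <- c(10.02, 20.2, 29.26)
  a <- rippleLockedActivity(sp, peaks)
  ctr <- a$centers
  expect_equal(dim(a$act), c(3L, 301L))
  ## spike at +0.02 of ripple 1: active in bins with |c - 0.02| <= 0.05
  expect_true(all(a$act[1, abs(ctr - 0.02) <= 0.049] == 1))
  expect_true(all(a$act[1, abs(ctr - 0.02) > 0.051] == 0))
  ## spike at -0.74 of ripple 3 only touches bins centred at or below
  ## -0.69 (bin half width 0.05)
  expect_equal(sum(a$act[3, ctr > -0.685]), 0)
  expect_gt(sum(a$act[3, ctr <= -0.69]), 0)
})

test_that("coactivity maps localise planted lags and respect symmetry", {
  set.seed(3)
  peaks <- sort(runif(250, 10, 590))
  sp <- coactivePairSpikes(peaks, 600, coactive = TRUE, lag = 0.025,
                           seed = 4)
  aA <- rippleLockedActivity(sp$a, peaks)
  aB <- rippleLockedActivity(sp$b, peaks)
  m <- buildCoactivityMap(aA, aB)
  z <- coactivityMatrix(m)
  am <- which(z == max(z, na.rm = TRUE), arr.ind = TRUE)[1, ]
  ## argmax within one bin-width of (0, +0.025)
  expect_lt(abs(m@binCentersA[am[1]]), 0.1)
  expect_lt(abs(m@binCentersB[am[2]] - 0.025), 0.1)
  ## the A-lead relation: argmax off-diagonal j - i ~ +5 steps
  expect_equal(m@binCentersB[am[2]] - m@binCentersA[am[1]], 0.025,
               tolerance = 0.06)
  ## symmetry z(A,B) = t(z(B,A))
  m2 <- buildCoactivityMap(aB, aA)
  expect_equal(coactivityMatrix(m2), t(z))
})

test_that("the Pearson variant equals z / sqrt(N - 1) wherever defined", {
  set.seed(5)
  peaks <- sort(runif(150, 10, 390))
  sp <- coactivePairSpikes(peaks, 400, coactive = TRUE, seed = 6)
  aA <- rippleLockedActivity(sp$a, peaks)
  aB <- rippleLockedActivity(sp$b, peaks)
  m <- buildCoactivityMap(aA, aB)
  pm <- coactivityPearsonMap(aA, aB)
  d <- abs(coactivityMatrix(pm) * sqrt(m@nRipples - 1) -
             coactivityMatrix(m))
  expect_lt(max(d, na.rm = TRUE), 1e-10)
  ## perfect association gives r = 1 on the diagonal bins that hold it
  aSame <- rippleLockedActivity(sp$a, peaks)
  pSame <- coactivityPearsonMap(aSame, aSame)
  expect_equal(max(coactivityMatrix(pSame), na.rm = TRUE), 1)
})

test_that("ripple selection splits follow phase windows and orderings", {
  tr <- syntheticTrials(5, seed = 7)
  ## 10 session ripples, 4 during retrieval; ripple #6 in retrieval
  inRet <- c(3, 5, 6, 8)
  pkRet <- tr$retrieval_start[c(1, 2, 3, 4)] + 1
  other <- tr$iti_start[c(1, 2, 3, 4, 5)] + 0.5
  pk <- sort(c(pkRet, other, tr$iti_start[5] + 1.2))
  rip <- data.frame(t_peak = pk, channel = "ch1")
  sel <- order(pk)
  lateKeep <- selectRipples(rip, tr, "retrieval", "late")
  earlyKeep <- selectRipples(rip, tr, "retrieval", "early")
  allKeep <- selectRipples(rip, tr, "retrieval", "all")
  ## early/late partition the phase ripples
  expect_equal(allKeep, earlyKeep | lateKeep)
  expect_false(any(earlyKeep & lateKeep))
  ## the ripple ranked 6th or later that falls in retrieval is "late"
  rk <- rank(rip$t_peak)
  expect_true(all(rk[lateKeep] > 5))
  ## no ripples in a phase: empty subset
  none <- selectRipples(rip[rip$t_peak < tr$retrieval_start[1], ,
                            drop = FALSE], tr, "retrieval")
  expect_equal(sum(none), 0L)
})

test_that("formation and movement splits partition the phase ripples", {
  fx <- behFixture()
  set.seed(8)
  pk <- sort(runif(200, 0, fx$duration))
  rip <- data.frame(t_peak = pk, channel = "ch1")
  fm <- memoryFormationByObject(fx$trials)
  before <- selectRipples(rip, fx$trials, "retrieval",
                          "before_formation", formation = fm)
  after <- selectRipples(rip, fx$trials, "retrieval", "after_formation",
                         formation = fm)
  phase <- selectRipples(rip, fx$trials, "retrieval", "all")
  expect_false(any(before & after))
  ## formation subsets partition the phase ripples (formation trials are
  ## defined for every object in this fixture)
  expect_true(all(is.finite(fm$formation_trial)))
  expect_equal(phase, before | after)
  mv <- selectRipples(rip, fx$trials, "retrieval", "moving",
                      nav = fx$nav)
  rs <- selectRipples(rip, fx$trials, "retrieval", "resting",
                      nav = fx$nav)
  expect_equal(phase, mv | rs)
  expect_false(any(mv & rs))
})

test_that("pair labelling applies the location-in-field rule", {
  tr <- syntheticTrials(8, seed = 9)
  tr$object_id <- rep(c(0, 1), 4)
  ## field covering the arena centre: bin of (0,0) on the 25x25 grid
  gridN <- 25
  centerBin <- 13 + 25 * 12
  tr$response_x <- rep(c(0, 4000), 4)      # obj0 inside, obj1 outside
  tr$response_y <- 0
  tr$correct_x <- rep(c(4000, 0), 4)       # re-encoding flips the rule
  tr$correct_y <- 0
  oc <- data.frame(unit = c(1, 2), preferred_object = c(0, 1))
  pcl <- list(list(unit = 3, fieldBins = centerBin, gridN = gridN))
  ret <- labelPairs(oc, pcl, tr, "retrieval")
  expect_true(ret[[1]]$associative)        # response of obj0 at centre
  expect_false(ret[[2]]$associative)
  ren <- labelPairs(oc, pcl, tr, "re_encoding")
  expect_false(ren[[1]]$associative)       # correct loc of obj0 at 4000
  expect_true(ren[[2]]$associative)
  ## trial subsets restrict to the preferred object
  expect_true(all(tr$object_id[ret[[1]]$associativeTrials] == 0))
})

test_that("group contrasts flag planted coactivity and stay quiet under the null", {
  set.seed(12)
  peaks <- sort(runif(300, 10, 890))
  assoc <- lapply(1:8, function(i) {
    sp <- coactivePairSpikes(peaks, 900, TRUE, seed = i)
    aA <- rippleLockedActivity(sp$a, peaks)
    aB <- rippleLockedActivity(sp$b, peaks)
    list(map = buildCoactivityMap(aA, aB),
         base = baselineCoactivityMap(aA, aB),
         sur = shiftSurrogateMap(aA, aB, seed = i))
  })
  nonass <- lapply(1:8, function(i) {
    sp <- coactivePairSpikes(peaks, 900, FALSE, seed = 100 + i)
    aA <- rippleLockedActivity(sp$a, peaks)
    aB <- rippleLockedActivity(sp$b, peaks)
    list(map = buildCoactivityMap(aA, aB))
  })
  mA <- lapply(assoc, `[[`, "map")
  r1 <- groupContrast(mA, mode = "vs_chance", nSurrogates = 201,
                      seed = 1)
  r2 <- groupContrast(mA, lapply(assoc, `[[`, "base"),
                      mode = "vs_baseline", nSurrogates = 201, seed = 2)
  r3 <- groupContrast(mA, lapply(nonass, `[[`, "map"),
                      mode = "vs_nonassociative", nSurrogates = 201,
                      seed = 3)
  r4 <- groupContrast(mA, lapply(assoc, `[[`, "sur"),
                      mode = "vs_shift_surrogate", nSurrogates = 201,
                      seed = 4)
  for (r in list(r1, r2, r3, r4))
    expect_true(any(r$clusters$significant))
  ## Bonferroni factor doubles the corrected p
  rB <- groupContrast(mA, mode = "vs_chance", nSurrogates = 201,
                      seed = 1, bonferroniFactor = 2)
  expect_equal(rB$clusters$pCorr,
               pmin(1, r1$clusters$pPlusOne * 2))
  ## exchangeable sets produce no effect
  r0 <- groupContrast(lapply(nonass, `[[`, "map"), mode = "vs_chance",
                      nSurrogates = 201, seed = 5)
  expect_equal(sum(r0$clusters$significant), 0L)
})
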