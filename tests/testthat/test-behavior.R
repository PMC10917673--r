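test_that("memory performance matches the center-object closed form", {
  r <- 5000
  ## drop error 0 -> 1; boundary response for center object -> ~0
  expect_equal(memoryPerformance(c(0, 0), c(0, 0), nSurrogates = 1e5,
                                 seed = 1), 1)
  pEdge <- memoryPerformance(c(0, 0), c(0.985 * r, 0), nSurrogates = 1e5,
                             seed = 1)
  expect_lt(pEdge, 0.05)
  ## center object, d = r/2 -> 1 - (1/2)^2 = 0.75 within Monte-Carlo 3 SE
  n <- 1e6
  p <- memoryPerformance(c(0, 0), c(r / 2, 0), nSurrogates = n, seed = 2)
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(p - 0.75), 3 * se)
})

test_that("memory performance decreases with drop error and grows toward the boundary", {
  ds <- seq(500, 4500, by = 1000)
  ps <- memoryPerformance(matrix(0, length(ds), 2), cbind(ds, 0),
                          nSurrogates = 1e5, seed = 3)
  expect_true(all(diff(ps) < 0))
  ## same drop error scores higher for a peripheral object
  pCenter <- memoryPerformance(c(0, 0), c(2000, 0), nSurrogates = 1e5,
                               seed = 4)
  pEdgeObj <- memoryPerformance(c(4500, 0), c(2500, 0), nSurrogates = 1e5,
                                seed = 4)
  expect_gt(pEdgeObj, pCenter)
})

test_that("learning summaries report the early/late split and trend", {
  tr <- data.frame(performance = seq(0.2, 0.9, length.out = 20))
  ls <- learningSummaries(tr)
  expect_gt(ls$lateMean, ls$earlyMean)
  expect_gt(ls$r, 0.9)
  trc <- data.frame(performance = rep(0.5, 20))
  lsc <- learningSummaries(trc)
  expect_equal(lsc$lateMean - lsc$earlyMean, 0)
  expect_true(is.na(lsc$r))
})

test_that("movement state flags idle runs longer than 2 s only", {
  fs <- 50
  seg <- function(n, x0, dx) x0 + cumsum(rep(dx, n))
  x <- c(seg(100, 0, 10), rep(1000, 160), seg(100, 1000, 10),
         rep(2000, 60), seg(50, 2000, 10))
  nav <- data.frame(t = (seq_along(x) - 1) / fs, x = x, y = 0,
                    heading = 0)
  ms <- movementState(nav)
  expect_true(all(ms$idle[110:250]))         # 3.2 s stationary run
  expect_false(any(ms$idle[370:415]))        # 1.2 s run stays unmasked
  expect_true(all(ms$moving[5:95]))
  expect_true(all(ms$speed >= 0))
})

test_that("memory formation trial matches a brute-force split search", {
  bruteForce <- function(perf) {
    sm <- ripplecoact:::movingAverage(perf, 3L)
    n <- length(perf)
    best <- NA_integer_; bt <- -Inf
    for (i in 2:(n - 1)) {
      tv <- ripplecoact:::pooledT(sm[(i + 1):n], sm[1:i])
      if (!is.na(tv) && tv > bt) { bt <- tv; best <- i }
    }
    best
  }
  set.seed(6)
  ## clean step at an interior trial
  step <- c(rep(0.2, 9), rep(0.8, 9)) + rnorm(18, 0, 0.01)
  mf <- memoryFormationTrial(step)
  expect_equal(mf$trial, bruteForce(step))
  expect_equal(mf$trial, 9)
  ## monotone ramp: interior index near the midpoint
  ramp <- seq(0.1, 0.9, length.out = 21) + rnorm(21, 0, 0.005)
  mfr <- memoryFormationTrial(ramp)
  expect_equal(mfr$trial, bruteForce(ramp))
  expect_gt(mfr$trial, 5); expect_lt(mfr$trial, 17)
  ## n = 4 with a step after trial 2: only candidates are 2 and 3
  s4 <- c(0.1, 0.1, 0.9, 0.9)
  expect_equal(memoryFormationTrial(s4)$trial, 2)
  ## constant series is undefined
  expect_true(is.na(memoryFormationTrial(rep(0.5, 8))$trial))
})
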