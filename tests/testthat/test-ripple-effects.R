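test_that("delta phase locking recovers the planted coupling phase", {
  fx <- lfpFixture()
  rip <- detectRipples(fx$x, fx$fs)
  pl <- deltaPhaseLocking(fx$x, rip$t_peak, fx$fs, nSurrogates = 101,
                          seed = 7)
  expect_lt(abs(pl$meanPhaseDeg - 30), 20)
  expect_lt(pl$rayleighP, 0.01)
  expect_lte(pl$pEmpirical, 0.05)
  expect_equal(length(pl$surrogateZ), 101L)
  ## a single ripple returns its own phase as the mean
  one <- suppressWarnings(
    deltaPhaseLocking(fx$x, rip$t_peak[1L], fx$fs, nSurrogates = 3,
                      seed = 1))
  expect_equal(one$meanPhaseDeg, one$phases[1L] * 180 / pi)
})

test_that("uniformly timed events show no spurious phase locking", {
  set.seed(11)
  lfp <- simulateLfp(120, list(numeric(0)), seed = 12)
  x <- lfpData(lfp)[1, ]
  ps <- replicate(30, {
    pk <- sort(runif(60, 5, 115))
    suppressWarnings(deltaPhaseLocking(x, pk, 2000, nSurrogates = 3,
                                       seed = 1)$rayleighP)
  })
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("ripple cross-correlations localise the imposed lag", {
  hc <- data.frame(t_start = seq(10, 290, by = 3),
                   t_end = seq(10, 290, by = 3) + 0.05)
  ot <- data.frame(t_start = hc$t_start + 0.1, t_end = hc$t_end + 0.1)
  xc <- rippleCrossCorrelation(hc, ot, 300)
  expect_equal(xc$lag[which.max(xc$z)], 0.1, tolerance = 0.02)
  ## identical trains peak at zero lag
  xc0 <- rippleCrossCorrelation(hc, hc, 300)
  expect_equal(xc0$lag[which.max(xc0$z)], 0, tolerance = 0.01)
  ## z-scoring across lags
  expect_lt(abs(mean(xc$z)), 1e-8)
  expect_equal(sd(xc$z), 1, tolerance = 1e-6)
})

test_that("independent event trains yield no significant cross-correlation cluster", {
  set.seed(13)
  hits <- replicate(40, {
    mk <- function() {
      s <- sort(runif(80, 5, 295))
      data.frame(t_start = s, t_end = s + 0.05)
    }
    zs <- t(replicate(8, {
      xc <- rippleCrossCorrelation(mk(), mk(), 300, fs = 200)
      xc$z
    }))
    any(clusterTest(zs, nSurrogates = 101,
                    seed = sample.int(1e6, 1))$clusters$significant)
  })
  expect_lte(mean(hits), 0.15)
})

test_that("ripple-locked firing shows the planted gain at the planted lag", {
  set.seed(14)
  dur <- 300
  peaks <- sort(runif(150, 10, dur - 10))
  base <- sort(runif(600, 0, dur))
  locked <- sort(c(base, peaks + rnorm(150, 0, 0.03)))
  rta <- rippleLockedFiring(locked, peaks, dur)
  at0 <- rta@values[1, which.min(abs(rta@time))]
  far <- rta@values[1, which.min(abs(rta@time + 2))]
  expect_gt(at0, far + 0.5)
  ## lag -0.25 s moves the response before the peak
  early <- sort(c(base, peaks - 0.25 + rnorm(150, 0, 0.03)))
  rtaE <- rippleLockedFiring(early, peaks, dur)
  expect_gt(rtaE@values[1, which.min(abs(rtaE@time + 0.25))],
            rtaE@values[1, which.min(abs(rtaE@time))])
  ## homogeneous unit stays near zero
  rta0 <- rippleLockedFiring(base, peaks, dur)
  expect_lt(max(abs(rta0@values)), 1)
  ## ordering invariance
  rtaP <- rippleLockedFiring(locked, sample(peaks), dur)
  expect_equal(rtaP@values, rta@values)
})

test_that("z-scored rates have zero mean and unit variance before averaging", {
  set.seed(15)
  v <- ripplecoact:::zscoreVec(rnorm(5000, 3, 2))
  expect_lt(abs(mean(v)), 1e-6)
  expect_equal(sd(v), 1, tolerance = 1e-6)
})

test_that("ripple-locked power reflects injected band-limited bursts", {
  fx <- lfpFixture()
  det <- detectIeds(fx$x, fx$fs)
  mask <- maskMatrix(buildArtifactMask(det$events, NULL, length(fx$x),
                                       fx$fs))[1, ]
  pw <- rippleLockedPower(fx$x, fx$rippleTimes, fx$fs, mask = mask)
  fsel <- pw@freq >= 80 & pw@freq <= 140
  at0 <- abs(pw@time) <= 0.05
  off <- abs(pw@time) >= 0.4
  expect_gt(mean(pw@values[fsel, at0], na.rm = TRUE),
            mean(pw@values[fsel, off], na.rm = TRUE) + 0.2)
})

test_that("unit quality metrics follow their definitions", {
  ## regular 10 Hz train has no sub-3 ms intervals
  q <- unitQuality(seq(0, 10, by = 0.1))
  expect_equal(q$isiShortPct, 0)
  ## two spikes 2 ms apart among 100: 1 of 99 intervals is short
  st <- c(seq(0.1, 9.9, by = 0.1), 9.902)
  q2 <- unitQuality(sort(st))
  expect_equal(q2$isiShortPct, 100 / 99, tolerance = 1e-9)
  ## SNR 50 uV peak over 5 uV noise = 10
  q3 <- unitQuality(c(1, 2), meanWaveform = c(5, -50, 10), noiseSd = 5)
  expect_equal(q3$snr, 10)
})
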