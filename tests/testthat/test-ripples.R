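test_that("the detector recovers injected ripples with tight peak timing", {
  fx <- cleanRippleFixture()
  rip <- fx$detected
  d <- vapply(fx$rippleTimes, function(t0) min(abs(rip$t_peak - t0)),
              numeric(1))
  expect_gte(sum(d <= 0.025), length(fx$rippleTimes) - 1L)
  expect_true(all(rip$t_start < rip$t_peak | rip$t_start <= rip$t_peak))
  expect_true(all(rip$duration > 0.02 & rip$duration < 0.5))
  ## events are pairwise non-overlapping
  o <- order(rip$t_start)
  expect_true(all(diff(rip$t_start[o]) > 0) &&
                all(rip$t_end[o][-nrow(rip)] <= rip$t_start[o][-1L]))
})

test_that("60 Hz bursts are rejected by the spectral-peak criterion", {
  fx <- cleanRippleFixture()
  lfp60 <- simulateLfp(60, list(fx$rippleTimes), rippleFreq = 60,
                       seed = 3)
  rip60 <- detectRipples(lfpData(lfp60)[1, ], 2000)
  d <- if (nrow(rip60)) vapply(fx$rippleTimes, function(t0)
    min(abs(rip60$t_peak - t0)), numeric(1)) else numeric(0)
  expect_equal(sum(d <= 0.025), 0L)
})

test_that("masked transients cannot seed events and leave the rest unchanged", {
  fx <- cleanRippleFixture()
  x <- fx$x; fs <- fx$fs
  ## add a huge transient, mask it out: detections must match the clean run
  x2 <- x
  i0 <- round(34.5 * fs)
  x2[i0:(i0 + 200)] <- x2[i0:(i0 + 200)] + 50
  mask <- logical(length(x))
  mask[(i0 - fs):(i0 + 200 + fs)] <- TRUE
  rip2 <- detectRipples(x2, fs, mask)
  expect_false(any(rip2$t_peak >= 33.5 & rip2$t_peak <= 36))
  clean <- fx$detected
  keep <- clean$t_peak < 33 | clean$t_peak > 36.2
  expect_equal(rip2$t_peak, clean$t_peak[keep], tolerance = 0.005)
  ## too little valid data is refused
  expect_error(detectRipples(x, fs, mask = rep(TRUE, length(x))),
               "valid")
  ## constant trace yields no candidates
  expect_equal(nrow(detectRipples(rep(0, 30 * fs), fs)), 0L)
})

test_that("ripple frequency comes from peak-trough delays", {
  fs <- 2000
  seg100 <- sin(2 * pi * 100 * (0:199) / fs)
  expect_equal(rippleProperties(seg100, fs)$frequency, 100)
  seg125 <- sin(2 * pi * 125 * (0:199) / fs)
  expect_equal(rippleProperties(seg125, fs)$frequency, 125)
  ## chirp 85 -> 95 Hz stays inside its band
  t <- (0:399) / fs
  chirp <- sin(2 * pi * (85 * t + (95 - 85) / (2 * 0.2) * t^2))
  f <- rippleProperties(chirp, fs)$frequency
  expect_gte(f, 85); expect_lte(f, 95)
})

test_that("surrogate ripples are uniform over the valid +-60 s window", {
  fs <- 2000; nS <- 200 * fs
  set.seed(5)
  draws <- makeSurrogateRipples(rep(100, 1000), nS, fs, seed = 5)
  expect_true(all(draws >= 40 & draws <= 160))
  ks <- suppressWarnings(stats::ks.test(draws, "punif", 40, 160))
  expect_gt(ks$p.value, 0.01)
  ## masked window forces the whole-session fallback with a warning
  mask <- logical(nS); mask[(38 * fs):(162 * fs + 2)] <- TRUE
  expect_warning(d2 <- makeSurrogateRipples(100, nS, fs, mask, seed = 1),
                 "whole session")
  expect_true(d2 < 38 || d2 > 162)
})

test_that("phase-wise ripple rates recover a constant event rate", {
  tr <- syntheticTrials(40, seed = 3)
  dur <- max(tr$re_encoding_end)
  set.seed(9)
  lambda <- 0.4
  pk <- sort(runif(rpois(1, lambda * dur), 0, dur))
  rr <- rippleRatesByPhase(data.frame(t_peak = pk, channel = "ch1"), tr,
                           nSurrogates = 101, seed = 2)
  expect_equal(colnames(rr$rates),
               c("iti", "cue", "retrieval", "feedback", "re_encoding"))
  for (ph in colnames(rr$rates)) {
    m <- mean(rr$rates[, ph])
    expect_lt(abs(m - lambda), 0.25)
  }
  ## zero ripples: all rates 0, correlations NA
  rr0 <- rippleRatesByPhase(data.frame(t_peak = numeric(0),
                                       channel = character(0)), tr,
                            nSurrogates = 101, seed = 2)
  expect_true(all(rr0$rates == 0))
  expect_true(all(is.na(rr0$correlations$rPerformance)))
})
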