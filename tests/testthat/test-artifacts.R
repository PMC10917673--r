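test_that("a large amplitude transient yields exactly one IED event", {
  fs <- 1000
  set.seed(1)
  x <- rnorm(60 * fs)
  spikeAt <- 30 * fs
  x[spikeAt:(spikeAt + 20)] <- 8 * sd(x)
  det <- detectIeds(x, fs)
  expect_equal(nrow(det$events), 1L)
  expect_true(det$events$start_s <= spikeAt / fs &
                det$events$end_s >= spikeAt / fs)
})

test_that("constant and stationary signals produce no IEDs", {
  fs <- 1000
  expect_warning(det0 <- detectIeds(rep(2, 30 * fs), fs), "constant")
  expect_equal(nrow(det0$events), 0L)
  t <- (0:(30 * fs - 1)) / fs
  detSin <- detectIeds(sin(2 * pi * 10 * t), fs)
  expect_equal(nrow(detSin$events), 0L)
})

test_that("the three IED criteria fire on the synthetic discharges", {
  fx <- lfpFixture()
  det <- detectIeds(fx$x, fx$fs)
  hits <- vapply(fx$iedTimes, function(t0)
    any(det$events$start_s <= t0 & det$events$end_s >= t0), logical(1))
  expect_true(all(hits))
})

test_that("the artifact mask dilates IEDs by 1 s and merges overlaps", {
  fs <- 2000; nS <- 40 * fs
  ied <- data.frame(start_s = 10, end_s = 10)
  m <- buildArtifactMask(ied, NULL, nS, fs)
  v <- maskMatrix(m)[1, ]
  expect_true(all(v[(9 * fs + 1):(11 * fs + 1)]))
  expect_false(v[9 * fs - 10]); expect_false(v[11 * fs + 20])
  ## empty inputs -> all-false mask
  m0 <- buildArtifactMask(ied[0, ], NULL, nS, fs)
  expect_false(any(maskMatrix(m0)))
  ## two IEDs 1.5 s apart merge into one 3.5 s interval
  m2 <- buildArtifactMask(data.frame(start_s = c(10, 11.5),
                                     end_s = c(10, 11.5)), NULL, nS, fs)
  runs <- ripplecoact:::runsFromLogical(maskMatrix(m2)[1, ])
  expect_equal(nrow(runs), 1L)
  expect_equal((runs$end - runs$start) / fs, 3.5, tolerance = 1e-3)
  ## monotonicity: adding an IED never unmasks a sample
  m3 <- buildArtifactMask(data.frame(start_s = c(10, 11.5, 30),
                                     end_s = c(10, 11.5, 30)), NULL, nS,
                          fs)
  expect_true(all(maskMatrix(m3)[maskMatrix(m2)]))
})

test_that("grand-average events require bursts on the majority of channels", {
  rt <- sampleRippleTimes(60, 5, seed = 4)
  lfpAll <- simulateLfp(60, list(rt, rt, rt), seed = 5)
  ev <- detectGrandAverageEvents(grandAverageSignal(lfpAll), 2000)
  hits <- vapply(rt, function(t0)
    any(ev$start_s - 0.02 <= t0 & ev$end_s + 0.02 >= t0), logical(1))
  expect_true(all(hits))
  ## bursts on one channel of ten dilute away
  lfpOne <- simulateLfp(60, c(list(rt), rep(list(numeric(0)), 9)),
                        seed = 6)
  ev2 <- detectGrandAverageEvents(grandAverageSignal(lfpOne), 2000)
  hits2 <- if (nrow(ev2)) vapply(rt, function(t0)
    any(ev2$start_s - 0.02 <= t0 & ev2$end_s + 0.02 >= t0),
    logical(1)) else logical(0)
  expect_equal(sum(hits2), 0L)
  ## zero signal -> none
  expect_equal(nrow(detectGrandAverageEvents(numeric(60 * 2000), 2000)),
               0L)
})

test_that("IED-behaviour statistics detect planted dependence and flag constants", {
  tr <- syntheticTrials(40, seed = 2)
  ## IEDs placed in cue periods of high-performance trials only
  hi <- which(tr$performance > median(tr$performance))
  ev <- data.frame(start_s = tr$cue_start[hi] + 0.5,
                   end_s = tr$cue_start[hi] + 0.6)
  st <- iedBehaviorStats(ev, tr)
  expect_gt(st$rPerformance[st$phase == "cue"], 0.3)
  ## no IEDs at all: constant prevalence -> NA correlations
  st0 <- iedBehaviorStats(ev[0, ], tr)
  expect_true(all(is.na(st0$rPerformance)))
})
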