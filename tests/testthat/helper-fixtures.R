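## Shared fixtures, built once per test run and cached. All fixtures are
## generated in code from fixed seeds; nothing is read from disk.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtureEnv[[name]])) .fixtureEnv[[name]] <- builder()
  .fixtureEnv[[name]]
}

## 48-trial behaviour session with tuned and untuned units
behFixture <- function() fixture("beh", function() {
  beh <- simulateBehavior(48, seed = 11)
  dur <- ceiling(max(beh$nav$t) + 1)
  units <- list(
    objectTuned = list(baseRate = 2, preferredObject = 3, objectGain = 4),
    placeTuned = list(baseRate = 2, placeCenter = c(1500, -1000),
                      fieldWidth = 800, placeGain = 4),
    untuned = list(baseRate = 2))
  spikes <- simulateSpikes(beh$nav, beh$trials, units, dur, seed = 12)
  names(spikes) <- names(units)
  ms <- movementState(beh$nav)
  trials <- addMemoryPerformance(beh$trials, nSurrogates = 2e4, seed = 5)
  list(nav = beh$nav, trials = trials, objects = beh$objects,
       spikes = spikes, idle = ms$idle, duration = dur, units = units)
})

## 120 s LFP with 19 injected ripples and 3 injected IEDs
lfpFixture <- function() fixture("lfp", function() {
  ied <- c(20.3, 55.7, 90.1)
  rt <- sampleRippleTimes(120, 20, couplingPhaseDeg = 30, seed = 2)
  rt <- rt[vapply(rt, function(t0) all(abs(t0 - ied) > 1.6), logical(1))]
  lfp <- simulateLfp(120, list(rt), list(ied), seed = 3)
  x <- lfpData(lfp)[1, ]
  list(lfp = lfp, x = x, fs = samplingRate(lfp), rippleTimes = rt,
       iedTimes = ied)
})

## clean 60 s LFP with 10 injected ripples (no IEDs) plus detection
cleanRippleFixture <- function() fixture("cleanRipples", function() {
  rt <- sampleRippleTimes(60, 10, couplingPhaseDeg = 30, seed = 2)
  lfp <- simulateLfp(60, list(rt), seed = 3)
  x <- lfpData(lfp)[1, ]
  list(x = x, fs = 2000, rippleTimes = rt,
       detected = detectRipples(x, 2000))
})

## simple synthetic trial table with exact phase windows (no navigation)
syntheticTrials <- function(n, seed = 1) {
  set.seed(seed)
  itiD <- runif(n, 3, 5); retD <- runif(n, 8, 16); reD <- runif(n, 5, 10)
  starts <- cumsum(c(0, head(itiD + 2 + retD + 1.5 + reD, -1)))
  data.frame(
    trial_index = seq_len(n), object_id = (seq_len(n) - 1L) %% 8L,
    iti_start = starts, iti_end = starts + itiD,
    cue_start = starts + itiD, cue_end = starts + itiD + 2,
    retrieval_start = starts + itiD + 2,
    retrieval_end = starts + itiD + 2 + retD,
    feedback_start = starts + itiD + 2 + retD,
    feedback_end = starts + itiD + 2 + retD + 1.5,
    re_encoding_start = starts + itiD + 2 + retD + 1.5,
    re_encoding_end = starts + itiD + 2 + retD + 1.5 + reD,
    response_x = 0, response_y = 0, correct_x = 0, correct_y = 0,
    performance = runif(n))
}

## homogeneous Poisson spikes plus optional ripple-locked joint activation
coactivePairSpikes <- function(peaks, durationS, coactive, lag = 0.025,
                               pJoint = 0.35, baseRate = 1, seed = 1) {
  set.seed(seed)
  a <- sort(runif(rpois(1, baseRate * durationS), 0, durationS))
  b <- sort(runif(rpois(1, baseRate * durationS), 0, durationS))
  if (coactive) {
    hit <- runif(length(peaks)) < pJoint
    ta <- peaks[hit] + rnorm(sum(hit), 0, 0.012)
    tb <- ta + lag + rnorm(sum(hit), 0, 0.012)
    a <- sort(c(a, ta)); b <- sort(c(b, tb))
  }
  list(a = a, b = b)
}
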