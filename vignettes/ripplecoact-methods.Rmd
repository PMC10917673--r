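---
title: "Methods: ripple detection and ripple-locked coactivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ripple detection and ripple-locked coactivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ripplecoact)
```

# Scope and data model

`ripplecoact` implements an analysis pipeline for simultaneous intracranial
EEG (2 kHz macroelectrode LFP) and single-neuron recordings acquired while a
participant performs an associative object-location memory task in a
circular virtual arena (~10,000 virtual units in diameter). Each test trial
consists of an inter-trial interval (3-5 s, uniform), a 2 s object cue, a
self-paced retrieval period in which the participant navigates to the
remembered object location, 1.5 s of feedback, and a self-paced re-encoding
period ending at the object's correct location.

The pipeline asks one central question: do object-tuned and place-tuned
neurons that represent the two elements of an object-location association
spike together during hippocampal ripples, and does this coactivity emerge
as learning progresses? The central statistic is a 2D time-by-time map of
pairwise coactivity z-scores around ripple peaks, evaluated with
cluster-based permutation tests.

Because raw patient recordings cannot be redistributed, the package ships a
synthetic-session generator (`simulateBehavior`, `simulateLfp`,
`simulateSpikes`, `simulateSession`) that produces sessions with known
ground truth: injected ripple and IED times, known delta-phase coupling,
known unit tuning, and a controllable ripple-locked coactivation gain for
chosen cell pairs. Every downstream stage is validated by parameter
recovery on these sessions.

# Preprocessing and artifact rejection

LFP channels are bipolar re-referenced between neighbouring contacts of the
same electrode shaft (inner minus outer; the contact ordering within a
shaft is a package convention since either sign convention yields the same
detector behaviour). Line noise is removed with zero-phase band-stop
filters at 50/100/150/200 +- 2 Hz (two-pass 4th-order Butterworth). All
zero-phase filtering uses 1 s of reflect padding to suppress edge
transients. Manual channel rejection is replaced by a variance/flat-line
heuristic (`flagBadChannels`) with an override list; this is a documented
deviation from visual inspection, whose criteria are not enumerable.

Interictal epileptiform discharges (IEDs) are detected per channel on a
0.5 Hz high-pass (5th-order) and 150 Hz low-pass (6th-order) filtered
copy. A sample belongs to an IED if its amplitude or sample-to-sample
gradient deviates more than four interquartile ranges from the respective
median, or if the frequency-wise z-scored natural-log Morlet power
(1-60 Hz, 30 log-spaced frequencies, 7 cycles) summed over frequencies
exceeds its median by four IQR. The power criterion is one-sided above
(discharges raise power); the amplitude and gradient criteria are
two-sided. Flagged runs closer than 50 ms merge into one event so a single
discharge is not fragmented. The exclusion mask dilates every IED by +-1 s
and adds the exact extents of ripple-like events detected in the
grand-average signal (sample-wise channel mean, line-noise filtered),
which flag globally coherent artifacts. Masked samples are set invalid
(NA) everywhere downstream, never zero-filled.

# Ripple detection

The detector band-passes 80-140 Hz (two-pass 4th-order Butterworth), takes
the Hilbert analytic amplitude, and smooths it with a centred 20 ms moving
average (the smoother shape is a package choice; only the window length is
prescribed by the method). Envelope mean and SD are computed over valid
(unmasked) samples only. Candidates are maximal runs above mean + 2 SD;
a candidate becomes a ripple iff its envelope peak exceeds mean + 3 SD,
its duration lies in (20, 500) ms, the band-pass trace contains at least
three strict local maxima and three strict local minima, and the event's
relative power spectrum (30-190 Hz in 2 Hz steps, Morlet 7 cycles,
divided by the whole-recording mean power per frequency) peaks globally
inside 80-140 Hz. The final criterion rejects gamma-band bursts whose
envelope mimics a ripple. The peak time is the band-pass maximum; ripple
frequency is 1 / (2 x mean adjacent peak-trough delay). Candidate extent
is the 2 SD run (not an expansion from the 3 SD peak); with fewer than
10 s of valid data the detector refuses to estimate envelope statistics.

Surrogate ripples draw one random artifact-free timepoint within +-60 s
of each true peak; when a window holds no valid sample the draw falls
back to the whole valid session with a warning.

# Ripple-triggered analyses

*Delta phase locking.* The LFP is filtered 0.5-2 Hz with a two-pass FIR
filter of order 8000 and Hilbert phases are read at the ripple peaks.
Significance uses 1,001 surrogate rounds with shuffled inter-ripple
intervals: the empirical p is 1 - rank of the empirical Rayleigh z among
the surrogate z values, and a two-sample Kuiper test compares empirical
and surrogate phases.

*Cross-regional coupling.* Ripple extents become binary sample trains;
unbiased cross-correlations (lag sums divided by n - |lag|) over +-5 s
are smoothed with a 0.2 s Gaussian kernel and z-scored across lags.

*Ripple-locked power and firing.* Whole-recording Morlet spectrograms
(50 log-spaced frequencies, 1-200 Hz) are z-scored per frequency across
time with IED samples invalid, averaged in +-3 s windows around ripple
peaks, smoothed over time (0.2 s Gaussian) and truncated to +-0.5 s.
Firing rates are 1 ms binned counts smoothed with a 0.2 s Gaussian and
then z-scored across the session (smoothing precedes z-scoring; the
reverse order changes the scale of the z values but not the shape of the
averages). Throughout, a "kernel length" of L seconds means a Gaussian
with total support L and sd L/5 - a documented constant, as only the
length is prescribed.

# Behaviour

Drop errors (response-to-correct Euclidean distance) are transformed into
memory performance by ranking against 10^7 surrogate drop errors between
the trial's correct location and uniform random arena locations (uniform
over the disk via inverse-CDF radius r*sqrt(u)). The strict ">" rank maps
the largest possible error to 0; ties have probability zero for
continuous surrogates. For a centre object the transform has the closed
form 1 - (d/r)^2, which the test-suite verifies by Monte Carlo.

The trial of strongest memory improvement per object smooths the
performance series with a centred 3-trial running average (shrunk at the
edges) and maximises the two-sample t statistic between later and earlier
blocks over interior split points; ties resolve to the earliest index.
Movement is speed > 0.001 vu/s from finite differences of the 50 Hz
trace; idle episodes are runs > 2 s without translation or turning.

# Tuning classification

*Object cells* satisfy two criteria. (1) The preferred object (highest
grand-average cue rate, ties to the lowest id) must yield a two-sample t
(preferred vs unpreferred cue-period average rates) above the 95th
percentile of 1,001 trial-shuffle surrogates that re-identify the
preferred object each round. (2) The time-resolved cue rates (0.01 s
bins, 0.5 s Gaussian kernel, baseline-corrected against the 1 s before
cue onset) must contain a significant positive cluster (one-sided
cluster-based permutation test, alpha 0.05). Criterion 2 is evaluated
only when criterion 1 holds, which also makes large null calibrations
affordable.

*Place cells* use behaviour resampled to 10 Hz, a 25 x 25 grid (bin edge
400 vu), exclusion of idle periods and of bins traversed fewer than
twice, and a 5 x 5 Gaussian kernel (sd 1.5 bins) normalised over valid
bins (plain zero-padded convolution would bleed rate mass out of the
arena edge). Candidate fields are 4-connected components above the 75th
percentile of valid-bin rates (connectivity is configurable; 4 is the
conservative choice); the candidate with the highest summed rate is the
field, and its strength is the pooled t between 10 Hz rates inside vs
outside. Significance compares against 1,001 circular-shift surrogates,
each re-running the entire candidate procedure; shift lags are uniform
over [30 s, session - 30 s] to avoid near-identity shifts. The
inside/outside t-test uses raw 10 Hz samples with membership from the
smoothed map - the natural reading of a sample-level contrast.

*Conjunctive object-place cells* re-run the place analysis once per
object (trials of that object only) and require significance at
alpha/8 for exactly one object.

# Coactivity

For every unit and ripple channel, ripple-locked activity is a binary
matrix over 301 bins (centres -0.75 to 0.75 s, width 0.1 s, step 0.005 s,
95% neighbour overlap): a unit is active in a bin iff it spiked within
+-0.05 s of the bin centre relative to the ripple peak. For a pair of
cells the coactivity z-score across N ripples is

$$z = \frac{n_{AB} - n_A n_B / N}{\sqrt{n_A n_B (N-n_A)(N-n_B) / (N^2 (N-1))}},$$

identically the Pearson correlation of the two binary vectors times
sqrt(N-1); bins with degenerate margins are missing and excluded
bin-wise from group tests. The central 101 x 101 map spans +-0.25 s. The
baseline map is the mean of the two diagonal 101 x 101 sub-blocks of the
301-grid with centres in [-0.75, -0.25] and [0.25, 0.75] s - the
concrete reading of "baseline windows averaged across the two windows"
on the 2D grid.

Condition splits: retrieval ripples lie between retrieval onset and
feedback onset, re-encoding ripples between re-encoding onset and the
next ITI onset; early/late are the first/last n/2 of all session ripples
(ordered per channel; simultaneous peaks across channels are ordered
within channel), then intersected with the phase; formation splits
partition phase ripples by the object-specific trial of strongest
improvement; movement splits use the 50 Hz movement state at the peak.
Associative pairs are those in which, on preferred-object trials, the
response location (retrieval) or the correct location (re-encoding)
falls inside the place field; other preferred-object trials define the
non-associative condition. Non-associative maps are pooled across pairs
(not matched per session).

Group inference uses three one-sided cluster-based permutation tests
(2,001 surrogates): against zero with sign-flipped map subsets, against
paired baseline maps with random subset swapping, and against
non-associative maps with random set reassignment; a variant subtracts a
circular-shift surrogate map (object-cell activity shifted by >= 20 bin
steps with wrap-around) before the test against zero. P values are
reported with both the rank convention (fraction of surrogate maxima at
or above the cluster sum) and the (1 + k)/(1 + n) convention that avoids
exact zeros; Bonferroni factors (e.g. 2 for analysing early and late
ripples) multiply the latter.

# The cluster-permutation engine

`clusterTest` covers 1D and 2D bin grids, one-sample and pooled
two-sample t statistics, one-sided (first-level alpha 0.05, 95th
percentile of surrogate maxima) and two-sided (0.025 at both levels,
negative clusters against the 2.5th percentile of surrogate minima)
tests, and the three surrogate schemes above. The sign-flip unit is the
whole observation (map or curve). Missing values are omitted bin-wise;
bins with fewer than 5 valid observations per set are excluded from
cluster formation. Connected components use union-find labelling
(4-connectivity by default). Calibration tests in the suite verify an
empirical type-I error within [0.02, 0.08] at nominal alpha 0.05.

`rayleighTest` uses z = n R-bar^2 with the standard series
approximation for p; `kuiperTwoSample` reports the raw statistic
V = D+ + D-, the toolbox-compatible k = n1 n2 V, and the asymptotic p
with effective sample size n1 n2 / (n1 + n2).

# The synthetic generator and what it does (not) capture

`simulateBehavior` produces a 50 Hz trace with stationary ITIs (> 2 s,
providing idle episodes), constant-speed polyline paths through a random
waypoint during self-paced phases, log-normal self-paced durations
matched to means of 13.415 s (retrieval) and 7.685 s (re-encoding) - the
distributions are a package choice, as only the means are known - and
response dispersions that decay exponentially per object presentation
(2,400 to 300 vu floor, time constant 2.5 presentations), producing the
early/late learning contrast. `simulateLfp` builds 1/f background
(spectral power slope -1), a deterministic 1 Hz delta oscillation,
Gaussian-windowed ripple bursts (carrier 100 Hz, envelope sd 20 ms)
calibrated to sit near 5 envelope SD so detector recovery is testable
but not trivial, and biphasic IED transients at ~10 IQR. Ripple times
are snapped to the requested delta phase, so bursts are phase-coupled by
construction. `simulateSpikes` draws inhomogeneous Poisson trains on a
20 ms rate grid (baseline 0.5-5 Hz) with multiplicative object-cue and
2D-Gaussian place gains, plus joint ripple-locked spikes for coactive
pairs (probability min(0.9, 0.15 x gain) per ripple, lag applied to the
place cell).

The generator reproduces the statistical structure the pipeline measures
- not biophysics. It has no spike waveforms (sorting is out of scope),
no sharp-wave component, no state-dependent ripple rates, and Poisson
(not bursty) spiking. Passing recovery tests therefore demonstrates the
correctness of the estimators under the stated model, not their
behaviour on pathological recordings.

# Problem sizes and numerical choices

The test-suite and acceptance runs use desk-scale problem sizes chosen
once: 48-trial sessions (about 23 min) for parameter recovery and
place-cell calibration, 104-trial sessions (the mean session length of
the motivating behavioural design) for object-cell calibration, 200 null
units per classifier calibration, 240 s LFP segments with 40 injected
ripples for detector recovery, and 101-201 surrogates in unit tests
versus the full 1,001/2,001 wherever a criterion depends on the
surrogate count. Monte-Carlo memory-performance checks use 10^6
surrogates per point (3 SE tolerance). Engine type-I calibrations run
200 null simulations at reduced grid sizes; validity of the permutation
scheme does not depend on the grid size.

Numerical conventions worth naming: percentiles use R's default linear
interpolation (type 7); envelope statistics are computed on valid
samples only, which the suite verifies against a mask-free clean copy;
t statistics with zero pooled variance are treated as missing; argmax
ties resolve to the lowest index everywhere (preferred objects,
formation trials); and all randomness flows from explicit integer seeds
with no reliance on global state beyond R's RNG, so identical seeds give
bit-identical sessions and statistic tables.

# Known limitations

Channel rejection and IED detection are automated stand-ins for
procedures that involved visual inspection in clinical practice. The
Kuiper p value is asymptotic (exact tables are impractical at these n).
The delta-band FIR kernel comes from a windowed design, whose passband
detail can differ slightly from other design methods at the same
order. Linear mixed models,
repeated-measures ANOVAs over session ensembles, electrode localisation
and spike sorting are out of scope; the package consumes sorted spike
times.
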