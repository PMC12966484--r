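---
title: "Single-trial directed connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial directed connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(corticoflow)
```

## The measurement problem

Single-pulse electrical stimulation of an intracranial electrode evokes,
at connected cortical sites, a stereotyped potential whose presence in the
*average* signal defines an effective connection. Averages, however, hide
the trial-to-trial dynamics of signal flow: a connection can transmit on
every pulse or on one pulse in five, symmetrically or in one preferred
direction, and differently in wake and sleep. `corticoflow` treats the
single trial as the unit of inference and aggregates upward from there.

## Detection model

**Line length.** Response magnitude is the mean absolute successive
difference of the analysis window scaled by sampling rate,
`LL = (Σ |xᵢ − xᵢ₋₁| / N)·(sf/1000)`. It is waveform-agnostic — well
suited to variable evoked morphologies — offset-invariant, and
homogeneous of degree one in the signal. The integration window is 250 ms,
wide enough to include both characteristic deflections of a cortical
response.

**Centroids.** Because one connection can express two contrasted
waveforms, trials are clustered into two centroids by k-means with a
correlation distance. On per-trial z-scored windows the squared Euclidean
distance equals `2(N−1)(1 − ρ)`, so Lloyd iterations on standardized
waveforms minimise correlation distance directly; we use 10 restarts under
a fixed seed (the clustering objective has local optima and the field's
convention is a seeded best-of-restarts). Centroids are plain averages of
the raw member trials. Degenerate inputs (fewer than two distinct
waveforms) return a duplicated centroid with a flag.

**Compound score.** A trial's score is `sign(ρ)·ρ²·LL`, with ρ the best
Pearson correlation against either centroid over lags up to ±10 ms. The
sign convention uses the correlation at the ρ²-maximising lag (an
alternative — the sign of the best signed correlation — can differ in
borderline cases; the maximising-lag convention is applied uniformly to
trials and surrogates, which is what calibration requires). ρ² → 1 means
the trial's energy is fully attributable to the expected waveform, so the
score reads as "line length attributable to the response".

**Surrogate nulls.** All significance is one-sided against statistics
computed *identically* on epochs drawn from non-stimulated baseline data
of the same channel: 400 surrogate epochs for the single-trial test, and,
for the connection-level test, 200 surrogate centroids per real centroid,
each averaging as many baseline epochs as that centroid has member trials.
Member-count matching matters: averaging n epochs suppresses noise line
length roughly by √n, so a pooled null across differently sized clusters
would be dominated by the small cluster and lose sensitivity. Surrogate
onsets are sampled with replacement — a 5-minute baseline cannot host 400
disjoint 600 ms epochs — which trades a little threshold variance for
unbiased sampling. P-values use the add-one estimator (1+k)/(1+n) so they
are never exactly zero. Connection-level decisions are Benjamini–Hochberg
corrected at 0.05 across connections; single-trial decisions are not
corrected (they are rates, not discoveries).

**Latency.** Signaling latency is the time of the first local extremum of
the averaged response that lies inside the span where the sliding 250 ms
line length exceeds the connection's surrogate threshold, and whose
amplitude reaches 2 baseline standard deviations (the prominence rule is
our choice; none is standard). Averages of pure noise usually fail the
line-length gate and return `NA` with a reason code.

**Outliers.** Trials with line length above 4× the connection median are
flagged (automating the visual screen for artifacts and epileptiform
discharges); the default excludes them from all counts, a flag-only mode
retains them.

## Connection metrics

Signaling probability is the significant fraction of delivered
stimulations. The directionality index
`DI = (P_AB − P_BA)/max(P_AB, P_BA)` is antisymmetric and undefined (not
zero) when both probabilities vanish — reporting 0 there would assert
bidirectionality of a silent pair. Connections are classed as local
(< 25 mm, same region and hemisphere), long-range short-latency (≤ 65 ms)
or long-range long-latency (> 65 ms); the latency threshold itself is the
95th percentile of within-region latencies where enough observations
exist. A directed connection is classed by its own latency (not the
pair minimum) — each direction is a separate physiological pathway.

The excitability index is the trapezoidal area under the
stimulation-response curve: magnitudes (line length of the average signal
per intensity level, levels with < 5 trials excluded as incomplete)
normalized by the connection's maximal complete-level magnitude **in
wake**, intensities normalized 0–1 over the 0.2–12 mA protocol range.
Sleep-state curves reuse the wake anchor so state contrasts are
meaningful. Missing intermediate levels are spanned by the trapezoid over
the available levels rather than interpolated to a fixed grid. Surrogate
ExI curves (200, trial counts matched per level, normalized by the same
wake anchor) provide the significance threshold.

## Group statistics

The probability model is a binomial GLM on success counts — not on
fractional probabilities, since each P is a binomial proportion with a
known denominator — with a single combined stimulation-by-response region
factor (cell coding, first pair alphabetically as reference; the formula
has an interaction without main effects, and cell coding matches it
literally) plus continuous distance. McFadden's pseudo-R² is reported
(the flavour is a convention choice and is labelled as such).
Directionality is tested at participant level: probabilities averaged
within participant per region pair, then a two-sided Wilcoxon signed-rank
across participants, BH-corrected across pairs. Sleep modulation uses
percent change `100·(sleep − wake)/wake` on state-complete connections
only, signed-rank per region pair with BH correction per measure; overall
probability agreement between states by Pearson correlation and
Bland–Altman bias; and a mixed-effects model of ΔP with stimulation
region fixed and participant random (REML, Satterthwaite p-values).

## The synthetic generator

The generator emulates the study conditions end to end: 1024 Hz bipolar
recordings; hourly blocks of a ≥ 5-min stimulation-free baseline, a 3 mA
mapping block covering every electrode 3–5 times, and a 14-intensity
(0.2–12 mA, ×3) stimulation-response block; inter-stimulus intervals
Gaussian 4.5 ± 0.2 s truncated at 3 s (the floor keeps epochs disjoint;
none is stated clinically). Background is 1/f-shaped noise plus a 50 Hz
line component; each stimulation adds an 8 ms square artifact of 20×
noise SD on all channels, attenuated as exp(−d/30 mm), so artifact
interpolation is genuinely exercised. Evoked responses are two
opposite-polarity Gaussian-windowed deflections (an early sharp
negative-going component at latency L, a broader opposite one at 2.5 L,
amplitude ratio 0.5) — a minimal parameterisation of the two
characteristic deflections, since the literature shows but does not
parameterise the waveform. Trial-to-trial variability is multiplicative
lognormal amplitude jitter (σ = 0.25) and ±5 ms uniform latency jitter.

Connection ground truth is a per-direction probability and amplitude
*referenced to the 3 mA mapping intensity in wake*; an intensity sigmoid
(normalized to 1 at 3 mA) and per-state gains multiply both probability
(clipped at 1) and amplitude. Defining the gain on both quantities makes a
0.75 NREM gain produce simultaneously the −25% magnitude change and a
reduced transmission rate, which is how state effects present
physiologically. N1 sleep receives the NREM gain in the generator but is
excluded from state contrasts in the analysis (only W, N2–3 as NREM, and
REM are compared). A ground-truth trial table (event × channel × injected
× realised amplitude and latency) makes recovery tests exact, and
identical seeds give bit-identical output.

What the generator does *not* emulate: volume conduction, biophysical
conduction delays, non-stationary background (sleep spindles, slow
waves), epileptiform activity, electrode drift. Passing recovery tests
therefore demonstrates the estimator chain is correct and calibrated
under the stated statistical structure, not that it is robust to every
feature of clinical data.

## Preprocessing choices

Artifacts are removed first, at the native rate, by linear interpolation
over a 12 ms window (midpoint of the 10–15 ms convention). Filtering is
zero-phase (forward–backward) so latencies are unshifted: a 4th-order
0.5–200 Hz Butterworth bandpass and 2nd-order notches at 50 Hz and
harmonics, applied via a compiled direct-form-II-transposed kernel with
odd-reflection edge padding. "Rescaling to a shared amplitude" is
implemented as division by the median absolute deviation of each
channel's stimulation-free baseline — robust to evoked outliers, unlike a
standard deviation. Resampling to 500 Hz (1024→500 is non-integer) is
polyphase. Analysis windows start at T0 + 12 ms so interpolated samples
never enter line-length or correlation windows at lag 0; the offset is
configurable and echoed in outputs.

## Numerical conventions

Quantiles are linear-interpolation (type 7) throughout, so the 95th
percentile of latencies 1…100 ms is 95.05 ms. The 95% surrogate threshold
uses ≥, matching the one-sided definition. Percent intensities map 0.2 mA
→ 0 and 12 mA → 1. All times are seconds from recording start, windows in
milliseconds, distances in millimetres, intensities in milliamperes, and
every analysis constant is echoed into the JSON metadata of each result
directory.

## Calibration and known limitations

On null (unconnected) simulations the single-trial test holds its nominal
5% rate on average across sessions. Two consequences of the surrogate
design are worth stating plainly. First, estimated signaling probability
carries an intrinsic positive offset `≈ (1 − P) × 0.05`: a truly silent
connection reads near 5%, and low-probability connections are inflated
proportionally. This is a property of the published estimator (a
one-sided 5% test applied per trial without correction), not an
implementation artifact, and it is visible in our recovery experiments at
low generative P. Second, because one 400-surrogate threshold serves all
trials of a connection, its sampling variability (the 95th percentile of
400 correlated draws) adds a per-connection component to the variance of
estimated P beyond the binomial term. Both effects shrink as P grows and
largely cancel in the directionality index, which compares two directions
measured against thresholds of the same construction.

Problem sizes in the bundled experiments (e.g. 300 trials per connection
for recovery, 13 synthetic participants with 8 trials per state for the
sleep analysis, 20 replicates) are the package's choices for a
desk-scale, fully reproducible validation; clinical trial counts (a
median near 288 trials per connection accumulated over days) arise from
ward logistics, not from the method.
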