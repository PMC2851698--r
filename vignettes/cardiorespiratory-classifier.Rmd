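---
title: "Classifying voluntary and involuntary electrodermal reactions from cardiorespiratory signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying voluntary and involuntary electrodermal reactions from cardiorespiratory signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edrclass)
```

## The problem and the model

A phasic electrodermal reaction (EDR) — a transient rise in skin
conductance of more than 0.05 μS within five seconds — can originate from a
deliberate mental act, a deep inspiration, an external startling stimulus,
or spontaneous sympathetic fluctuation. `edrclass` classifies each detected
reaction as *voluntary* (mental imagery, deep inspiration) or *involuntary*
(startle, non-specific) using two companion signals recorded at the same
256-Hz sampling rate: respiration from a belt and blood volume pulse (BVP)
from a photoplethysmograph.

The pipeline is three filters applied in sequence.

**Detection.** The tonic EDA gradient is predominantly negative; at the
initiation of a reaction it turns sharply positive. Over non-overlapping
one-second windows the detector computes the mean first difference
$C$ (μS/sample; algebraically the net rise across the window divided by the
number of steps) and flags windows with $C \ge D$. Consecutive flagged
windows merge into one event whose onset is the first flagged window's
start. Events are validated by a trough-to-peak amplitude floor: the
largest rise from a running minimum over the flagged span (begun one window
early, so the response's foot is included) and the five seconds that follow
must reach `min_edr_amp_uS` (default 0.02 μS, the lenient visual-scoring
definition; the stricter 0.05 μS working definition of an EDR is used as
the ground-truth floor when scoring the detector on synthetic data — both
are exposed in `detector_config()` / `detection_performance()` because the
field uses both).

**Respiration filter.** The respiration length line over a five-second
window,
$\mathrm{RLL} = \sum_i \sqrt{\delta^2 + (r_{i+1} - r_i)^2}$ with
$\delta = 1/f$ the sampling interval, is the arc length of the sampled belt
trace in the (time, amplitude) plane; it grows with both breathing rate and
amplitude. Because a single RLL value depends on where measurement starts
on the curvilinear trace, it is recomputed ten more times at 0.1-s offsets
and averaged — all eleven windows enter the average (the description of the
procedure is ambiguous between ten and eleven; averaging everything that
was computed is the reading adopted). Thresholds
$\psi = \mu_{trim} \pm 3\sigma_{trim}$ come from 5% trimmed statistics of
baseline `rll_avg`. Two numerical choices matter here. First, the trimmed
SD of a Gaussian sample is biased low (two-sided 5% trimming shrinks it to
about $0.79\sigma$), so it is rescaled by the usual normal-consistency
factor; without this the nominal $3\sigma$ band is really a $2.4\sigma$
band and the false-flag rate on stationary breathing is several times the
intended $\le 1\%$. Second, the band is two-sided — suppressed breathing
shortens the length line just as a deep inspiration lengthens it — and the
comparison is strict (`rll_avg` exactly on the boundary is not flagged).
If the trimmed SD is exactly zero the threshold degenerates; a warning is
raised and the band widened by machine epsilon. A reaction is attributed to
respiration when a flagged second (whose flag covers the 5-s window it
opens) overlaps the five seconds preceding the EDR onset — the lookback
absorbs the EDR latency after an inspiration.

**Cardiorespiratory filter.** At rest, heart rate fluctuates at the
respiratory frequency (respiratory sinus arrhythmia, RSA); the classifier's
premise is a momentary lapse of that coupling before voluntary reactions.
Instantaneous heart rate is inverted from BVP interbeat intervals: pulse
peaks are local maxima at least 0.33 s apart (rates up to ~180 bpm) with
prominence at least a quarter of the signal's interquartile range; each
interval's rate 60/IBI is placed at the interval midpoint, linearly
interpolated to the sampling grid and lightly smoothed (0.5-s moving
average) — midpoint placement matters, as holding the rate over the beat
lags the true profile by half a beat. Relative heart-rate change
$HR'(t) = (HR(t+\delta) - HR(t))/HR(t)$ (the forward relative difference;
the companion respiration series is the plain first difference) is z-scored
over the whole trial along with $R'(t)$, and their windowed
cross-correlation is computed in two-second windows with 50% overlap
(window $m$ spans $[m-1, m+1]$ s, $M = \lceil T - \delta \rceil - 1$
windows). The cross-correlation statement admits two readings — a pointwise
product series or a lag correlation; the lag-correlation reading is
implemented, as it is the canonical meaning of "cross-correlation between
two signals" and produces one curve per window: lags span ±1 s on the
sampling grid (513 points at 256 Hz), each value a sum of products divided
by the overlap count at that lag.

Each curve is represented by a finite Fourier sum with $K = 512$ requested
harmonics. A 513-point curve can carry at most
$\lfloor (n-1)/2 \rfloor = 256$ harmonics, so the requested $K$ is capped
at the curve's capacity — at the cap the representation is exact (the
tests assert reconstruction to 1e-8) and the fitted curves equal the raw
curves; with smaller $K$ the fit is a spectral truncation. The fitted
coefficient vectors average into $\bar W$, giving the mean curve $M(t)$;
$S(t)$ is the pointwise sample SD of the fitted curves about $M(t)$, floored
at 1e-12 (with a warning) when curves are identical.

**Prediction bands.** The band constant $\theta$ is calibrated by
bootstrap: each of $N_B = 1000$ resamples draws $M - 1$ curves with
replacement and recomputes mean and variability curves $M_i, S_i$; the
standardized deviation of a curve from these is
$D(t) = (\hat C(t) - M_i(t))/S_i(t)$. Two calibrations are offered. The
default takes, per resample, the max-over-time deviation of **one curve
drawn at random from the full sample** (a predictive draw), and sets
$\theta$ to the empirical $1-\alpha$ quantile (order statistic, rounded
up — the conservative "higher" type) of these $N_B$ maxima: a single new
resting curve then falls inside $U, L = M \pm \theta S$ with probability
about $1-\alpha$, which is the guarantee the membership test of a single
2-s segment needs, and the one the package's coverage checks verify.
`fit_resting_model(family_wise = TRUE)` instead takes the maximum over all
$M-1$ resampled curves jointly, bounding the worst curve of a whole
resample; this family-wise variant is far more conservative for
single-segment testing (a single held-out curve is covered essentially
always) and is provided because descriptions of this construction vary on
exactly this point. A segment's membership statistic is
$D(s) = (Q(s) - M(s))/S(s)$ with $Q$ the Fourier fit of its curve; the
indicator is raised when $\max_s |D(s)| > \theta$, and an EDR whose 3-s
analysis segment $[{\rm onset}-2, {\rm onset}+1]$ (chosen to bridge the
0.25–2-s cardiac and 1.3–2.5-s electrodermal response latencies) overlaps
any raised window is classified voluntary.

The resting model should be fitted on at least 25 curves (warning below,
error below 5) from at least 30 s of rest; the package follows per-session
pooling — all the session's quiet-rest trials feed one model. Pooling is
not cosmetic: a single two-minute trial can realize a slightly narrower or
wider curve population than the process average, and bands fitted on it
inherit that bias; pooling four rest trials stabilizes both $S(t)$ and
$\theta$ (the acceptance check fits on four pooled trials, ~516 curves).

## The synthetic generator

`simulate_recording()` produces the three channels from a scenario (block
A–D mirroring the experimental protocol: quiet rest 130 s, music imagery
220 s with 20-s alternating rest/imagery periods, with or without five
scheduled auditory startles and a continuous-background-noise condition)
and a physiology object. Defaults, chosen once as resting adult physiology:

* respiration: 0.25 Hz sinusoid, amplitude 1 (belt units arbitrary), with
  smooth multiplicative jitter (8% frequency, 10% amplitude, ~3-s
  correlation time); a deep breath is a 2.5× amplitude, 0.6× frequency
  excursion over 8 s;
* heart rate: 70 bpm + 5 bpm × the respiratory oscillation (RSA) + 0.3 bpm
  slow noise; BVP is a smooth pulse train (`exp(k(cos 2πΦ − 1))`, k = 3)
  whose phase integrates the rate;
* EDA: tonic 2 μS drifting at −0.001 μS/s plus bi-exponential reactions
  (rise 1.5 s, decay 4 s time constants, unit-normalized peak), amplitudes
  uniform on [0.05, 1] μS, onset latency uniform on [1.3, 2.5] s after the
  stimulus; events closer than 5 s are thinned (near-coincident sudomotor
  responses superpose and are scored as one);
* sensor noise: band-limited (0.25-s moving average) with SDs 0.001 μS
  (EDA), 0.005 (respiration), 0.01 (BVP). All slow modulations are
  mean-centred and doubly smoothed so their sample-scale increments stay
  far below the physiological signals — a rough envelope leaks into the
  respiration arc length and the EDA first difference, which no belt or
  electrode drifts fast enough to do.

The voluntary/involuntary distinction is implemented purely as the
presence or absence of RSA decorrelation: before each voluntary reaction,
over a window starting 0.25–2 s before the EDR onset and ending 1 s after
it, the RSA term crossfades (0.25-s cosine ramps) into an independent
smooth fluctuation of matched power (`decorr_strength` scales the blend; at
0 a voluntary event is physiologically indistinguishable from rest). A
sinusoidal replacement was rejected: over a 2-s window any two
low-frequency oscillations correlate substantially, so a sinusoid changes
the lag-curve shape without actually lapsing the zero-lag coupling the
premise describes. Startles keep the coupling and add only a small
respiration-independent rate transient (default 1.5 bpm over 3 s) whose
magnitude is a parameter, since published startle heart-rate transients are
not quantified precisely enough to fix it. Spontaneous reactions occur at
7.5/min. Every generated event is annotated with its stimulus time, actual
EDR onset, drawn amplitude, and the realised noiseless rise within 5 s — in
compound traces superposition on a preceding decay can cancel a rise, and
an event whose realised rise never reaches the defining 0.05 μS is not a
detectable EDR in the signal.

What the generator does **not** emulate: pulse-waveform morphology changes,
motion and electrode artifacts, apnea or irregular breathing patterns
beyond deep breaths, startle habituation, circadian drifts, and any
participant-to-participant variability. Passing tests therefore demonstrate
the statistical machinery under the stated assumptions, not performance on
recorded human data.

## Threshold calibration

`calibrate_threshold()` sweeps a logarithmic grid (default 10⁻⁶–10⁻², 40
points/decade) and scores per-window sensitivity + specificity against
annotated rising limbs ($[\mathrm{onset}, \mathrm{onset} + t_{peak}]$,
$t_{peak} \approx 2.35$ s for the default kernel); ties break toward the
larger threshold (fewer false positives). Windows overlapping the limbs of
sub-threshold (realised rise < 0.05 μS) events are scored neither positive
nor negative. The calibration signal, `make_calibration_recording()`, is a
quiet-rest trial with exactly five reactions of graded amplitude
(0.05–1 μS) at staggered sub-second onset phases: because the window
statistic is a *net* rise, the window values an event contributes depend on
where its onset falls within the one-second grid, and the graded, staggered
design guarantees the sweep sees statistics spanning the whole detectable
range, so the tie-break lands just below the smallest reliably detectable
window value rather than against an arbitrary large reaction. Detector
scoring (`detection_performance()`) is event-level for sensitivity (a true
EDR is hit when a validated detection's flagged span overlaps its rising
limb) and window-level for specificity, with guard collars of one window
after and one window plus the 5-s validation horizon before each limb —
a window flagged just before a rise validates *through* that rise and is
not evidence of a false-positive mechanism. Purely per-window scoring of
100%/100% is unattainable in principle: a window overlapping the last
sliver of a rise has a net first difference indistinguishable from noise.

## Known limitations

* Reactions that creep just over the 0.05 μS definition while riding a
  large preceding decay can have rise *rates* at the noise floor; a
  windowed first-difference detector (at any threshold) cannot see them.
  On the synthetic suite this affects roughly one event in a hundred on
  some seeds.
* $\theta$ fitted on ~100 curves carries seed-to-seed estimation spread of
  a few percentage points in realized coverage; per-session pooling
  mitigates but does not remove it.
* The indicator tests overlapping windows, so false positives cluster; the
  per-event false-positive rate is somewhat above the per-window α.
* The compliance assumption of the evaluation (rest ⇒ involuntary, imagery
  ⇒ voluntary) mislabels spontaneous reactions that occur during imagery
  periods; the generator stores event-level truth so this penalty can be
  quantified, and `evaluate_events()` works from whichever truth labels the
  caller attaches.

## What the checks compute

The test suite verifies, among others: exact brute-force equivalence of the
window statistic, arc length, trimmed moments, Fourier fit and chi-squared
test; band ordering $U \ge M \ge L$ and $\theta \ge 0$; detector
monotonicity in $D$ and shift equivariance; RLL translation invariance and
amplitude monotonicity; prediction-band coverage of held-out resting curves
(95% ± 3 at α = 0.05, model pooled over four rest trials, 1000 bootstrap
resamples, ≥500 held-out curves); perfect detector sensitivity/specificity
on the clean fixture suite at the calibrated threshold; and an end-to-end
parameter-recovery curve — classification accuracy on a balanced 40-event
benchmark rises monotonically with decorrelation strength, from the 50%
prevalence baseline at strength 0 to above 90% at full strength.
`scripts/acceptance.R` recomputes the coverage and detector numbers from
scratch for any seed. Problem sizes (130–510-s recordings, 100–516 fit
curves, 1000 resamples, 8-recording suites) were chosen as the smallest at
which these statistical checks are stable.
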