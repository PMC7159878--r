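---
title: "Models and methods: chronometry of action-stopping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: chronometry of action-stopping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopcascade)
```

# The problem

In the stop-signal task a participant initiates a speeded manual response to
a Go cue and, on a minority of trials, tries to abort it when a Stop signal
appears after a staircased stop-signal delay (SSD). The latency of the
latent stopping process (SSRT) is classically estimated from keypresses and
the go-RT distribution, but a keypress is the *end* of a motor cascade:
muscle activity precedes it by tens of milliseconds, and the response
becomes mechanically unstoppable some time before the key actually closes.
`stopcascade` implements a set of measures that place the moment of stopping
at successive levels of that cascade:

* **CancelTime** — on Successful Stop trials with a small ("partial") EMG
  burst, the latency from the Stop signal to the moment the trial-by-trial
  EMG envelope starts to decline;
* **SSRT_Beh / SSRT_EMG** — integration-method SSRT computed from
  keypresses, or from EMG onsets with partial-EMG trials recoded as
  responses (per SSD, then averaged);
* **SSRT_BEESTS** — the posterior mean stopping latency of a hierarchical
  Bayesian ex-Gaussian race model with trigger failures;
* **BurstTime** — the envelope-peak time of frontal beta bursts between the
  Stop signal and SSRT;
* **MEP suppression chronometry** — when motor-evoked potentials in a
  task-irrelevant muscle become suppressed, in absolute time and relative
  to the single-trial EMG decline.

Every stage runs against a synthetic-data generator with complete ground
truth, so the whole chain is testable without recordings.

# The generative race

A trial's Go process finishes at an ex-Gaussian time `G ~ exG(mu_go,
sigma_go, tau_go)` (seconds); finishing means *reaching the point of no
return*: the EMG envelope crosses the press threshold. On stop trials a
Stop process starts at the SSD; with probability `p_tf` it is never
triggered, otherwise it finishes at `S ~ exG(mu_stop, sigma_stop,
tau_stop)` centrally and silences the muscle one corticospinal conduction
time (default 23 ms) later. The trial outcomes follow mechanically:

* keypress iff the crossing precedes both the muscle cancellation and the
  1 s deadline; the keypress lands `ballistic_ms + electromech_ms` after
  the crossing (defaults 35 + 25 ms — the un-cancellable mechanical stage
  plus device delay, 60 ms total);
* a *partial* EMG burst iff EMG drive began before the cancellation but the
  crossing did not: the width of that window is the envelope's
  rise-to-threshold lag (`rise_lag_ms()`, ~79 ms at the defaults), which is
  what makes roughly half of successful stops carry a partial burst;
* otherwise a Successful Stop with no EMG.

Because both post-crossing delays sit after the race is decided, SSRT
computed from keypresses exceeds SSRT computed from EMG events by exactly
that delay in expectation — the property exploited by the ballistic-stage
sweep (`sweep_ballistic()`), which asks how long the un-cancellable stage
must be for the simulated gap to reach an observed one.

Default race parameters were chosen once so that the simulated task
reproduces the behavioral regime of the studies the package emulates: go
keypress RT mean ~483 ms (SD ~95), P(respond|stop) ~0.5 under the
+/-50 ms staircase, mean SSD ~250 ms, muscle cancellation ~160 ms after the
Stop signal, ~4% trigger failures, partial bursts on ~half of successful
stops with amplitudes around half of keypress bursts.

# EMG synthesis and the single-trial pipeline

**Envelope.** A burst rises as a gamma-like function `r(u) = u^2 exp(2(1-u))`
over `emg_rise_ms` (100 ms) to `emg_peak_mv` (1 mV) and decays
exponentially (`emg_decay_ms`, 19 ms). Cancellation truncates the drive:
the envelope decays from the level attained at the cancellation time, so
partial amplitude grows with SSD (later cancellation = further up the
rise). The press threshold (0.95 mV) fixes the rise-to-threshold lag.

**Carrier and noise.** The burst is rendered as the envelope modulating a
140 Hz sinusoidal carrier with random phase, plus Gaussian baseline noise
(10 µV RMS, a typical surface-EMG noise floor) and a 60 Hz line component
(50 µV). Motor-unit interference structure is deliberately not modelled
(out of scope); a coherent carrier keeps the rectified-RMS trace of a
single trial smooth, so the landmark rules below measure the envelope
rather than carrier statistics. The carrier frequency is a multiple of
10 Hz so that an integer number of rectified-carrier periods fits the
50 ms RMS window, which removes ripple from the RMS trace.

**Decay constant.** The decline landmark is detected on a *centered* 50 ms
RMS trace, whose maximum sits where the envelope's rise half a window
before the truncation balances its decay half a window after. The default
`emg_decay_ms = 19` satisfies that balance at the median truncation lag,
so detected declines track injected cancellations with ~3 ms bias and
~8 ms median absolute error at the default noise level; both numbers are
recomputed by the test suite.

**Detection chain** (all parameters in `detection_params()`): 4th-order
Butterworth band-stop notches at 60/120/180 Hz applied forward-backward;
full-wave rectification; centered 50 ms RMS with shrink-to-valid windows at
the epoch edges. A burst is any excursion above the fixation-to-Go baseline
mean + 8 SD (the first 100 ms of the baseline are excluded from the
statistics to guard against the zero-phase filters' edge transient; a
zero-variance baseline falls back to mean + epsilon, flagged). The onset is
found by backtracking from the peak to the latest point below 20% of the
peak for 5 consecutive ms; the decline is the first strictly decreasing
5 ms run after the peak; the offset mirrors the onset rule forward
(non-normative: no rule is stated for it in the source method). CancelTime
= decline - Stop time on partial trials, with a 50 ms floor and a
Q3 + 1.5 IQR upper cutoff applied per participant; landmark distributions
additionally get the two-sided 1.5 IQR rule.

# SSRT estimators

`ssrt_integration()` uses the nth ordered go RT with `n = ceiling(p * N)`
and replaces omissions by the maximum RT (consensus practice; the source
method cites the standard integration approach without detail).
`ssrt_emg()` recodes partial-EMG trials as responses, uses Correct-Go EMG
onsets as the finishing-time distribution, estimates SSRT at every SSD
with at least 5 stop trials and a non-degenerate response probability, and
averages the per-SSD estimates unweighted.

Two sampling properties matter when interpreting simulations. First, the
per-SSD estimates at extreme response probabilities (near 0 or 1) are
biased upward by quantile estimation in the skewed tails; the 5-trial
minimum removes most such levels at realistic session sizes, and at a
10,000-trial session both estimators are unbiased to ~1 ms. Second, the
*difference* between the two estimators in a single 10,000-trial session
has a Monte-Carlo SD around 10 ms, so equivalence of the two estimators is
asserted on the mean over many replicate sessions, not per session.

`fit_weibull()` fits the cumulative Weibull inhibition function
`w(t) = gamma - (gamma - delta) exp(-(t/alpha)^beta)` by bounded weighted
nonlinear least squares (start values from the data range; weights = trial
counts).

# The hierarchical race model

The likelihood treats a Correct Go RT as `f_G(t)`; a go omission as
`S_G(deadline)`; a Failed Stop RT at SSD `d` as
`f_G(t) (p_tf + (1 - p_tf)(1 - F_S(t - d)))`; and a Successful Stop as the
deadline-aware inhibition probability, whose integral is evaluated by
fixed Gauss-Legendre quadrature (64 nodes; deterministic, ~1e-8 accurate,
and equal to the sampling-based censoring construction in expectation).
The ex-Gaussian mean is `mu + tau` and its variance `sigma^2 + tau^2`.

Priors are bounded uniforms (`mu`: U(0,2); `sigma`, `tau`: U(0,0.5);
`p_tf`: U(0,1), seconds), with truncated-normal group distributions over
individual parameters and uniform hyperpriors on the group means (same
bounds) and SDs (0 to the bound width). Sampling is Metropolis-within-Gibbs
with per-parameter Gaussian random walks adapted toward ~30% acceptance
during burn-in, plus two families of opposite-sign "ridge" proposals
(mu/tau and sigma/tau, at the individual level and jointly with the group
mean) that traverse the posterior's slow trade-off directions; without
them the mu_stop/tau_stop ridge mixes an order of magnitude slower.
Convergence is the split-chain Gelman-Rubin statistic with the usual
Rhat < 1.1 rule. Default runs here use 2-3 chains with a few hundred
burn-in and ~1000 kept sweeps — smaller than a publication-grade run of
5000 x 5 thinned samples, chosen so a full cohort fit completes in minutes;
Rhat is always reported and flags insufficient runs.

**Identifiability.** With a few hundred trials per participant (of which
only a quarter are stop trials) the stop-side composite quantities — above
all the mean `mu_stop + tau_stop`, the model's SSRT — are well recovered,
but the *individual* split of the stop distribution into `sigma_stop` vs
`tau_stop`, and a trigger-failure rate of a few percent, sit on nearly
flat likelihood ridges: simulated-data checks in the test suite show the
likelihood at the drifted component values exceeding the likelihood at the
generating values, with the composite mean preserved, while a single
participant with ten thousand trials recovers every parameter. Component-
level stop-shape and trigger-failure estimates at realistic session sizes
should therefore be read with caution; this is a property of the design
(censored stop finishes), not of the sampler, and the corresponding
recovery checks in the test suite document it by failing at the strict 10%
mark while the SSRT summary passes.

# Beta bursts

`morlet_tf()` uses Morlet wavelets with 3 cycles at the lowest frequency,
increasing by 0.5 per 1 Hz step, normalized to unit gain at their center
frequency. The frontal-component rule (`select_peak_beta()`) accepts a
signal only if mean 13-30 Hz power from Stop signal to SSRT_Beh exceeds
the pre-Go baseline (-1000 to -500 ms), and returns the beta frequency
with maximal Stop-window power. ICA decomposition and dipole fitting are
not part of the package: the module consumes an already spatially filtered
single channel (the surrogate generator provides one directly), and only
the power rule — the part of component selection that is algorithmic
rather than visual — is implemented.

`detect_bursts()` filters at the peak beta frequency with a
frequency-domain Gaussian window (FWHM 5 Hz), takes the Hilbert envelope
(the same FFT supplies the analytic signal), pools envelope amplitudes from
the 500-1000 ms post-alignment window of all trials, and thresholds at
median + 1.5 SD (detection) and median + 1 SD (burst width); "SD" is the
plain standard deviation of the pooled amplitude distribution, implemented
literally as stated even though it mixes a robust location with a
non-robust scale. BurstTime is the envelope peak of each supra-width run
containing a supra-detection sample; a burst belongs to a window if its
BurstTime falls inside it. Burst % binary-codes supra-width samples across
trials. The surrogate generator injects one Gaussian-windowed burst
(~3 cycles FWHM) per triggered Successful Stop trial at
`muscle_cancel - beta_lead_ms` over 1/f background; because every such
trial receives a burst at high SNR, surrogate burst percentages are far
higher than scalp-EEG values — the generator validates detection and
timing, not EEG signal-to-noise.

# MEP chronometry

QC applies the two stated rules: pre-TMS EMG < 0.05 mV in the 90 ms before
the pulse, and amplitude within the group mean +/- 1.5 IQR per time-point x
trial-type cell (skipped, flagged, below 4 trials — and note the rule's
non-robust mean makes it fragile in small contaminated cells). Amplitudes
are expressed as % of the mean ITI amplitude collapsed across trial types.
The trial-by-trial analysis subtracts the EMG decline time from the TMS
time, bins into half-open 30 ms windows labeled by lower edge over
[-90, 60), and reports bins with >= 50 pooled trials. MEP amplitude in the
generator is lognormal around 0.4 mV with a suppression factor of 0.6
applied to Successful Stop trials stimulated at or after 140 ms
post-Stop. The conduction-time onset rule (first point above the
pre-stimulus mean + 3 SD sustained 1 ms, minimum across 10 trials) is an
automated stand-in for the visual inspection used in the source protocol,
and is documented as non-normative.

# The permutation test

The across-participant correlation between mean BurstTime and mean
CancelTime could be inflated by each participant's Stop window simply
being longer or shorter. The null therefore redraws BurstTimes uniformly
on (0, SSRT_Beh) per participant — one draw per observed burst, preserving
each participant's averaging noise (the alternative, one draw per
participant, is exposed as an option) — for 3000 iterations, recomputing
the correlation each time; `p = (1 + #{r >= r_obs}) / (1 + n_iter)`
(add-one convention, so p is never exactly 0). Calibration under the null
and power under a lead-lag coupling are both exercised in the tests.

# Problem sizes and reproducibility

All generators and the sampler take explicit integer seeds and restore the
caller's RNG state; identical (config, seed) gives bit-identical output.
The shipped analyses use a 12-participant x 600-trial cohort; the test
suite uses 1000 injected partial trials for CancelTime recovery, 50
replicate 10,000-trial sessions for SSRT equivalence, one million races
per SSD for the likelihood oracle, a 20 x 600 cohort for hierarchical
recovery, and 500 replicate cohorts for permutation calibration. These
sizes were chosen so each property is measured well inside its stated
tolerance while a full run stays in the minutes range.

# What the synthetic data does not show

The generator emulates the *structure* of the recorded studies — task
schedule, race logic, burst truncation, surrogate beta timing, MEP
suppression — with clean, known parameters. It does not emulate motor-unit
physiology, EMG crosstalk between muscles, real EEG signal-to-noise or
topography, TMS coil variability, or violations of race independence
(beyond trigger failures). Passing tests therefore demonstrate that the
estimators recover what they are defined to recover under the model's own
assumptions, not that those assumptions hold in any particular recording.
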