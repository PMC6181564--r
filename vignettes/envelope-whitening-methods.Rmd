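---
title: "Methods: envelope coding, temporal whitening, and synthetic populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope coding, temporal whitening, and synthetic populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(envwhiten)
```

## The scientific problem

Weakly electric fish sense amplitude modulations (AMs, "beats") of their
quasi-sinusoidal electric organ discharge (EOD).  When two fish move
relative to one another, the AM itself waxes and wanes: this second-order
feature, the *envelope*, carries relative-movement information and occupies
very low temporal frequencies (0.05--1 Hz).  Natural movement envelopes have
a power spectrum that decays as a power law, approximately `f^-0.8`.
Efficient-coding theory predicts that a neuron optimally encodes such input
when its tuning opposes the stimulus decay, i.e. when the squared gain
cancels the stimulus spectrum so that the *response* power is independent of
frequency -- temporal whitening.  A neuron with power-law gain
`G(f) = G0 * f^beta` whitens an `f^alpha` stimulus exactly when
`2*beta + alpha = 0`; for `alpha = -0.8` the optimal exponent is
`beta = 0.4`, which is what hindbrain (ELL) pyramidal cells and midbrain
multipolar cells show, while feedback-inactivated pyramidal cells and
stellate cells are flat (`beta ~ 0`).

`envwhiten` implements the complete analysis chain used to establish such
results, together with a synthetic-data generator producing stimuli,
spiking neurons and behavior with *known programmed tuning*, so that every
stage of the pipeline can be validated by parameter recovery rather than
by re-using in-vivo recordings.

## The analysis chain

1. **Spike detection** (`detect_spikes`): voltage traces are high-pass
   filtered (100 Hz, 8th-order Butterworth, zero-phase) and spike times are
   upward threshold crossings, refined by linear interpolation.
2. **Cycle histogram and gain** (`cycle_histogram`, `fit_sinewave`,
   `compute_gain`): spikes are folded by envelope phase over complete
   cycles (32 bins by default), a sinewave is fitted to the histogram, and
   the gain is the fitted firing-rate modulation amplitude divided by the
   envelope amplitude, in Hz per unit contrast.
3. **Filtered firing rates** (`filtered_rate`): a unit-area delta train
   low-pass filtered (2nd-order Butterworth, zero-phase) with cutoffs 0.2,
   0.35, 0.75, 1.5, 2.5 and 3.5 Hz paired with envelope frequencies 0.05,
   0.1, 0.2, 0.5, 0.75 and 1 Hz.  Used for display and as an independent
   cross-check of the cycle-histogram gain (the suite requires agreement
   within 10%).
4. **Power-law tuning fits** (`fit_power_law`): ordinary least squares on
   log10 gain versus log10 frequency; the exponent is the slope.
5. **Response-power prediction and whitening index**
   (`predict_response_power`, `white_index`): predicted response power is
   `gain(f)^2 * f^alpha` with `alpha = -0.8`; the whitening index is the
   trapezoidal area under the response-power curve divided by the area of
   the constant-maximum curve.  It is scale-invariant, lies in [0, 1], and
   equals 1 exactly for a flat spectrum.  On the six standard frequencies a
   flat-gain unit scores ~0.229 (the `f^-0.8` pass-through value).
6. **Spike-triggered averages** (`compute_sta`,
   `sta_percent_of_control`): mean stimulus in a 2 s window around each
   spike; AM responsiveness is quantified as STA peak-to-peak, reported as
   a percentage of the control condition.
7. **Behavior** (`eod_frequency`, `behavioral_gain`): the EOD frequency is
   extracted from upward zero crossings of the EOD signal, converted to a
   unit-area delta sequence and low-pass filtered (2nd-order Butterworth,
   0.05 Hz); behavioral gain uses the same cycle-average machinery on the
   continuous trace.
8. **Population statistics** (`wilcoxon_signed_rank`, `kruskal_wallis`,
   `compare_conditions`): paired contrasts use the signed-rank test (exact
   by enumeration up to n = 25, tie-aware), unpaired contrasts use
   Kruskal-Wallis; dispersion is reported as mean +/- SEM, and p-values are
   uncorrected at the 0.05 level (an optional Holm correction can be
   applied downstream with `stats::p.adjust`).

## The synthetic-data generator

The generator defines the study conditions the tests run under.

**Stimuli** (`stimulus_spec`, `make_stimulus`): the carrier is 5--15 Hz
Gaussian noise (4th-order Butterworth band-pass applied forward-backward,
so the band edges are those of the analog prototype and no phase
distortion biases STA shapes), normalized to unit RMS in dimensionless
contrast units with baseline 1.  Sinusoidal envelopes are
`1 + depth*sin(2*pi*f*t)` with depth 0.20 by default; naturalistic
envelopes shape white noise in the frequency domain to an `f^-0.8`
spectrum over 0.02--2 Hz (zero outside), scaled to 20% RMS contrast and
offset to mean 1.  Restricting the shaping band keeps realizations
strictly positive at this contrast -- full-band power-law noise would
place appreciable power at very low frequencies and drive excursions
below zero, which would have to be clipped, distorting the spectrum.
Realizations that would still go non-positive are rejected, never
clipped.

**Neurons** (`neuron_spec`, `simulate_neuron`): an inhomogeneous Poisson
process (thinning; candidate spikes at the peak rate, guarded to stay
below 1/0.5 ms) with rectified rate

```
rate(t) = max(0, baseline + PL[envelope(t) - 1] + am_sensitivity * am(t))
```

where `PL` applies the power-law transfer function `G0 * |f|^beta` in the
frequency domain.  For a sinusoidal envelope of depth `d` at frequency
`f` the programmed modulation amplitude is exactly `G0 * f^beta * d`,
which is the closed-form oracle the recovery tests use.  The rate model
is deliberately phenomenological: the quantity under study is the tuning
curve, and a Poisson process is the simplest generator matching a purely
rate-based analysis.  ON- and OFF-type cells are pooled in the analyses
this package mirrors, so a single positive-gain sign convention is used.

**Condition presets** (`condition_preset`): the presets encode the
qualitative tuning structure per condition -- control pyramidal cells and
multipolar cells `beta = 0.4`; complete feedback inactivation,
indirect-feedback inactivation and stellate cells `beta = 0`; complete
inactivation scales `G0` down (x0.2, attenuation at every frequency) and
indirect-feedback inactivation scales it up (x1.2, raised low-frequency
gain).  The numeric baselines (40--60 Hz) and gain coefficients (150--264
Hz/contrast) are synthetic-population choices, selected so that (a) rate
modulations never clip against zero at 20% depth (peak modulation at most
~0.75 of baseline), and (b) shot noise in the gain estimates stays near
1.5% under the default duration policy (see below).  In particular the
stellate preset uses a 40 Hz baseline for estimator stability rather than
the ~1.4 Hz spontaneous rate reported for these cells in vivo; the
comparisons consume tuning *shape*, not absolute rate.

**Behavior** (`behavior_spec`, `simulate_behavior`): the instantaneous
EOD frequency is the base frequency (800 Hz by default) plus the envelope
deviation passed through a behavioral power-law transfer `Gb * f^beta_b`
with negative exponent (low-pass tracking); the signal is synthesized
phase-continuously by integrating the instantaneous frequency.  The
programmed frequency trace is returned alongside the signal as a
ground-truth oracle.

## Trial durations: a shot-noise power analysis

The standard error of the cycle-histogram modulation-amplitude estimate
for a Poisson neuron with mean rate `lambda` over duration `T` is
`sqrt(2*lambda/T)`.  For a high-pass unit the modulation amplitude is
`A(f) = G0 * f^0.4 * depth`, so the *relative* error scales as
`f^-0.4 / sqrt(T)`; holding it constant across frequencies requires
`T(f) ~ f^-0.8`.  The per-unit whitening index is the binding constraint:
it divides by the *maximum* of six noisy power values, so with relative
gain errors `s` the expected index of a perfectly whitened unit is
roughly `1/(1 + 2.5*s)`; keeping population means above 0.95 requires
`s` below about 2%.

The package therefore ships two duration policies
(`duration_for_frequency`):

- `cycles20`: `max(100 s, 20 cycles)` -- the casual default for
  single-unit work (gain errors ~5%);
- `power`: `max(100 s, 250 * f^-0.8 s)` (2747 s at 0.05 Hz down to 250 s
  at 1 Hz, ~5600 s per unit) -- the default for population experiments,
  giving ~1.6% gain errors at every frequency.

Population experiments run at a 500 Hz stimulus sampling rate: the AM
carrier tops out at 15 Hz, so this is ~16-fold oversampled, and spike
thinning operates in continuous time with the rate interpolated between
samples.  With these sizes a full paired 8-unit, six-frequency,
two-condition experiment takes on the order of a minute on one CPU.

## Numerical choices

- **All filtering is zero-phase** (forward-backward `filtfilt`), so
  amplitude estimates and STA lag structure carry no filter delay.
  Traces are mean-subtracted before filtering and the mean restored
  afterwards, which shrinks boundary transients driven by the large DC
  offset of rate traces.
- **Sinewave fits are closed-form Fourier projections** of the cycle
  histogram (identical to least squares for uniform complete bins):
  deterministic, with no optimizer failure modes.  When a continuous
  trace is folded and some phase bins are empty (sampling commensurate
  with the envelope period), the fit switches to explicit least squares
  at the occupied bin centers -- the uniform-bin projection would leak the
  large DC offset into the fundamental.
- **The first envelope cycle is discarded** before cycle averaging
  (`analyze_unit`), avoiding onset transients; only complete cycles are
  folded.
- **EOD-frequency extraction is two-stage.**  A 0.05 Hz 2nd-order filter
  designed directly at a 2--20 kHz sampling rate has a normalized cutoff
  of order 1e-5 and is numerically fragile, and the raw crossing train
  carries carrier lines whose modulation sidebands can alias into the
  envelope band.  The unit-area crossing train is therefore anti-alias
  filtered (4th-order) and decimated to `min(200, crossing rate/8)` Hz
  before the 0.05 Hz filter is applied.  The reported quantity -- the
  low-pass filtered crossing rate -- is unchanged.
- **Behavioral filter-gain correction.**  A 0.05 Hz cutoff attenuates a
  1 Hz envelope modulation by ~1.6e5 (forward-backward squared response),
  so `behavioral_gain` divides the extraction filter's exact squared
  magnitude response at the envelope frequency out of the fitted
  amplitude by default (`correct_filter_gain = FALSE` reproduces the raw
  attenuated values; relative pre/post comparisons are unaffected either
  way).  Because the surviving modulation is tiny, edge transients are
  aggressively trimmed (five filter time constants) before folding.
- **Power-law fits exclude zero gains** with a warning rather than
  flooring them: flooring injects an arbitrary constant into the slope.
- **Paired designs share the stimulus seed** across the two conditions
  within a unit (mirroring within-cell pre/post recordings); neuron noise
  seeds always differ.  All generators restore the caller's RNG state, and
  identical specifications are byte-reproducible.

## What the generator does and does not emulate

It emulates: the band-limited AM carrier and its slow envelopes at the six
standard frequencies and 20% depth; `f^-0.8` naturalistic envelope
statistics over the behaviorally relevant band; programmed power-law
envelope tuning with Poisson variability; low-pass power-law behavioral
tracking of the envelope by the EOD frequency.

It does not emulate: biophysical spike generation (no conductances, no
SK-channel dynamics, no bursting), spatial receptive fields, ON/OFF
asymmetries, adaptation beyond the discarded first cycle, EOD carrier
harmonics, or social (three-fish) envelopes.  Passing recovery tests
therefore demonstrates that the *analysis* is correct and unbiased under
Poisson variability with known tuning -- not that real neurons satisfy the
model's assumptions.

## Known limitations

- Gain estimates assume the response at the envelope frequency is
  sinusoidal; strong rectification (modulation amplitudes approaching the
  baseline rate) compresses the fundamental and biases gains downward.
  The presets deliberately stay below that regime.
- The behavioral filter-gain correction amplifies any residual artifact
  at the envelope frequency by the same large factor as the signal;
  recovery is accurate to a few percent under the shipped conditions but
  degrades if edge trimming is reduced or the EOD carrier is placed at a
  low multiple of the decimated rate.
- The whitening index estimated from noisy gains is biased slightly
  downward for perfectly whitened units (it divides by a maximum); the
  `power` duration policy keeps this bias within ~0.05.

## Reproducing a population contrast

```{r example}
cfg <- experiment_config(n_units = 8, duration_policy = "power", seed = 123)
res <- compare_conditions(cfg, "control_ell", "np_inactivated")
res$population   # mean +/- SEM exponents and white indices per condition
res$tests        # paired signed-rank p-values
```
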