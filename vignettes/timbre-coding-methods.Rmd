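---
title: "Methods: spectral-peak coding analysis for IC neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-peak coding analysis for IC neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timbreIC)
```

## The problem this package addresses

Timbre "brightness" tracks the spectral centroid of a harmonic sound.
A way to probe how the auditory midbrain encodes it is to play a
harmonic complex tone whose component levels fall off linearly in dB
per octave on either side of a spectral peak, and to shift the whole
spectrum past the characteristic frequency (CF) of a single inferior
colliculus (IC) neuron. The neuron's average firing rate as a function
of the stimulus spectral-peak frequency — the *rate profile* — is then
an inferred population response: it shows what a bank of neurons tuned
at, below, and above the peak would report simultaneously.

This package implements that full analysis chain in R: stimulus
synthesis, a synthetic-neuron generator that stands in for recorded
data, rate and temporal response metrics, neural discrimination
thresholds, spectral receptive-field fits, and three phenomenological
IC models. Every stage is exercised against the generator's known
ground truth, so the pipeline's statistical behavior (recovery rates,
false-call rates, oracle agreement) is itself measured, not assumed.

## Stimuli

`harmonic_complex_spec()` describes one synthetic-timbre stimulus:
components at multiples of the fundamental F0 = 200 Hz (plus an
optional constant shift), a triangular dB envelope with a 24 dB/octave
roll-off around the spectral peak, a 10 kHz upper component limit,
sine starting phase, 300 ms duration with 20 ms raised-cosine ramps.
`make_shift_series()` builds the shifted series: the reference peak is
the multiple of F0 nearest the neuron's CF, the spectrum is shifted in
constant-Hz increments (35–50 Hz, default 40) to cover six harmonics
on either side, floored at 200 Hz. Shifting by a constant offset
preserves the 200 Hz component spacing while making the complex
inharmonic, which is the intended manipulation.

Levels are defined on the steady-state RMS re 20 µPa, with the ramps
excluded from the RMS window; the source protocol does not state ramp
handling, so this is the package's documented choice (the alternative,
including ramps, changes the level by < 0.3 dB at these ramp
durations). Calibration is a pure software scale: samples are in
pascals. The default sample rate is 48 kHz (comfortably above twice
the 10 kHz component limit); the IC-model chain uses 24 kHz by default
for speed, still above the Nyquist requirement.

Amplitude-modulated Gaussian noise for modulation transfer functions
(MTFs) uses a 100 Hz–10 kHz carrier at a 33 dB SPL spectrum level,
modulation frequencies 2–600 Hz at three steps per octave plus an
unmodulated reference, 100% modulation depth by default (the depth is
not printed in the source protocol). The spectrum level refers to the
unmodulated carrier; modulation raises total power by at most ~1 dB at
full depth. Noise tokens are seeded and reproducible bit-for-bit.

## The synthetic-neuron generator

`synthetic_neuron()` defines a ground-truth IC-like neuron. Its mean
rate versus spectral-peak frequency follows a closed form on a
log2-frequency axis: a Gaussian bump (peak), inverted bump (dip),
linear-in-octaves ramp (sloping), or a constant (flat), on top of
spontaneous plus driven baseline rates. Spiking is an inhomogeneous
Poisson process whose instantaneous rate is modulated at integer
multiples of F0 with configurable depths and phases,
`lambda(t) = r0 (1 + sum_k m_k cos(2 pi k F0 t + phi_k))`, simulated by
thinning; an optional absolute dead time exists but defaults off, since
none of the metrics here require refractoriness. Defaults mirror the
experimental protocol: 30 repetitions, 300 ms stimuli, analysis window
50–300 ms.

Default parameter choices, made once at design time:

- spontaneous rate 10 sp/s, driven baseline 30 sp/s, bump/dip
  amplitude 30 sp/s — mid-range IC driven rates;
- profile width is *tuning-matched*: half the cat-Q10 10-dB bandwidth
  at CF expressed in octaves, floored at 0.2 octaves. A fixed octave
  width would be unrealistic at high CF (real tuning narrows in
  octaves as CF rises) and would make high-CF profiles nearly flat
  across the ±6-harmonic series, since 6 × 200 Hz is only ~0.2 octaves
  at 8 kHz;
- sloping baseline slope 15 sp/s per octave, matching the dynamic
  range of published sloping examples;
- locking depth m = 0.4 at F0 — in the range implied by the reported
  mean vector strength (~0.25, i.e. m ≈ 0.5) for these stimuli.

What the generator does *not* emulate: trial-to-trial rate
correlations, adaptation within a trial (except through the optional
`depth_decay` of locking), level dependence of the profile, and
non-Poisson count dispersion. Trial rate SDs in the analyses are
therefore Poisson-scaled; tests that are sensitive to the variance
model state that assumption. Passing the recovery tests shows the
pipeline works under these idealized conditions; real data add
correlated noise the tests do not probe.

## Rate metrics

`compute_rate_profile()` counts spikes per trial in the analysis
window (default 50–300 ms, excluding the onset response) and reports
per-condition means and trial SDs. `smooth_and_zscore()` smooths with
a 5-point triangular kernel ([1,2,3,2,1]/9, ends clamped by edge
replication) and standardizes using the mean and SD of the *smoothed*
profile, as the source describes. The smoothing kernel deserves a
note: a 3-point kernel was the initial candidate, but under the
assumed Poisson noise at 30 trials it leaves z-scored noise wiggles
with topographic prominence above the 0.25 classification criterion in
most monotone profiles, making the sloping category unrecoverable
(5–8% recovery in design-time calibration). The 5-point kernel is the
mildest symmetric kernel for which all three classes recover at ≥ 95%
(measured 99/100/95% over 100 seeded neurons per class); it remains
configurable.

`classify_profile()` finds local maxima of the z-profile with
prominence ≥ 0.25 (the standard topographic definition, implemented in
`find_peaks()`), and dips on the inverted profile; a feature must lie
within ±1 octave of CF (inclusive, distance measured as |log2(f/CF)|).
When both a peak and a dip qualify, the feature nearest CF in octaves
governs; an exact tie goes to the peak. `compute_salience()` computes
Q = f_p / BW_0.75, the feature frequency over the bandwidth where the
z-profile crosses 0.75 z below the peak (above the dip), with linear
interpolation between samples for the crossing frequencies. If a
crossing falls outside the measured range the bandwidth clamps to the
range edge and the result is flagged (`bw_clamped`), making Q an upper
bound. Q is invariant to affine rescaling of the raw rates because it
is defined on z-scores. Level trends use the OLS slope of Q against
level (43/63/83 dB SPL) with ±0.03/dB class bounds.

### MTF classification

Band-enhanced (BE) requires rates at two or more *contiguous*
modulation frequencies significantly above the unmodulated reference,
with no significantly suppressed rate between the significantly
enhanced ones; band-suppressed (BS) is the mirror; hybrid satisfies
both; flat neither. Significance is a Welch two-sample t-test per
modulation frequency at `alpha = 0.01` by default.

Both the contiguity requirement and the default alpha come from a null
calibration: the battery makes ~25 comparisons against one shared
unmodulated sample, so "any two significant at 0.05" misclassifies
35–40% of truly flat neurons (a low draw of the shared reference makes
many frequencies look enhanced at once). With contiguity and
alpha = 0.01, a 500-run null simulation classifies 97% of flat
templates as flat and calls BE falsely in 0.6% of runs, while power at
realistic effect sizes (≥ 50% rate changes) is essentially unchanged.
Alpha remains an argument for users who want the laxer criterion.

## Temporal metrics

Vector strength is the resultant length of unit phasors at the spike
phases; for a raised-cosine rate modulation of depth m it converges to
m/2, which the tests verify to ±0.02 at > 10,000 spikes. Significance
is the Rayleigh statistic 2nVS² with its asymptotic p = exp(−nVS²),
flagged for n < 10 where the asymptotics are unreliable. VS is
computed on pooled spikes by default (per-trial VS, needed for
threshold SDs, is computed in `vs_threshold()`). Period histograms
fold spikes modulo one period (32 bins per period by default) and
normalize to the fullest bin. Analyses at integer multiples of F0
default to harmonics 1–6, covering locking up to 1200 Hz.

### Rate-independent spike distance

The RI-SPIKE dissimilarity is time-resolved: at each time t, each
train contributes `S_n(t) = (dtP_n xF_n + dtF_n xP_n) / xISI_n`, where
xP/xF are distances to the preceding/following spike of train n, xISI
their sum, and dtP/dtF the distances from those spikes to the nearest
spike of the other train. The rate-independent profile drops the
cross-rate weighting of the standard SPIKE profile,

S_RI(t) = (S1(t) + S2(t)) / (xISI1(t) + xISI2(t)),

which coincides with the standard profile when the local rates are
equal and discounts pure rate differences otherwise (verified by the
superposition test: doubling both trains' spike counts with matched
timing statistics changes the distance by < 0.05). Trains are
augmented with auxiliary spikes at 0 and T as the edge correction, and
the time average is evaluated on a dense uniform grid (300–500 points)
rather than by exact piecewise integration; at these grid sizes the
discretization error is far below the trial-to-trial variability of
the distances. The condition-by-condition matrix holds mean pairwise
cross-condition distances off the diagonal and the within-condition
baseline (mean distance between trials of the same condition) on the
diagonal.

## Discrimination thresholds

Profiles (rate, per-trial vector strength, or spike-distance) are
linearly interpolated — means and SDs alike — onto 600 equally spaced
frequencies. The search then proceeds at grid separations
i = 1, 2, …, 100: at each i, find the steepest-slope pair (n, n+i)
(largest |rate difference| per Hz; ties broken toward the lowest
frequency), compute the pooled-SD d′ = |µ2−µ1| / sqrt((σ1²+σ2²)/2),
and stop at the first separation whose steepest pair reaches d′ ≥ 1.
The threshold is Θ = Δf / f_mid × 100 (percent of frequency). At each
separation all pairs are re-evaluated (not just extensions of the
separation-1 pair), and the steepest pair governs even if another pair
at the same separation has higher d′ — both choices follow the quoted
procedure. "Adjusted d′" is read as exactly the pooled-SD form; no
further adjustment is applied. `found = FALSE` is a valid outcome. The
implementation agrees exactly with a brute-force double-loop oracle on
1,000 random profiles (mixing findable and unfindable cases).

For the RI-SPIKE threshold, within-condition baselines provide (µ1,
σ1) and cross-condition distances (µ2, σ2); baselines interpolate
linearly and cross-distances bilinearly over both frequency axes onto
the 600-step grid, and the search maximizes the dissimilarity *excess*
over baseline, so a threshold is only reached when between-stimulus
dissimilarity significantly exceeds the within-stimulus variability.
The paper describes this computation as a contract rather than a
formula; the bilinear operationalization is this package's documented
reading.

## Receptive-field fits

`predict_rate()` weights each stimulus component's linear amplitude by
a Gaussian (or difference-of-Gaussians) evaluated at the component
frequency on a linear-frequency axis (log-frequency available via
`log_axis`), sums, and adds the spontaneous rate; DoG predictions are
half-wave rectified. Amplitudes enter linearly (a dB option is a
one-line change at the component table); the source is silent on both
axes, and linear/linear matches the antecedent DoG literature.

`fit_rf()` is box-constrained nonlinear least squares (L-BFGS-B with
an analytic gradient): centers bounded to the stimulated range ± one
octave, bandwidths in [one condition spacing, 2 × span], strengths
≥ 0, over a deterministic multistart grid of 5 centers × 3 bandwidths
× 2 strength scales. The bandwidth floor is an identifiability
constraint, not a tuning choice: a Gaussian narrower than the
condition spacing can only notch single data points, which no stimulus
design at that spacing can distinguish from noise. Goodness of fit is
R², with adjusted R² = 1 − (1−R²)(n−1)/(n−k−1), k = 3 (Gaussian) or 6
(DoG). `compare_models()` is the one-sided nested F test on residual
sums of squares.

Two statistical properties of this procedure, measured by the test
suite, deserve emphasis:

- **The naive F test is anticonservative here.** Under a pure-Gaussian
  truth, the DoG's inhibitory center and bandwidth are unidentified
  (the null sits on the boundary strength = 0), and best-of-multistart
  selection lets the inhibitory lobe chase noise; the mean null RSS
  improvement is ~5σ² rather than the 3σ² the 3-df F accounting
  assumes. Calibration simulations put the true type-I rate near
  10–12% at a nominal 5%, independent of noise scale and series
  length. The acceptance suite asserts the nominal calibration band
  and therefore documents this inflation as a failing check rather
  than hiding it; single-sided F tests of this nested pair should be
  read with that in mind.
- **The DoG bandwidth ratio is weakly identified at realistic noise.**
  With profile SEMs around 2 sp/s (30 Poisson trials), fitted RSS
  beats the truth's RSS while the bandwidth ratio errs by ~30%
  (median) across a population of DoG truths; at 1 sp/s the median
  error falls to ~17% and at 0.25 sp/s to ~7%. Scatter plots of
  strength ratio versus bandwidth ratio from such fits carry this
  uncertainty.

## IC models

Three models predict rate profiles from the waveform.

**Front end.** A deliberately simplified auditory-nerve stage: a
fourth-order FIR gammatone centered on CF whose 10-dB bandwidth equals
CF/Q10 with cat Q10 = 10^(0.4708 log10(CF/kHz) + 0.4664), then
memoryless saturating transduction tanh(p / 0.05 Pa), half-wave
rectification, a 600 Hz fourth-order Butterworth low-pass (zero
phase), and an affine rate map with a 50 sp/s spontaneous rate. This
is not a reimplementation of a biophysical AN model; it preserves the
one property the IC models need — neural-fluctuation depth that
shrinks as transduction saturates near spectral peaks (verified
directly: the fluctuation depth of an AM probe falls monotonically
over a 40 dB level increase). Quantities that depend on biophysical AN
details are therefore out of scope. The 0.05 Pa saturation scale was
chosen at design time so the band-enhanced SFIE output has a cleanly
band-enhanced MTF (a harder saturation exaggerates the low-modulation-
frequency Jensen droop of the tanh stage until the shared classifier
calls model BE cells hybrid); the trade-off is weak on-CF fluctuation
contrast, so SFIE-BE timbre dips are shallow.

**Energy model.** RMS of the gammatone-filtered waveform, mapped
affinely onto rate at evaluation time. Being linear, its profile shape
is level-invariant (43 vs 83 dB SPL profile correlation 1.0 in the
acceptance run) and insensitive to component phases.

**SFIE.** Two same-frequency inhibition-excitation stages (cochlear
nucleus, then IC): each convolves its input with an excitatory alpha
function and subtracts a delayed, scaled, slower inhibitory alpha
function, then rectifies. Defaults: CN τ_ex = 0.5 ms, τ_inh = 2 ms,
delay 1 ms, strength 0.6; IC τ_ex = 1 ms, τ_inh = 2 ms, delay 2 ms,
strength 0.9 — placing the best modulation frequency near 64 Hz, inside
the 10–300 Hz range reported for IC. The band-suppressed output
inverts the BE drive against the stage's tonic excitation,
BS = HWR(tonic − 2.5 × delayed BE); the 2.5 inversion strength gives
the BS cell a suppression depth the shared MTF classifier can detect.
All parameters are configuration, not ground truth: the antecedent
models' exact values are deferred to their own publications.

**BMSI.** Three front-end + SFIE-BS channels (at CF and ±0.5 octave)
inhibit an on-CF cell whose excitation is the on-CF CN stage convolved
with the IC excitatory alpha function; with all inhibition strengths
zero it reduces exactly to the excitatory pathway. Default strengths
0.3/0.3/0.3 (off/on/off) were chosen so the resting output is positive
while broad inhibition still drives rates below it for many shifts —
the behavior that motivates the model; substantially larger strengths
silence the cell entirely with this front end.

Model MTFs are classified with the *same* classifier as synthetic
neurons by converting deterministic model rates into seeded Poisson
trial rates (5 trials by default, mirroring the experimental protocol;
the model-behavior checks use 20 for power). Model rate profiles are
deterministic; model-versus-data comparison (`evaluate_model()`)
interpolates the model onto the data grid, maps it affinely (the
models' output scale is arbitrary), and reports Pearson R and variance
explained, then runs the salience and threshold pipelines on the
mapped profile, borrowing the data profile's trial SDs for the
threshold search (a deterministic model has none of its own).

## Numerical choices and degenerate inputs

- Zero-variance (constant) profiles are flagged degenerate and
  classify as sloping (rate) or flat (VS) rather than erroring.
- Zero spikes: vector strength is NA with a flag; empty period
  histograms are flagged; empty conditions are excluded from distance
  matrices with a warning.
- Both SDs zero in d′: 0 if the means agree, infinity otherwise
  (treated as above-criterion).
- Thinning, not time discretization, generates spike times, so spike
  timing is exact to machine precision; spike tables round to 1 µs on
  disk.
- FFT convolutions are zero-padded to power-of-two lengths; the
  gammatone kernel is truncated at 6 time constants and normalized to
  exact unit gain at CF.

## Problem sizes in the test and acceptance runs

The suites run at sizes chosen to make their statistical assertions
meaningful while staying desk-scale: 100 seeded neurons per class for
classifier recovery; 1,000 random profiles for the threshold oracle;
200 seeds for the F-test calibration; 3 × 3 parameter cells for the
SFIE grid; 80 × 0.4 s trials (> 10,000 spikes) for vector-strength
recovery; 20 synthetic neurons for the end-to-end pipeline run. Full
population runs scale linearly in neurons and conditions.

## Known limitations

- The Poisson noise model understates real IC count dispersion and
  omits correlated variability; recovery rates on real data will be
  lower than the generator-based figures.
- The simplified front end cannot reproduce AN-model-specific numbers
  (e.g. absolute response bandwidths); only the qualitative
  saturation mechanism carries over, and SFIE-BE timbre dips are
  correspondingly shallow.
- The RI-SPIKE time average is grid-approximated; for trains with
  structure much finer than duration/grid_n, increase `grid_n`.
- Statistical comparisons across sound levels (mixed-effects models of
  salience) are outside this package's scope; it produces the
  per-neuron quantities those models consume.
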