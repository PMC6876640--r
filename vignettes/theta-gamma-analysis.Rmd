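---
title: "Theta–gamma coupling analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta–gamma coupling analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`gammakit` analyses continuous hippocampal LFP for the interaction of theta
(4–12 Hz) with slow (30–60 Hz) and fast (60–120 Hz) gamma oscillations,
plus the laminar, optogenetic and behavioural measurements that typically
accompany such recordings. Because raw in vivo recordings are rarely
shareable, the package carries a synthetic-data module that generates
signals with known ground truth; the test suite validates every estimator
by parameter recovery against that ground truth or against closed-form
oracles.

# The generative model

`synth_spec()` + `generate_lfp()` implement a phenomenological (not
biophysical) model of CA1 LFP:

- **Theta.** A sinusoid at `freq_hz` (default 8 Hz, 4–12 allowed),
  amplitude `amp_uv` (default 100 µV). Asymmetry — the sharp rise / slow
  fall of real theta — is produced by a monotone phase warp
  `ψ = θ + a·sin(θ)` with `a ∈ [0, 1)`, not by adding harmonics. The warp
  keeps the true instantaneous phase available in closed form, which is
  what makes the waveform-phase estimator testable sample-by-sample. An
  optional Ornstein–Uhlenbeck wander of the instantaneous frequency
  (`freq_drift_sd_hz`, correlation time `drift_tau_s`, default 2 s)
  emulates the cycle-to-cycle frequency variability of real theta; without
  some spectral width a pure tone makes the comodulogram's theta axis
  non-identifiable in principle, since every phase filter containing the
  tone returns the same phase.
- **Gamma.** Each component has a band (named or explicit), an envelope
  amplitude `amp_uv`, a coupling strength `κ ≥ 0` and a preferred phase
  `φ₀`. The envelope is `e(t) = A·(1 + κ·cos(ψ(t) − φ₀))/(1 + κ)` — always
  non-negative, phase-independent at κ = 0, and fully concentrated at φ₀ as
  κ → ∞ is approached. The carrier is narrowband-filtered white noise
  (RMS-matched to a unit tone) by default, giving the intermittent, bursty
  appearance of real gamma; a pure-tone carrier is available for exact
  spectral tests.
- **Background.** 1/f^α noise (default α = 1, `sd_uv` 10 µV) by spectral
  shaping of white noise — the standard LFP broadband floor.
- **Locomotor state.** Optional exponential ON/OFF bouts (defaults: mean
  15 s on, 60 s off, theta gain 0.2 when off, 0.25 s raised-cosine ramps).
  These defaults put roughly 10–20% of the session in the high-theta state,
  so that a 2-SD threshold on session-z-scored theta power falls between
  the two amplitude regimes; this is the regime in which theta-state
  masking is meaningful at all.
- **Stimulation.** An optional sinusoid at the schedule's stimulation
  frequency during ON epochs, with raised-cosine onset/offset ramps
  (default 20 ms).

Random streams are derived per component from the master seed, so altering
one component leaves the others bit-identical.

The laminar generator projects a common theta+gamma signal across a
16-channel, 50 µm probe: a Gaussian dipole kernel (whose discrete second
difference is the analytic CSD ground truth), a sign flip of theta at a
declared reversal depth, and a ripple-band component with a Gaussian depth
profile. The behaviour generator produces Gaussian-step random walks with
reflecting boundaries on a circular platform or square open field; in
object-biased mode a smooth attraction well (15 cm length scale)
concentrates dwell near one landmark, a deliberately strong-preference
regime whose discrimination index approaches 1.

**What the synthetic data does not emulate:** non-sinusoidal gamma
waveforms, sharp-wave ripples as events, movement and EMG artifacts,
electrode drift, volume conduction between distant sources, cross-regional
phase lags, or realistic exploratory behaviour (head direction, wall
following). Passing parameter-recovery tests therefore demonstrates
estimator correctness under the stated model, not robustness to every
artifact of real recordings.

# Spectral estimators

**Wavelet.** `morlet_spectrogram()` evaluates the continuous wavelet
transform with the complex Morlet wavelet, bandwidth 1.0 and centre
frequency 1.5, per target frequency via FFT convolution. The kernel is
peak-normalised in the frequency domain, and power is scaled so a sinusoid
of amplitude A produces a ridge of height A²/2 — its variance — making
wavelet ridges commensurate with band-integrated Welch PSD. Because the
wavelet is constant-Q, the ridge width grows with frequency; mean band
power over a linear grid therefore depends on where in the band a tone
sits, and tests compare against the closed-form kernel response rather
than assuming intensive band means. Edge columns within 3 wavelet time-SDs
(of the lowest analysed frequency) are trimmed by default.

**Fourier.** `fourier_spectrogram()` uses Hann-tapered moving windows: 2 s
for theta-band work, 5 s for gamma-band work, 10 ms steps. Per-bin power is
scaled so the column sum equals the taper-weighted window variance
(Parseval) and a tone integrates to A²/2. Times are window centres, so half
a window is implicitly unavailable at each end.

**Sampling rate.** All analysed bands lie below 250 Hz; recordings acquired
at higher rates should be decimated (`decimate_recording()`, anti-aliased)
to 1 kHz before analysis. This is a configuration choice, not a hard
requirement.

**Theta-sorted gamma.** Time steps are ordered by ascending session-z
theta power and summarised in 20 quantile bins by default. Quantile
(equal-occupancy) bins compare like behavioural states across sessions
with different state composition; the sorting is a pure permutation, so
total gamma power is conserved exactly.

# Phase estimation

Both methods share the package-wide convention **0° = theta peak**, 90° =
descending zero, 180° = trough, 270° = ascending zero. The convention is
arbitrary but fixed; any comparison with figures that use a trough-zero
convention needs a 180° rotation.

- `hilbert_phase()`: order-4 Butterworth band-pass applied
  forward–backward (zero phase distortion — mandatory for phase work),
  then the analytic-signal angle via FFT.
- `waveform_phase()`: the broad-band landmark method. The trace is filtered
  1–60 Hz; peaks are local maxima separated by at least 1/12 s (one cycle
  of the fastest theta, which suppresses gamma-riding spurious peaks);
  troughs and zero crossings are located between consecutive peaks; phase
  is interpolated linearly between landmarks. Cycles with peak-to-peak
  duration outside [1/12, 1/4] s — outside 4–12 Hz — are masked invalid, as
  is everything before the first and after the last landmark. On symmetric
  theta the two methods agree to a few degrees; on asymmetric theta the
  narrow-band Hilbert phase is systematically distorted (the band-pass
  symmetrises the waveform) while the landmark method tracks the warped
  ground truth more closely, which the tests verify with circular RMSE.

Theta states are defined by session-z-scored theta power exceeding a
threshold (default 2 SD); downstream PAC windows overlapping sub-threshold
time are dropped.

# Phase–amplitude coupling

`pac_profile()` follows a specific convention: the **raw, unfiltered trace
is z-scored once per session**, and gamma power is then extracted from the
z-scored trace (Morlet power averaged over in-band frequencies by default;
filter-Hilbert envelope as an option). Z-scoring the raw trace rather than
the filtered gamma keeps between-group differences in absolute gamma power
visible in the coupling profiles instead of normalising them away. In
non-overlapping 2 s windows, phase is binned into 40 bins of 9°, gamma
power is averaged per bin, and bin means are averaged across windows;
windows touching invalid or masked samples are excluded, and fewer than 5
valid windows (configurable) is an error.

The **modulation index** normalises the binned amplitudes to a probability
vector P and computes `MI = D_KL(P‖uniform)/ln 40`, with `0·ln 0 ≡ 0`. The
reference distribution is taken to be uniform. MI is 0 for a flat profile,
1 for a single-bin delta, and invariant under bin rotation and positive
rescaling. Averaging z-scored quantities can produce negative bin values;
since KL needs a probability vector, the profile is shifted by its minimum
before normalisation and the result is flagged (`shifted`) rather than
silently accepted. The preferred phase is the amplitude-weighted circular
mean — sub-bin resolution and more noise-stable than the argmax bin.
Whether bins should be pooled across windows before computing MI, or MI
averaged per window, is not dictated by the definition; profiles pool
(average) bins across windows here.

# Comodulograms

For each pair (f_θ, f_γ) on the default grids (theta 4–12 Hz step 0.5,
gamma 30–120 Hz step 2.5): phase at f_θ ± 1 Hz, filter-Hilbert envelope
power at f_γ, MI on pooled 40-bin profiles. The **amplitude filter
half-width is adaptive, f_θ + 2 Hz** by default. This is deliberate: an
envelope modulated at f_θ carries spectral sidebands at f_γ ± f_θ, so an
amplitude filter narrower than the phase frequency removes the modulation
entirely — a ±5 Hz window cannot detect 8 Hz modulation no matter how
strong the coupling, and instead produces spurious responses at the
sideband frequencies. The adaptive width is the narrowest filter that
passes both sidebands with margin, preserving localisation along the gamma
axis; a fixed width remains available and is validated against band
overlap. The max-over-theta projection keeps, per gamma frequency, the
maximal MI across theta frequencies. Optional significance uses 200
circular-time-shift surrogates of the amplitude series with a pointwise
95th percentile — a null that preserves both spectra while destroying the
phase–amplitude alignment.

# Laminar analyses

`csd()` implements the plain discrete second spatial difference with
constant conductivity σ (default 1, i.e. relative CSD), dropping the two
edge channels; no Vaknin padding and no spline inverse methods, so results
are directly interpretable as the stated formula. Channel spacing must be
uniform to 1%. Analytic identities pin the implementation: a linear depth
profile gives 0, a quadratic profile gives a constant −2σ independent of
Δx, and the operator is linear to floating-point tolerance.

Ripple-band power per channel (default 100–250 Hz; the band is
config-exposed since conventions differ) localises the putative pyramidal
layer as the argmax channel. Theta phase reversal between two channels is
the circular mean Hilbert-phase difference, with "reversal" declared for
|Δφ| ∈ [150°, 210°].

# Stimulation metrics

Epochs come from tabular ON/OFF schedules (50% duty cycle by default, so
total illumination is frequency-independent). For ratios, 100 ms is
trimmed from each epoch boundary (onset transients), Welch PSD (Hann, 1 s
segment cap, 50% overlap) is computed per epoch interior, the target is
integrated by the trapezoidal rule, and each ON epoch is compared with the
immediately preceding OFF epoch — an intra-session control matching
alternating designs. A pooled-mean alternative is available and agrees
with adjacent pairing within a few percent on stationary signals.

Two target modes exist: a band (e.g. slow gamma 30–60 Hz) and a narrow
frequency window (stimulation frequency ± 0.5 Hz). A caveat worth knowing:
a per-pair ratio over a ±0.5 Hz window has very few effective degrees of
freedom per 2 s epoch (≈ 2·bandwidth·duration), so its mean is inflated by
~10% even with no stimulation at all. Band ratios do not suffer from this
at any practical epoch length, and the null-behaviour test uses them; the
narrow window is the right tool where a large entrained peak dominates the
estimator noise.

`entrainment_fidelity()` is the fraction of reference-band (4–12 Hz) PSD
within ±0.5 Hz of the stimulation frequency, via Welch with 4 s segments
(0.25 Hz resolution, so the ±0.5 Hz window is well resolved). It is
dimensionless, bounded in [0, 1], and invariant under amplitude rescaling.

# Behavioural scoring

- Object exploration: nose within 1 cm of an object; epochs shorter than
  0.1 s are rejected as tracking jitter; missing nose data falls back to
  the body centre with a warning. The discrimination index uses the ratio
  form DI = t_D/(t_D + t_F), whose chance level for two objects is 0.5 and
  which satisfies DI(D,F) + DI(F,D) = 1; the difference form
  (t_D − t_F)/(t_D + t_F) is a trivial transform of it.
- Cup-platform errors: 20 cups on a 1 m platform (ring radius 40 cm by
  default); a visit is the body centre within 3 cm of a cup for ≥ 0.2 s;
  each unbaited cup counts at most once per trial, bounding errors at 19.
  The visit criterion is config-exposed since it is a tracking convention,
  not a law.
- Quadrant occupancy partitions the arena by position angle with half-open
  intervals, so boundary samples are assigned deterministically and the
  four occupancies sum to exactly 1; chance is 25%.
- Alternation success is correct choices over trials; partial η² is the
  plain substitution SS_effect/(SS_effect + SS_error), with the ANOVA sums
  of squares themselves delegated to standard routines (`stats::aov`).

# Numerical choices and degenerate inputs

- Filters: Butterworth order 4, forward–backward; band edges at or above
  Nyquist are errors, not clamped.
- Gaps are explicit validity masks, never NaN; windowed analyses drop any
  window touching an invalid sample.
- Zero-variance inputs error in z-scoring, phase extraction and fidelity
  rather than returning NaN.
- Container I/O: flat binary (little-endian int16 with declared µV/bit
  gain, or float64) plus a JSON sidecar declaring rate, geometry and
  encoding; the sidecar is authoritative and truncated payloads are
  integrity errors. Schedules and tracks are CSV with declared headers.
- Problem sizes in the test suite are chosen for thorough yet desk-scale
  verification: 300 s at 1 kHz for coupling parameter recovery (κ grid
  {0, 0.2, 0.4, 0.6, 0.8} × 3 seeds), 120 s for comodulogram localisation,
  10⁴ s walks for occupancy statistics, 20 seeds for null-ratio behaviour.

# Interfaces

The package is an R library; analyses are composed with pipes on tibbles
and result objects (`tidy()`, `glance()`, `autoplot()`), and any pipeline
stage can be scripted with `Rscript` directly. Phase series, schedules,
tracks and profiles all round-trip through plain CSV for interoperability
with acquisition and tracking tools.

# Known limitations

- The comodulogram's theta axis cannot be sharper than the spectral width
  of theta itself; on near-tonal theta the maximum may sit one grid step
  off the nominal frequency.
- MI depends on the amplitude estimator's bandwidth; values are comparable
  within one convention but not across conventions.
- The waveform phase method needs visible theta cycles; under heavy
  broadband noise its validity mask shrinks and PAC windows with it.
- CSD assumes constant conductivity and uniform spacing; no correction for
  electrode tip effects or anisotropy is attempted.
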