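# gammakit

Analysis of hippocampal local field potentials (LFP), centred on the
interaction of theta (4–12 Hz) and gamma (slow 30–60 Hz, fast 60–120 Hz)
oscillations. The package is aimed at systems-neuroscience labs analysing
continuous extracellular recordings (single microelectrodes or laminar
silicon probes) together with optogenetic stimulation schedules and
video-tracking output.

## What it computes

- **Time–frequency decomposition**: complex Morlet wavelet spectrograms
  (bandwidth 1.0, centre frequency 1.5) and moving-window Fourier
  spectrograms (2 s windows in the theta band, 5 s in the gamma band, 10 ms
  steps), with band power, theta peak frequency, session z-scored theta
  power and theta-power-sorted gamma power.
- **Instantaneous theta phase** by two methods: zero-phase band-pass (4–12
  Hz) + Hilbert transform, and a broad-band (1–60 Hz) waveform method that
  interpolates phase linearly between peak (0°), descending zero (90°),
  trough (180°) and ascending zero (270°), preserving theta's natural
  asymmetry.
- **Phase–amplitude coupling (PAC)**: gamma power of the z-scored raw trace
  averaged in 40 theta-phase bins of 9° within 2 s windows; a modulation
  index defined as the Kullback–Leibler distance of the binned amplitude
  distribution P from uniform,

  `MI = D_KL(P ‖ U) / ln N,  N = 40`,

  so MI ∈ [0, 1]; amplitude-weighted preferred phase; and theta–gamma
  comodulograms over (4–12) × (30–120) Hz with a max-over-theta projection.
- **Laminar diagnostics**: current source density by the discrete second
  spatial difference

  `CSD(x, t) = σ (2 V(x,t) − V(x+Δx,t) − V(x−Δx,t)) / Δx²`

  on equally spaced channels (Δx = 50 µm probes), ripple-band power per
  channel (pyramidal-layer localization) and theta phase reversal between
  channels.
- **Optogenetic entrainment**: per-epoch stimulation/baseline PSD ratios
  under alternating ON/OFF schedules, and entrainment fidelity — the
  fraction of theta-band power within ±0.5 Hz of the stimulation frequency.
- **Behavioural scoring**: object exploration (nose within 1 cm) and the
  discrimination index t_D/(t_D+t_F); spatial errors on a 20-cup circular
  platform (bounded by 19); target-quadrant occupancy (chance 25%);
  alternation success rate; and partial η² = SS_effect/(SS_effect+SS_error).
- **Synthetic data with ground truth**: theta-nested-gamma LFP (asymmetric
  theta by phase warping, gamma envelope `A(1+κ cos(θ−φ₀))/(1+κ)`, 1/f
  background, locomotor-state gating, stimulation-locked components),
  16-channel laminar dipole profiles with an analytic CSD, and arena random
  walks — so every stage is testable by parameter recovery.

Everything user-facing takes/returns tibbles or small S3 result objects
with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Generate 120 s of synthetic LFP whose slow-gamma envelope is coupled to
theta phase (coupling strength κ = 0.8, preferred phase 180°), then recover
the coupling:

```r
library(gammakit)

spec <- synth_spec(
  theta = list(freq_hz = 8, amp_uv = 100),
  gamma = list(list(band = "slow", amp_uv = 20, kappa = 0.8,
                    phi0_deg = 180)),
  noise = list(sd_uv = 10))
rec <- generate_lfp(spec, duration_s = 120, fs = 1000, seed = 42)
rec
#> <lfp_recording> 1 channel(s) x 120000 samples @ 1000 Hz (120.0 s)

pp <- pac_profile(hilbert_phase(rec), rec, gamma_band = "slow")
pp
#> <pac_profile> 40 bins, MI = 0.0438, preferred phase = 181.3 deg (60 windows)
glance(pp)
#> # A tibble: 1 x 4
#>       mi preferred_phase_deg n_windows shifted
#> 1 0.0438                181.        60 FALSE

theta_peak_frequency(morlet_spectrogram(rec, freqs = 1:120, step_s = 0.01))
#> [1] 8
```

The preferred phase lands within 1.3° of the generator's 180° and the MI is
far above the uncoupled floor (≈ 5e−5 at κ = 0); `autoplot(pp)` draws the
40-bin profile over two theta cycles.

Entrainment fidelity on its defining two-tone case — a 10 Hz "stimulated"
tone plus a 6 Hz tone with power ratio (1/2) : (1/3), so exactly 60% of
theta-band power lies within 9.5–10.5 Hz:

```r
fs <- 1000; t <- (0:(60 * fs - 1)) / fs
x <- sin(2 * pi * 10 * t) + sqrt(2/3) * sin(2 * pi * 6 * t)
entrainment_fidelity(x, stim_hz = 10, fs = fs)
#> [1] 0.5999999
```

## Documentation

The methods vignette (`vignettes/theta-gamma-analysis.Rmd`) describes the
generative model, the estimators, the numerical choices (filters, wavelet
normalisation, edge policies, the negative-bin policy for MI in z units)
and the known limitations of the synthetic benchmark.
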