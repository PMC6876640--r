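# shared builders for synthetic fixtures (all generated at test time)

coupled_spec <- function(kappa, phi0 = 180, band = "slow", amp = 20,
                         noise_sd = 10, freq = 8) {
  synth_spec(theta = list(freq_hz = freq, amp_uv = 100),
             gamma = list(list(band = band, amp_uv = amp, kappa = kappa,
                               phi0_deg = phi0)),
             noise = list(sd_uv = noise_sd))
}

tone_recording <- function(freq, amp = 1, duration = 10, fs = 1000,
                           phase = 0) {
  t <- (0:(duration * fs - 1)) / fs
  lfp_recording(amp * cos(2 * pi * freq * t + phase), fs = fs)
}

circle_arena <- function(radius = 50) list(shape = "circle", radius_cm = radius)
square_arena <- function(side = 45) list(shape = "square", side_cm = side)
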