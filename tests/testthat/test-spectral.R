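# analytic response of the Morlet kernel (fb = 1, fc = 1.5, peak-normalised
# in frequency) to a real tone of amplitude A at f0, evaluated at analysis
# frequency nu: independent closed-form oracle for the wavelet pipeline
morlet_tone_power <- function(nu, f0, A, fb = 1, fc = 1.5) {
  a <- fc / nu
  (A^2 / 2) * exp(-pi^2 * fb * (a * f0 - fc)^2)^2
}

test_that("wavelet spectrogram matches the analytic tone response", {
  rec <- tone_recording(8, amp = 2, duration = 20)
  sp <- morlet_spectrogram(rec, freqs = 1:40, step_s = 0.05)
  prof <- rowMeans(sp$power)
  # ridge at the tone frequency with height A^2/2, constant over time
  expect_equal(sp$freqs[which.max(prof)], 8)
  expect_equal(max(prof), 2, tolerance = 0.01)
  mid <- sp$power[8, ]
  expect_lt(stats::sd(mid) / mean(mid), 0.01)
  # whole profile against the closed form
  expect_equal(prof, morlet_tone_power(1:40, 8, 2), tolerance = 0.02)

  # two tones: ridge powers in squared-amplitude ratio
  t <- (0:19999) / 1000
  two <- lfp_recording(3 * cos(2 * pi * 8 * t) + cos(2 * pi * 40 * t),
                       fs = 1000)
  sp2 <- morlet_spectrogram(two, freqs = 1:60, step_s = 0.05)
  p2 <- rowMeans(sp2$power)
  expect_equal(p2[8] / p2[40], 9, tolerance = 0.05)

  # zero in, zero out
  z <- lfp_recording(rep(0, 5000), fs = 1000)
  expect_equal(max(morlet_spectrogram(z, freqs = 1:40)$power), 0)

  expect_error(morlet_spectrogram(rec, freqs = c(10, 600)), "Nyquist")
})

test_that("Fourier spectrogram uses the stated windows and conserves power", {
  rec <- tone_recording(10, amp = 1, duration = 12)
  sp <- fourier_spectrogram(rec, "theta", step_s = 0.1)
  expect_equal(sp$params$window_s, 2)
  # peak bin at the tone every step, within the 0.5 Hz bin width
  peaks <- sp$freqs[apply(sp$power, 2, which.max)]
  expect_true(all(abs(peaks - 10) <= 0.5))
  # Parseval: column sum ~ tone variance A^2/2
  expect_equal(mean(colSums(sp$power)), 0.5, tolerance = 0.01)

  expect_equal(fourier_spectrogram(rec, "gamma")$params$window_s, 5)
  short <- lfp_recording(rnorm(500), fs = 1000)
  expect_error(fourier_spectrogram(short, "theta"), "insufficient")
})

test_that("a band-power step is localised within one window length", {
  fs <- 1000
  t <- (0:(60 * fs - 1)) / fs
  amp <- ifelse(t < 30, 1, 2)
  rec <- lfp_recording(amp * cos(2 * pi * 40 * t), fs = fs)
  sp <- fourier_spectrogram(rec, "gamma", step_s = 0.1)
  bp <- band_power(sp, "slow")
  before <- bp$value[bp$t_s < 27]
  after <- bp$value[bp$t_s > 33]
  # squared-amplitude step of 4x, fully resolved one window away
  expect_equal(mean(after) / mean(before), 4, tolerance = 0.05)
})

test_that("band power and theta peak frequency follow the analytic oracles", {
  rec <- tone_recording(8, duration = 20)
  sp <- morlet_spectrogram(rec, freqs = 1:40, step_s = 0.05)
  expect_equal(theta_peak_frequency(sp), 8)
  expect_error(band_power(sp, c(300, 400)), "empty band")

  # equal-amplitude tones at 35 and 90 Hz: in-band means must match the
  # closed-form kernel response summed over the analysis grid (the
  # constant-Q ridge is wider at higher frequency, so the two band means
  # differ by a known factor rather than being equal)
  t <- (0:29999) / 1000
  two <- lfp_recording(cos(2 * pi * 35 * t) + cos(2 * pi * 90 * t),
                       fs = 1000)
  sp2 <- morlet_spectrogram(two, freqs = 1:120, step_s = 0.05)
  slow <- band_power(sp2, "slow")
  fast <- band_power(sp2, "fast")
  oracle_slow <- mean(morlet_tone_power(30:60, 35, 1))
  oracle_fast <- mean(morlet_tone_power(60:120, 90, 1))
  expect_equal(mean(slow$value), oracle_slow, tolerance = 0.03)
  expect_equal(mean(fast$value), oracle_fast, tolerance = 0.03)

  # white noise: total in-band Fourier power ~ bandwidth / Nyquist share
  set.seed(11)
  wn <- lfp_recording(rnorm(30000), fs = 1000)
  spw <- fourier_spectrogram(wn, "theta", step_s = 0.25)
  sel <- spw$freqs >= 4 & spw$freqs <= 12
  frac <- mean(colSums(spw$power[sel, ])) / mean(colSums(spw$power))
  expect_equal(frac, 8 / 500, tolerance = 0.25)
})

test_that("session z-scoring behaves as a z-score and rejects degenerate input", {
  rec <- generate_lfp(synth_spec(noise = list(sd_uv = 10)), 30, 1000,
                      seed = 2)
  bp <- band_power(fourier_spectrogram(rec, "theta", step_s = 0.1), "theta")
  z <- normalized_theta_power(bp)
  expect_equal(mean(z$value), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$value), 1, tolerance = 1e-12)

  # a constructed outlier at mean + 5 sd stays at ~5 after normalization
  v <- c(rnorm(999), 0)
  v[1000] <- mean(v[1:999]) + 5 * stats::sd(v[1:999])
  fake <- bp[1:1000, ]
  fake$value <- v
  attr(fake, "band") <- attr(bp, "band")
  class(fake) <- class(bp)
  z2 <- normalized_theta_power(fake)
  expect_equal(z2$value[1000], 5, tolerance = 0.05)

  const <- bp
  const$value <- rep(1, nrow(bp))
  class(const) <- class(bp)
  expect_error(normalized_theta_power(const), "zero variance")
})

test_that("theta-sorted gamma power is a conservative permutation", {
  rec <- generate_lfp(synth_spec(noise = list(sd_uv = 10),
                                 state = list(mean_on_s = 5,
                                              mean_off_s = 10)),
                      120, 1000, seed = 6)
  spg <- morlet_spectrogram(rec, freqs = 1:100, step_s = 0.1)
  th <- normalized_theta_power(band_power(spg, "theta"))
  gm <- band_power(spg, "slow")
  ts <- theta_sorted_spectrogram(gm, th, n_bins = 20)
  # permutation: multiset of gamma values conserved exactly
  expect_equal(sort(ts$sorted$gamma), sort(gm$value))
  expect_equal(sum(ts$sorted$gamma), sum(gm$value))
  expect_equal(nrow(ts$bins), 20)
  # cumulative distribution ends at 1
  expect_equal(ts$cumulative$cum_gamma_frac[nrow(ts$cumulative)], 1)

  bad <- gm[-1, ]
  class(bad) <- class(gm)
  expect_error(theta_sorted_spectrogram(bad, th), "alignment")
})

test_that("gamma locked to theta amplitude sorts monotonically", {
  # gamma envelope rises with the locomotor state that also drives theta,
  # so per-bin gamma means must increase with normalized theta power
  fs <- 1000
  n <- 120 * fs
  t <- (0:(n - 1)) / fs
  gate <- 0.25 + 0.75 * (sin(2 * pi * t / 30) > 0)
  x <- 100 * gate * cos(2 * pi * 8 * t) +
    20 * gate * cos(2 * pi * 45 * t) + rnorm(n, sd = 5)
  rec <- lfp_recording(x, fs = fs)
  spg <- morlet_spectrogram(rec, freqs = 1:100, step_s = 0.1)
  th <- normalized_theta_power(band_power(spg, "theta"))
  gm <- band_power(spg, "slow")
  ts <- theta_sorted_spectrogram(gm, th, n_bins = 10)
  expect_gt(ts$bins$mean_gamma[10], ts$bins$mean_gamma[1] * 2)
  expect_true(mean(diff(ts$bins$mean_gamma) >= 0) > 0.6)
})
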