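test_that("Hilbert phase advances linearly with 0 deg at the cosine peak", {
  rec <- tone_recording(8, duration = 10)
  ph <- hilbert_phase(rec)
  # 360 deg per 125 ms
  mid <- 2000:6000
  d <- diff(ph$phase_deg[mid]) %% 360
  expect_equal(mean(d), 360 * 8 / 1000, tolerance = 1e-3)
  # phase at the waveform maxima is 0 +- 2 deg
  pk <- which(diff(sign(diff(rec$samples[1, ]))) == -2) + 1
  pk <- pk[pk > 1000 & pk < 9000]
  offs <- gammakit:::circ_diff_deg(ph$phase_deg[pk], 0)
  expect_lt(max(abs(offs)), 2)
  expect_error(hilbert_phase(rec, band = c(4, 600)), "Nyquist")
})

test_that("both phase methods recover the generator's ground-truth phase", {
  spec <- synth_spec(theta = list(freq_hz = 8, amp_uv = 100, asymmetry = 0),
                     noise = list(sd_uv = 5))
  rec <- generate_lfp(spec, 30, 1000, seed = 42)
  gt <- attr(rec, "ground_truth")$theta_phase_deg
  hp <- hilbert_phase(rec)
  wp <- waveform_phase(rec)
  ok <- wp$valid
  ok[1:1000] <- FALSE
  ok[(length(ok) - 999):length(ok)] <- FALSE
  expect_lt(gammakit:::circ_rmse_deg(hp$phase_deg[ok], gt[ok]), 5)
  expect_lt(gammakit:::circ_rmse_deg(wp$phase_deg[ok], gt[ok]), 5)
  # the two methods agree on symmetric theta
  expect_lt(gammakit:::circ_rmse_deg(hp$phase_deg[ok], wp$phase_deg[ok]), 5)
})

test_that("waveform phase tracks asymmetric theta better than Hilbert", {
  spec <- synth_spec(theta = list(freq_hz = 8, amp_uv = 100,
                                  asymmetry = 0.5),
                     noise = list(sd_uv = 5))
  rec <- generate_lfp(spec, 60, 1000, seed = 9)
  gt <- attr(rec, "ground_truth")$theta_phase_deg
  hp <- hilbert_phase(rec)
  wp <- waveform_phase(rec)
  ok <- wp$valid
  e_h <- gammakit:::circ_rmse_deg(hp$phase_deg[ok], gt[ok])
  e_w <- gammakit:::circ_rmse_deg(wp$phase_deg[ok], gt[ok])
  expect_lt(e_w, e_h)
})

test_that("waveform phase is valid only between landmarks and needs cycles", {
  # a single full cycle: valid samples only between first and last landmark
  fs <- 1000
  t <- (0:299) / fs
  rec <- lfp_recording(cos(2 * pi * 8 * t), fs = fs)
  wp <- waveform_phase(rec)
  first_lm <- min(which(wp$valid))
  last_lm <- max(which(wp$valid))
  expect_gt(first_lm, 1)
  expect_lt(last_lm, 300)
  expect_error(waveform_phase(lfp_recording(rep(0, 1000), fs = 1000)),
               "degenerate")
})

test_that("phase methods are rotation-consistent under time shifts", {
  fs <- 1000
  f <- 8
  for (shift_ms in c(31, 62)) {
    t <- (0:(10 * fs - 1)) / fs
    a <- lfp_recording(cos(2 * pi * f * t), fs = fs)
    b <- lfp_recording(cos(2 * pi * f * (t - shift_ms / 1000)), fs = fs)
    for (fun in list(hilbert_phase, waveform_phase)) {
      pa <- fun(a)
      pb <- fun(b)
      ok <- pa$valid & pb$valid
      ok[1:1000] <- FALSE
      ok[(length(ok) - 999):length(ok)] <- FALSE
      d <- gammakit:::circ_mean_deg(
        gammakit:::circ_diff_deg(pa$phase_deg[ok], pb$phase_deg[ok]))
      expected <- 360 * f * shift_ms / 1000
      expect_lt(abs(gammakit:::circ_diff_deg(d, expected)), 3)
    }
  }
})

test_that("phase at generator envelope maxima equals the preferred phase", {
  spec <- coupled_spec(0.8, phi0 = 180, noise_sd = 5)
  rec <- generate_lfp(spec, 60, 1000, seed = 12)
  gt <- attr(rec, "ground_truth")$theta_phase_deg
  hp <- hilbert_phase(rec)
  # envelope maxima are where true theta phase passes phi0 = 180
  # (window wider than the per-sample phase step of ~2.9 deg)
  at_max <- which(abs(gammakit:::circ_diff_deg(gt, 180)) < 2)
  at_max <- at_max[at_max > 1000 & at_max < length(gt) - 1000]
  m <- gammakit:::circ_mean_deg(hp$phase_deg[at_max])
  expect_lt(abs(gammakit:::circ_diff_deg(m, 180)), 9)
})

test_that("theta-state mask flags threshold crossings and bursts", {
  # constructed series crossing z = 2 at known rows
  bp <- tibble::tibble(t_s = seq(0, 99.9, by = 0.1),
                       value = rep(0, 1000))
  class(bp) <- c("band_power_series", class(bp))
  bp$value[301:400] <- 3
  mk <- theta_state_mask(bp, 2)
  expect_equal(range(which(mk$state)), c(301, 400))
  # all-below-threshold: empty mask and downstream insufficient-data
  none <- theta_state_mask(bp, 10)
  expect_false(any(none$state))
  rec <- generate_lfp(coupled_spec(0.5), 20, 1000, seed = 2)
  expect_error(pac_profile(hilbert_phase(rec), rec, "slow", mask = none),
               "insufficient")
})

test_that("theta-state mask recovers generator locomotion bouts", {
  spec <- synth_spec(theta = list(freq_hz = 8, amp_uv = 100),
                     noise = list(sd_uv = 15),
                     state = list(mean_on_s = 15, mean_off_s = 60,
                                  low_gain = 0.15))
  rec <- generate_lfp(spec, 600, 1000, seed = 2)
  gt_on <- attr(rec, "ground_truth")$state_on
  sp <- fourier_spectrogram(rec, "theta", step_s = 0.1)
  z <- normalized_theta_power(band_power(sp, "theta"))
  mk <- theta_state_mask(z, 2)
  gt_at <- stats::approx(rec_times(rec), as.numeric(gt_on), xout = mk$t_s,
                         method = "constant", rule = 2)$y >= 0.5
  jaccard <- sum(mk$state & gt_at) / sum(mk$state | gt_at)
  expect_gte(jaccard, 0.9)
})
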