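# Phase-amplitude coupling: 40-bin profiles, the KL modulation index and
# theta-gamma comodulograms.

PAC_N_BINS <- 40L            # 40 bins of 9 degrees

pac_bin_centers <- function() (seq_len(PAC_N_BINS) - 0.5) * 360 / PAC_N_BINS

phase_to_bin <- function(phase_deg) {
  b <- floor(wrap_deg(phase_deg) / (360 / PAC_N_BINS)) + 1L
  pmin(as.integer(b), PAC_N_BINS)
}

new_pac_profile <- function(amplitude, n_windows, gamma_band, phase_method,
                            shifted = FALSE) {
  amp_nn <- amplitude
  if (any(amp_nn < 0)) amp_nn <- amp_nn - min(amp_nn)
  w <- amp_nn
  if (sum(w) <= 0) w <- rep(1, PAC_N_BINS)
  pref <- circ_mean_deg(pac_bin_centers(), w)
  structure(list(
    profile = tibble::tibble(bin = seq_len(PAC_N_BINS),
                             phase_deg = pac_bin_centers(),
                             amplitude = amplitude),
    mi = kl_modulation_index(amplitude),
    preferred_phase_deg = pref,
    n_windows = n_windows,
    gamma_band = gamma_band,
    phase_method = phase_method,
    shifted = shifted), class = "pac_profile")
}

#' @export
print.pac_profile <- function(x, ...) {
  cat(sprintf(
    "<pac_profile> %d bins, MI = %.4f, preferred phase = %.1f deg (%d windows)\n",
    PAC_N_BINS, x$mi, x$preferred_phase_deg, x$n_windows))
  invisible(x)
}

#' @export
tidy.pac_profile <- function(x, ...) x$profile

#' @export
glance.pac_profile <- function(x, ...) {
  tibble::tibble(mi = x$mi, preferred_phase_deg = x$preferred_phase_deg,
                 n_windows = x$n_windows, shifted = x$shifted)
}

# per-sample gamma power of the z-scored raw trace
gamma_power_samples <- function(rec, gamma_band, channel = 1,
                                power_method = c("wavelet", "envelope"),
                                freq_step = 2.5) {
  power_method <- match.arg(power_method)
  b <- band_range(gamma_band)
  x <- rec$samples[channel, ]
  xz <- (x - mean(x)) / stats::sd(x)      # z-score the raw, unfiltered trace
  zrec <- lfp_recording(xz, fs = rec$fs, valid = rec$valid)
  if (power_method == "wavelet") {
    freqs <- seq(b[1], b[2], by = freq_step)
    sp <- morlet_spectrogram(zrec, freqs = freqs, trim = FALSE)
    colMeans(sp$power)
  } else {
    env <- abs(analytic_signal(bandpass(xz, rec$fs, b[1], b[2])))
    env^2
  }
}

#' Phase-amplitude coupling profile
#'
#' In non-overlapping windows (2 s by default), theta phase is binned into 40
#' bins of 9 degrees and gamma power is averaged per bin; per-window bin
#' means are then averaged across windows. Following the source convention,
#' gamma power is extracted from the z-scored raw (unfiltered) trace, so
#' group differences in absolute gamma power are not normalised away.
#' Windows containing any invalid phase sample, masked-out time or invalid
#' recording sample are excluded.
#'
#' @param phase A `phase_series` (see [hilbert_phase()],
#'   [waveform_phase()]), on the recording's time base.
#' @param rec The [lfp_recording()] supplying gamma amplitude.
#' @param gamma_band `"slow"`, `"fast"` or `c(lo, hi)` Hz.
#' @param window_s Window length in seconds (default 2).
#' @param mask Optional `state_mask` (e.g. [theta_state_mask()]); windows
#'   overlapping masked-out time are dropped.
#' @param min_windows Minimum number of valid windows (default 5).
#' @param power_method `"wavelet"` (Morlet power averaged over in-band
#'   frequencies, default) or `"envelope"` (filter-Hilbert).
#' @param channel Channel index.
#' @return An object of class `pac_profile` with fields `profile` (40-bin
#'   tibble), `mi`, `preferred_phase_deg` (amplitude-weighted circular
#'   mean), `n_windows`.
#' @export
pac_profile <- function(phase, rec, gamma_band = "slow", window_s = 2,
                        mask = NULL, min_windows = 5,
                        power_method = c("wavelet", "envelope"),
                        channel = 1) {
  stopifnot(inherits(phase, "phase_series"), inherits(rec, "lfp_recording"))
  if (nrow(phase) != n_samples(rec))
    stop("alignment error: phase and recording differ in length",
         call. = FALSE)
  gp <- gamma_power_samples(rec, gamma_band, channel, power_method)
  usable <- phase$valid & rec$valid
  if (!is.null(mask)) usable <- usable & mask_at_times(mask, phase$t_s)

  nw <- round(window_s * rec$fs)
  n_win <- floor(n_samples(rec) / nw)
  bins <- phase_to_bin(phase$phase_deg)
  acc <- matrix(NA_real_, n_win, PAC_N_BINS)
  used <- 0L
  for (w in seq_len(n_win)) {
    sel <- ((w - 1) * nw + 1):(w * nw)
    if (!all(usable[sel])) next
    used <- used + 1L
    bw <- bins[sel]
    s <- rowsum(gp[sel], bw)
    cnt <- tabulate(bw, PAC_N_BINS)
    row <- rep(NA_real_, PAC_N_BINS)
    row[sort(unique(bw))] <- s[, 1] / cnt[cnt > 0]
    acc[used, ] <- row
  }
  if (used < min_windows)
    stop("insufficient data: only ", used, " valid window(s)", call. = FALSE)
  amplitude <- colMeans(acc[seq_len(used), , drop = FALSE], na.rm = TRUE)
  new_pac_profile(amplitude, used, band_range(gamma_band),
                  attr(phase, "method"),
                  shifted = any(amplitude < 0))
}

kl_modulation_index <- function(amplitude) {
  a <- amplitude
  if (any(a < 0)) a <- a - min(a)       # KL needs a probability vector
  s <- sum(a)
  if (s <= 0) stop("modulation index undefined: all-zero amplitudes",
                   call. = FALSE)
  p <- a / s
  nz <- p > 0
  n <- length(p)
  sum(p[nz] * log(p[nz] * n)) / log(n)  # D_KL(P || uniform) / log(N)
}

#' Modulation index
#'
#' Kullback-Leibler distance between the phase-binned gamma amplitude
#' distribution and the uniform distribution, normalised by `log(N)` with
#' N = 40 bins, so MI lies in \[0, 1\]: 0 for a flat profile, 1 when all
#' amplitude falls in a single bin. Bin amplitudes are normalised to a
#' probability vector first; profiles in z units containing negative bins
#' are shifted to non-negative (and flagged in the profile) before
#' normalisation.
#'
#' @param x A `pac_profile` or a numeric vector of non-negative bin
#'   amplitudes.
#' @return A dimensionless scalar in \[0, 1\].
#' @export
modulation_index <- function(x) {
  if (inherits(x, "pac_profile")) return(x$mi)
  kl_modulation_index(as.numeric(x))
}

# ---- comodulogram ----------------------------------------------------------

narrowband_phase <- function(xz, fs, f0, halfwidth,
                             method = c("hilbert", "waveform")) {
  method <- match.arg(method)
  xf <- bandpass(xz, fs, max(f0 - halfwidth, 0.5), f0 + halfwidth)
  if (method == "hilbert")
    return(wrap_deg(Arg(analytic_signal(xf)) * 180 / pi))
  rec <- lfp_recording(xf, fs = fs)
  ph <- suppressWarnings(
    waveform_phase(rec, filter_band = c(max(f0 - halfwidth, 0.5),
                                        f0 + halfwidth)))
  out <- ph$phase_deg
  out[!ph$valid] <- NA_real_
  out
}

#' Theta-gamma comodulogram
#'
#' Modulation index over a grid of (phase frequency, amplitude frequency)
#' pairs: narrowband phase at each theta frequency (+-`phase_halfwidth`),
#' amplitude at each gamma frequency (+-`amp_halfwidth`, filter-Hilbert
#' envelope power of the z-scored raw trace), MI on pooled 40-bin profiles.
#'
#' @param rec An [lfp_recording()].
#' @param theta_freqs Phase-frequency grid within 4-12 Hz (default step
#'   0.5 Hz).
#' @param gamma_freqs Amplitude-frequency grid within 30-120 Hz (default
#'   step 2.5 Hz).
#' @param phase_method `"hilbert"` or `"waveform"` (landmark interpolation
#'   on the narrowband trace).
#' @param phase_halfwidth Phase filter half-width in Hz.
#' @param amp_halfwidth Amplitude filter half-width in Hz. The default
#'   (`NULL`) adapts it per phase frequency to `f_theta + 2` Hz: the
#'   amplitude of a gamma oscillation modulated at `f_theta` carries
#'   spectral sidebands at `f_gamma` ± `f_theta`, so the amplitude filter
#'   must be wider than the phase frequency to see the modulation at all,
#'   while staying narrow enough to localise the coupled gamma frequency.
#'   A fixed numeric half-width is accepted; it must not make the bands
#'   overlap.
#' @param mask Optional `state_mask` restricting the analysed samples.
#' @param n_surrogates If > 0, circular-time-shift surrogates of the
#'   amplitude series; the pointwise 95th-percentile MI is returned as
#'   `$mi_threshold`.
#' @param channel Channel index.
#' @param seed Seed for the surrogate shifts.
#' @return An object of class `comodulogram`: `$mi` \[theta x gamma\],
#'   `$theta_freqs`, `$gamma_freqs`, optional `$mi_threshold`.
#' @export
comodulogram <- function(rec, theta_freqs = seq(4, 12, by = 0.5),
                         gamma_freqs = seq(30, 120, by = 2.5),
                         phase_method = c("hilbert", "waveform"),
                         phase_halfwidth = 1, amp_halfwidth = NULL,
                         mask = NULL, n_surrogates = 0, channel = 1,
                         seed = 1L) {
  stopifnot(inherits(rec, "lfp_recording"))
  phase_method <- match.arg(phase_method)
  if (min(theta_freqs) < 4 - 1e-9 || max(theta_freqs) > 12 + 1e-9)
    stop("parameter error: theta grid must lie in 4-12 Hz", call. = FALSE)
  if (min(gamma_freqs) < 30 - 1e-9 || max(gamma_freqs) > 120 + 1e-9)
    stop("parameter error: gamma grid must lie in 30-120 Hz", call. = FALSE)
  lo_guard <- max(theta_freqs) + phase_halfwidth + 0.5
  if (!is.null(amp_halfwidth) &&
      lo_guard >= min(gamma_freqs) - amp_halfwidth)
    stop("parameter error: phase and amplitude bands overlap", call. = FALSE)
  fs <- rec$fs
  x <- rec$samples[channel, ]
  xz <- (x - mean(x)) / stats::sd(x)
  usable <- rec$valid
  if (!is.null(mask)) usable <- usable & mask_at_times(mask, rec_times(rec))
  if (sum(usable) < 10 * fs / min(theta_freqs))
    stop("insufficient data for comodulogram", call. = FALSE)

  mi <- matrix(0, length(theta_freqs), length(gamma_freqs))
  thr <- if (n_surrogates > 0)
    matrix(0, length(theta_freqs), length(gamma_freqs)) else NULL
  set.seed(seed)
  shifts <- if (n_surrogates > 0)
    sample(seq(round(fs), length(xz) - round(fs)), n_surrogates,
           replace = TRUE) else integer(0)
  for (i in seq_along(theta_freqs)) {
    hw <- if (is.null(amp_halfwidth)) theta_freqs[i] + 2 else amp_halfwidth
    ph <- narrowband_phase(xz, fs, theta_freqs[i], phase_halfwidth,
                           phase_method)
    ok <- usable & !is.na(ph)
    bins <- phase_to_bin(ph[ok])
    cnt <- tabulate(bins, PAC_N_BINS)
    for (j in seq_along(gamma_freqs)) {
      lo <- max(gamma_freqs[j] - hw, lo_guard)
      hi <- min(gamma_freqs[j] + hw, fs / 2 - 1)
      a_full <- abs(analytic_signal(bandpass(xz, fs, lo, hi)))^2
      s <- rowsum(a_full[ok], bins)
      prof <- rep(0, PAC_N_BINS)
      prof[sort(unique(bins))] <- s[, 1]
      prof[cnt > 0] <- prof[cnt > 0] / cnt[cnt > 0]
      mi[i, j] <- kl_modulation_index(prof)
      if (n_surrogates > 0) {
        sur <- vapply(shifts, function(sh) {
          a <- c(a_full[(sh + 1):length(a_full)], a_full[1:sh])[ok]
          s2 <- rowsum(a, bins)
          p2 <- rep(0, PAC_N_BINS)
          p2[sort(unique(bins))] <- s2[, 1]
          p2[cnt > 0] <- p2[cnt > 0] / cnt[cnt > 0]
          kl_modulation_index(p2)
        }, numeric(1))
        thr[i, j] <- stats::quantile(sur, 0.95)
      }
    }
  }
  structure(list(mi = mi, theta_freqs = theta_freqs,
                 gamma_freqs = gamma_freqs, mi_threshold = thr,
                 phase_method = phase_method),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  pk <- arrayInd(which.max(x$mi), dim(x$mi))
  cat(sprintf(
    "<comodulogram> %d theta x %d gamma freqs; max MI %.4f at (%g Hz, %g Hz)\n",
    length(x$theta_freqs), length(x$gamma_freqs), max(x$mi),
    x$theta_freqs[pk[1]], x$gamma_freqs[pk[2]]))
  invisible(x)
}

#' @export
tidy.comodulogram <- function(x, ...) {
  tibble::tibble(
    theta_hz = rep(x$theta_freqs, times = length(x$gamma_freqs)),
    gamma_hz = rep(x$gamma_freqs, each = length(x$theta_freqs)),
    mi = as.vector(x$mi))
}

#' Maximum projection of a comodulogram
#'
#' For each gamma (amplitude) frequency, keeps only the theta frequency with
#' maximal coupling — the compact per-gamma coupling profile.
#'
#' @param x A `comodulogram`.
#' @return A tibble: `gamma_hz`, `mi`, `theta_at_max_hz`.
#' @export
max_projection <- function(x) {
  stopifnot(inherits(x, "comodulogram"))
  i <- apply(x$mi, 2, which.max)
  tibble::tibble(gamma_hz = x$gamma_freqs,
                 mi = x$mi[cbind(i, seq_along(x$gamma_freqs))],
                 theta_at_max_hz = x$theta_freqs[i])
}
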