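# Time-frequency decomposition and theta-referenced gamma-power bookkeeping.

new_spectrogram <- function(power, freqs, times, method, params) {
  stopifnot(all(power >= -1e-12), !is.unsorted(freqs), !is.unsorted(times))
  structure(list(power = power, freqs = freqs, times = times,
                 method = method, params = params),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram:%s> %d freqs (%g-%g Hz) x %d times (%.2f-%.2f s)\n",
              x$method, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
tidy.spectrogram <- function(x, ...) {
  tibble::tibble(
    t_s = rep(x$times, each = length(x$freqs)),
    freq_hz = rep(x$freqs, times = length(x$times)),
    power = as.vector(x$power))
}

#' Complex Morlet wavelet spectrogram
#'
#' Continuous wavelet transform with the complex Morlet wavelet, bandwidth
#' parameter 1.0 and centre-frequency parameter 1.5, evaluated per target
#' frequency via FFT convolution. Power is scaled so a sinusoid of amplitude
#' A produces a ridge of height A^2/2 (its variance), commensurate with
#' band-integrated Welch PSD.
#'
#' @param rec An [lfp_recording()] (first channel is analysed unless
#'   `channel` is given).
#' @param freqs Target frequencies in Hz (default 1-120 Hz in 1 Hz steps);
#'   all must lie below Nyquist.
#' @param channel Channel index.
#' @param step_s Output time step in seconds; `NULL` keeps per-sample
#'   resolution.
#' @param trim Drop edge columns within 3 wavelet time-SDs (of the lowest
#'   frequency) of the recording ends, where convolution wraps.
#' @return A `spectrogram` (fields `power` \[freq x time\], `freqs`,
#'   `times`).
#' @export
morlet_spectrogram <- function(rec, freqs = 1:120, channel = 1,
                               step_s = NULL, trim = TRUE) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- rec$fs
  if (max(freqs) >= fs / 2)
    stop("parameter error: frequencies must be below Nyquist", call. = FALSE)
  x <- rec$samples[channel, ]
  n <- length(x)
  fb <- 1.0; fc <- 1.5
  X <- stats::fft(x)
  nu <- (0:(n - 1)) * fs / n            # two-sided grid; keep positive side
  pos <- nu <= fs / 2
  P <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    a <- fc / freqs[i]
    H <- numeric(n)
    H[pos] <- exp(-pi^2 * fb * (a * nu[pos] - fc)^2)  # analytic wavelet
    W <- stats::fft(X * H, inverse = TRUE) / n
    P[i, ] <- 2 * abs(W)^2
  }
  times <- rec$t0 + (0:(n - 1)) / fs
  keep <- rep(TRUE, n)
  if (trim) {
    sigma_t <- (fc / min(freqs)) * sqrt(fb / 2)
    m <- ceiling(3 * sigma_t * fs)
    if (2 * m < n) keep[c(seq_len(m), (n - m + 1):n)] <- FALSE
  }
  if (!is.null(step_s)) {
    stride <- max(1L, round(step_s * fs))
    sel <- seq(1, n, by = stride)
    keep <- keep & seq_len(n) %in% sel
  }
  new_spectrogram(P[, keep, drop = FALSE], freqs, times[keep],
                  "wavelet", list(fb = fb, fc = fc, step_s = step_s))
}

#' Moving-window Fourier spectrogram
#'
#' Hann-tapered moving-window Fourier power: 2 s windows for theta-band use,
#' 5 s windows for gamma-band use, 10 ms steps. Power is per frequency bin
#' (µV²), so the column sum approximates the windowed signal variance
#' (Parseval).
#'
#' @param rec An [lfp_recording()].
#' @param band `"theta"` (2 s window) or `"gamma"` (5 s window); or set
#'   `window_s` directly.
#' @param window_s Window length in seconds (overrides `band`).
#' @param step_s Step between window centres in seconds (default 0.01).
#' @param channel Channel index.
#' @return A `spectrogram` with times at window centres.
#' @export
fourier_spectrogram <- function(rec, band = c("theta", "gamma"),
                                window_s = NULL, step_s = 0.01,
                                channel = 1) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (is.null(window_s))
    window_s <- switch(match.arg(band), theta = 2, gamma = 5)
  fs <- rec$fs
  nw <- round(window_s * fs)
  x <- rec$samples[channel, ]
  if (length(x) < nw)
    stop("insufficient data: recording shorter than one window",
         call. = FALSE)
  stride <- max(1L, round(step_s * fs))
  starts <- seq(1, length(x) - nw + 1, by = stride)
  w <- hann_window(nw)
  # per-bin power scaled so that the column sum equals the (taper-weighted)
  # window variance (Parseval) and a tone of amplitude A contributes A^2/2
  # in total across its spectral peak
  scale <- sum(w^2) * nw
  nfreq <- nw %/% 2 + 1
  P <- matrix(0, nfreq, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + nw - 1)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg)[1:nfreq])^2 / scale
    if (nw %% 2 == 0) p[2:(nfreq - 1)] <- 2 * p[2:(nfreq - 1)]
    else if (nfreq > 1) p[2:nfreq] <- 2 * p[2:nfreq]
    P[, j] <- p
  }
  freqs <- (0:(nfreq - 1)) * fs / nw
  times <- rec$t0 + (starts - 1 + nw / 2) / fs
  new_spectrogram(P, freqs, times, "fourier",
                  list(window_s = window_s, step_s = step_s))
}

#' Band power over time and theta peak frequency
#'
#' `band_power()` averages spectrogram power over in-band frequencies per
#' time step. `theta_peak_frequency()` returns the argmax of the
#' time-averaged theta-band (4-12 Hz) spectrum.
#'
#' @param spec A `spectrogram`.
#' @param band A band name or `c(lo, hi)` in Hz (see [band_range()]).
#' @return `band_power()`: a tibble of class `band_power_series` with
#'   columns `t_s`, `value` and attributes `band`, `normalization`.
#'   `theta_peak_frequency()`: a single frequency in Hz.
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "spectrogram"))
  b <- band_range(band)
  sel <- spec$freqs >= b[1] & spec$freqs <= b[2]
  if (!any(sel)) stop("parameter error: empty band", call. = FALSE)
  out <- tibble::tibble(t_s = spec$times,
                        value = colMeans(spec$power[sel, , drop = FALSE]))
  attr(out, "band") <- b
  attr(out, "normalization") <- "raw"
  class(out) <- c("band_power_series", class(out))
  out
}

#' @rdname band_power
#' @export
theta_peak_frequency <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  b <- band_range("theta")
  sel <- spec$freqs >= b[1] & spec$freqs <= b[2]
  if (!any(sel)) stop("parameter error: spectrogram lacks theta band",
                      call. = FALSE)
  avg <- rowMeans(spec$power[sel, , drop = FALSE])
  spec$freqs[sel][which.max(avg)]
}

#' Session-wide z-scoring of a band-power series
#'
#' Normalized theta power, `(x - mean) / sd` over the whole session, the
#' reference used both for theta-sorted spectrograms and for the 2-SD
#' theta-state criterion.
#'
#' @param series A `band_power_series`.
#' @return A `band_power_series` in z units.
#' @export
normalized_theta_power <- function(series) {
  stopifnot(inherits(series, "band_power_series"))
  if (nrow(series) < 2)
    stop("degenerate input: need at least 2 samples", call. = FALSE)
  s <- stats::sd(series$value)
  if (s == 0) stop("degenerate input: zero variance", call. = FALSE)
  out <- series
  out$value <- (series$value - mean(series$value)) / s
  attr(out, "band") <- attr(series, "band")
  attr(out, "normalization") <- "z"
  out
}

#' Gamma power sorted by normalized theta power
#'
#' Orders time steps by ascending normalized theta power, then reports gamma
#' power per theta-power quantile bin and as a cumulative distribution. The
#' sorting is a pure permutation: the multiset of gamma values (and hence
#' total power) is conserved. Equal-occupancy (quantile) bins compare like
#' behavioural states across sessions of different composition.
#'
#' @param gamma_power A `band_power_series` (raw gamma power).
#' @param theta_norm A `band_power_series` in z units on the same time base.
#' @param n_bins Number of theta-power quantile bins (default 20).
#' @return An object of class `theta_sorted`: `$sorted` (tibble `rank`,
#'   `theta_z`, `gamma`), `$bins` (tibble `bin`, `theta_mid`, `mean_gamma`,
#'   `n`), `$cumulative` (tibble `frac_time`, `cum_gamma_frac`).
#' @export
theta_sorted_spectrogram <- function(gamma_power, theta_norm, n_bins = 20) {
  if (nrow(gamma_power) != nrow(theta_norm) ||
      max(abs(gamma_power$t_s - theta_norm$t_s)) > 1e-6)
    stop("alignment error: series must share a time base", call. = FALSE)
  o <- order(theta_norm$value)
  sorted <- tibble::tibble(rank = seq_along(o),
                           theta_z = theta_norm$value[o],
                           gamma = gamma_power$value[o])
  bin <- ceiling(sorted$rank / (nrow(sorted) / n_bins))
  bin <- pmin(bin, n_bins)
  bins <- sorted |>
    dplyr::mutate(bin = bin) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(theta_mid = stats::median(theta_z),
                     mean_gamma = mean(gamma), n = dplyr::n(),
                     .groups = "drop")
  total <- sum(sorted$gamma)
  cumulative <- tibble::tibble(
    frac_time = sorted$rank / nrow(sorted),
    cum_gamma_frac = cumsum(sorted$gamma) / ifelse(total > 0, total, 1))
  structure(list(sorted = sorted, bins = bins, cumulative = cumulative,
                 n_bins = n_bins),
            class = "theta_sorted")
}

#' @export
print.theta_sorted <- function(x, ...) {
  cat(sprintf("<theta_sorted> %d time steps in %d theta-power bins\n",
              nrow(x$sorted), x$n_bins))
  invisible(x)
}

#' @export
tidy.theta_sorted <- function(x, ...) x$bins
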