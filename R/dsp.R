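# Shared signal-processing primitives.

#' Zero-phase Butterworth band-pass
#'
#' Order-4 Butterworth applied forward and backward (`signal::filtfilt`), so
#' the net response is zero-phase — a requirement for any phase estimation.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz; `lo = 0` gives a low-pass.
#' @param order Filter order before the forward-backward pass.
#' @return Filtered vector, same length as `x`.
#' @export
bandpass <- function(x, fs, lo, hi, order = 4) {
  ny <- fs / 2
  if (hi >= ny) stop("parameter error: band edge at or above Nyquist",
                     call. = FALSE)
  if (lo < 0 || lo >= hi) stop("parameter error: need 0 <= lo < hi",
                               call. = FALSE)
  bf <- if (lo <= 0) signal::butter(order, hi / ny, type = "low")
        else signal::butter(order, c(lo, hi) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# analytic signal via frequency-domain construction: doubles positive
# frequencies, zeroes negatives. Standard Hilbert-transform route; no
# installed package exposes it for signals.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Welch power spectral density
#'
#' Mean modified periodogram over Hann-tapered, 50%-overlapping,
#' mean-detrended segments; one-sided density scaling, so
#' `sum(psd) * df ~ var(x)` and a sinusoid of amplitude A integrates to
#' A^2/2.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length in samples (default: `min(length(x), fs)`,
#'   i.e. up to 1 s).
#' @param overlap Fractional overlap between segments.
#' @return A tibble with columns `freq_hz`, `psd` (µV²/Hz).
#' @export
welch_psd <- function(x, fs, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, round(fs))
  nperseg <- min(nperseg, n)
  step <- max(1, round(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- hann_window(nperseg)
  scale <- fs * sum(w^2)
  nfreq <- nperseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    P <- abs(stats::fft(seg)[1:nfreq])^2 / scale
    acc <- acc + P
  }
  psd <- acc / length(starts)
  # one-sided: double all bins except DC (and Nyquist when present)
  if (nperseg %% 2 == 0) {
    psd[2:(nfreq - 1)] <- 2 * psd[2:(nfreq - 1)]
  } else if (nfreq > 1) {
    psd[2:nfreq] <- 2 * psd[2:nfreq]
  }
  tibble::tibble(freq_hz = (0:(nfreq - 1)) * fs / nperseg, psd = psd)
}

# trapezoidal integral of y(x) over [a, b], interpolating at the limits
trapz_band <- function(x, y, a, b) {
  if (a >= b) stop("parameter error: empty integration band", call. = FALSE)
  a <- max(a, min(x)); b <- min(b, max(x))
  xs <- sort(unique(c(a, b, x[x > a & x < b])))
  ys <- stats::approx(x, y, xout = xs)$y
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Anti-aliased decimation
#'
#' Low-pass (8th-order Chebyshev via `signal::decimate`) then downsample.
#' Acquisition systems often sample at 20+ kHz while every analysed band
#' lies below 250 Hz; decimating to 1 kHz first keeps filters well
#' conditioned.
#'
#' @param rec An [lfp_recording()].
#' @param fs_out Target sampling rate in Hz; must divide `rec$fs`.
#' @return A decimated [lfp_recording()].
#' @export
decimate_recording <- function(rec, fs_out = 1000) {
  q <- rec$fs / fs_out
  if (abs(q - round(q)) > 1e-9)
    stop("parameter error: fs_out must divide fs", call. = FALSE)
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  sam <- t(apply(rec$samples, 1, function(ch)
    signal::decimate(ch, q, ftype = "iir")))
  idx <- seq(1, n_samples(rec), by = q)
  lfp_recording(sam, fs = fs_out, t0 = rec$t0,
                channel_depths = rec$channel_depths, labels = rec$labels,
                valid = rec$valid[idx])
}

# circular helpers (degrees)
wrap_deg <- function(x) ((x %% 360) + 360) %% 360

circ_diff_deg <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  d
}

circ_mean_deg <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  th <- x * pi / 180
  wrap_deg(atan2(sum(w * sin(th)), sum(w * cos(th))) * 180 / pi)
}

circ_rmse_deg <- function(a, b) {
  sqrt(mean(circ_diff_deg(a, b)^2))
}
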