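# Instantaneous theta phase (two extraction methods) and theta-state masking.
#
# Package-wide phase convention: 0 deg at the theta waveform peak, increasing
# through the descending zero crossing (90), trough (180) and ascending zero
# crossing (270).

new_phase_series <- function(t_s, phase_deg, valid, method, band, fs) {
  out <- tibble::tibble(t_s = t_s, phase_deg = phase_deg, valid = valid)
  attr(out, "method") <- method
  attr(out, "band") <- band
  attr(out, "fs") <- fs
  class(out) <- c("phase_series", class(out))
  out
}

#' Instantaneous theta phase via the Hilbert transform
#'
#' Zero-phase band-pass (4th-order Butterworth, forward-backward) followed by
#' the analytic-signal angle. For a cosine-like theta waveform the angle is 0
#' at the peak, matching the package convention.
#'
#' @param rec An [lfp_recording()].
#' @param band Pass band in Hz (default theta, 4-12).
#' @param channel Channel index.
#' @return A tibble of class `phase_series`: `t_s`, `phase_deg` in
#'   \[0, 360), `valid`.
#' @export
hilbert_phase <- function(rec, band = c(4, 12), channel = 1) {
  stopifnot(inherits(rec, "lfp_recording"))
  b <- band_range(band)
  xf <- bandpass(rec$samples[channel, ], rec$fs, b[1], b[2])
  ph <- wrap_deg(Arg(analytic_signal(xf)) * 180 / pi)
  new_phase_series(rec_times(rec), ph, rec$valid, "hilbert", b, rec$fs)
}

# local maxima with a minimum separation, greedy from the highest
find_peaks <- function(x, min_sep) {
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand)
    if (!length(kept) || min(abs(kept - i)) >= min_sep)
      kept <- c(kept, i)
  sort(kept)
}

#' Instantaneous theta phase from waveform landmarks
#'
#' The broad-band waveform method: the raw trace is filtered between 1 and
#' 60 Hz; peaks, troughs and zero crossings are located and assigned phases
#' 0, 90, 180 and 270 degrees, with linear interpolation in between. Unlike
#' the Hilbert angle of a narrow-band filtered trace, this preserves the
#' natural rise/fall asymmetry of theta cycles.
#'
#' Peaks are local maxima of the filtered trace separated by at least 1/12 s
#' (one cycle of the fastest theta); cycles with peak-to-peak duration
#' outside \[1/12, 1/4\] s — outside the 4-12 Hz range — are masked invalid,
#' as are samples before the first and after the last landmark.
#'
#' @param rec An [lfp_recording()].
#' @param channel Channel index.
#' @param filter_band Broad-band filter edges in Hz (default 1-60).
#' @return A tibble of class `phase_series`.
#' @export
waveform_phase <- function(rec, channel = 1, filter_band = c(1, 60)) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- rec$fs
  xf <- bandpass(rec$samples[channel, ], fs,
                 filter_band[1], min(filter_band[2], fs / 2 - 1))
  n <- length(xf)
  if (stats::sd(xf) < 1e-12)
    stop("degenerate input: no detectable cycles", call. = FALSE)
  peaks <- find_peaks(xf, min_sep = fs / 12)
  if (length(peaks) < 2)
    stop("degenerate input: fewer than two theta peaks", call. = FALSE)

  idx <- c(); phs <- c()
  cyc_valid <- rep(FALSE, n)
  for (k in seq_len(length(peaks) - 1)) {
    p1 <- peaks[k]; p2 <- peaks[k + 1]
    dur <- (p2 - p1) / fs
    seg <- xf[p1:p2]
    tr <- p1 + which.min(seg) - 1
    dz <- p1 + which(seg[-length(seg)] >= 0 & seg[-1] < 0)[1] - 1  # desc 0x
    az_rel <- which(seg[-length(seg)] < 0 & seg[-1] >= 0)
    az_rel <- az_rel[p1 + az_rel - 1 > tr][1]
    az <- p1 + az_rel - 1
    lm_i <- c(p1, dz, tr, az)
    lm_p <- 360 * (k - 1) + c(0, 90, 180, 270)
    ok <- !is.na(lm_i)
    lm_i <- lm_i[ok]; lm_p <- lm_p[ok]
    ord <- !duplicated(lm_i) & c(TRUE, diff(lm_i) > 0)
    # keep only strictly increasing landmark chain within the cycle
    keep <- rep(TRUE, length(lm_i))
    last <- -Inf
    for (j in seq_along(lm_i)) {
      if (lm_i[j] <= last) keep[j] <- FALSE else last <- lm_i[j]
    }
    idx <- c(idx, lm_i[keep]); phs <- c(phs, lm_p[keep])
    if (dur >= 1 / 12 && dur <= 1 / 4) cyc_valid[p1:p2] <- TRUE
  }
  idx <- c(idx, peaks[length(peaks)])
  phs <- c(phs, 360 * (length(peaks) - 1))
  dup <- duplicated(idx)
  idx <- idx[!dup]; phs <- phs[!dup]
  o <- order(idx); idx <- idx[o]; phs <- phs[o]

  ph <- rep(NA_real_, n)
  ph[idx[1]:idx[length(idx)]] <-
    stats::approx(idx, phs, xout = idx[1]:idx[length(idx)])$y
  valid <- !is.na(ph) & cyc_valid & rec$valid
  ph[is.na(ph)] <- 0
  new_phase_series(rec_times(rec), wrap_deg(ph), valid, "waveform",
                   filter_band, fs)
}

#' Theta-state mask
#'
#' Marks times where normalized theta power exceeds a z threshold (2 SD by
#' default) — the "theta state" gating of phase-amplitude analyses.
#'
#' @param theta_norm A z-scored `band_power_series`
#'   (see [normalized_theta_power()]).
#' @param threshold Z-score threshold (default 2).
#' @return A tibble of class `state_mask`: `t_s`, `state` (logical).
#' @export
theta_state_mask <- function(theta_norm, threshold = 2) {
  stopifnot(inherits(theta_norm, "band_power_series"), is.finite(threshold))
  out <- tibble::tibble(t_s = theta_norm$t_s,
                        state = theta_norm$value > threshold)
  class(out) <- c("state_mask", class(out))
  out
}

# nearest-neighbour lookup of a (possibly coarser) mask at arbitrary times;
# times outside the mask's span are FALSE
mask_at_times <- function(mask, query_t) {
  if (nrow(mask) == 0) return(rep(FALSE, length(query_t)))
  v <- stats::approx(mask$t_s, as.numeric(mask$state), xout = query_t,
                     method = "constant", rule = 2)$y
  out <- v >= 0.5
  out[query_t < min(mask$t_s) - 1e-9 | query_t > max(mask$t_s) + 1e-9] <- FALSE
  out
}
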