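# Optogenetic-epoch analyses: stimulation/baseline contrasts and
# entrainment fidelity.

epoch_psd <- function(x, fs, nperseg_s) {
  welch_psd(x, fs, nperseg = round(min(length(x) / fs, nperseg_s) * fs))
}

#' Stimulation/baseline power ratio
#'
#' Welch PSD is estimated on each epoch interior (100 ms trimmed from each
#' boundary to discard onset transients; Hann segments of at most 1 s, 50%
#' overlap), integrated over the target band by the trapezoidal rule, and
#' each ON epoch is compared with its immediately preceding OFF epoch — an
#' intra-session control matching the alternating stimulation design.
#'
#' @param rec An [lfp_recording()].
#' @param schedule A [stim_schedule()].
#' @param target Either `list(frequency = f, halfwidth = 0.5)` (integrate
#'   `f` ± halfwidth Hz; `frequency = NULL` uses each ON epoch's
#'   `stim_hz`), or `list(band = c(lo, hi))`.
#' @param trim_s Seconds trimmed from each epoch boundary (default 0.1).
#' @param nperseg_s Welch segment length cap in seconds (default 1).
#' @param pairing `"adjacent"` (default: per ON/OFF pair ratios) or
#'   `"pooled"` (single ratio of mean ON to mean OFF band power).
#' @return An object of class `stim_contrast`: `$pairs` (tibble
#'   `on_start_s, off_start_s, on_power, off_power, ratio`), and via
#'   [glance()] the summary `mean_ratio`, `sem_ratio`, `n_pairs`.
#' @export
stim_baseline_ratio <- function(rec, schedule,
                                target = list(frequency = NULL,
                                              halfwidth = 0.5),
                                trim_s = 0.1, nperseg_s = 1,
                                pairing = c("adjacent", "pooled")) {
  stopifnot(inherits(rec, "lfp_recording"))
  pairing <- match.arg(pairing)
  ep <- extract_epochs(rec, schedule)
  if (!any(ep$label == "ON") || !any(ep$label == "OFF"))
    stop("insufficient data: need at least one ON and one OFF epoch",
         call. = FALSE)
  fs <- rec$fs
  band_for <- function(k) {
    if (!is.null(target$band)) return(target$band)
    hw <- target$halfwidth %||% 0.5
    f <- target$frequency %||% schedule$stim_hz[k]
    if (is.na(f)) f <- stats::na.omit(schedule$stim_hz)[1]
    c(f - hw, f + hw)
  }
  power <- rep(NA_real_, nrow(ep))
  for (k in seq_len(nrow(ep))) {
    i0 <- ep$i0[k] + round(trim_s * fs)
    i1 <- ep$i1[k] - round(trim_s * fs)
    if ((i1 - i0 + 1) / fs < 0.5)
      stop("insufficient data: epoch shorter than 0.5 s after trimming",
           call. = FALSE)
    seg <- rec$samples[1, i0:i1]
    psd <- epoch_psd(seg, fs, nperseg_s)
    b <- band_for(k)
    power[k] <- trapz_band(psd$freq_hz, psd$psd, b[1], b[2])
  }
  on_idx <- which(ep$label == "ON")
  if (pairing == "adjacent") {
    prev_off <- vapply(on_idx, function(k) {
      cand <- which(ep$label == "OFF" & seq_len(nrow(ep)) < k)
      if (length(cand)) max(cand) else NA_integer_
    }, integer(1))
    keep <- !is.na(prev_off)
    pairs <- tibble::tibble(
      on_start_s = ep$start_s[on_idx[keep]],
      off_start_s = ep$start_s[prev_off[keep]],
      on_power = power[on_idx[keep]],
      off_power = power[prev_off[keep]])
  } else {
    off_idx <- which(ep$label == "OFF")
    pairs <- tibble::tibble(on_start_s = NA_real_, off_start_s = NA_real_,
                            on_power = mean(power[on_idx]),
                            off_power = mean(power[off_idx]))
  }
  pairs$ratio <- pairs$on_power / pairs$off_power
  if (any(pairs$ratio <= 0)) stop("non-positive power ratio", call. = FALSE)
  structure(list(pairs = pairs, pairing = pairing, target = target),
            class = "stim_contrast")
}

#' @export
print.stim_contrast <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<stim_contrast> mean ON/OFF ratio %.3f +- %.3f SEM (%d pairs)\n",
              g$mean_ratio, g$sem_ratio, g$n_pairs))
  invisible(x)
}

#' @export
tidy.stim_contrast <- function(x, ...) x$pairs

#' @export
glance.stim_contrast <- function(x, ...) {
  r <- x$pairs$ratio
  tibble::tibble(mean_ratio = mean(r),
                 sem_ratio = stats::sd(r) / sqrt(length(r)),
                 n_pairs = length(r))
}

#' Entrainment fidelity
#'
#' Fraction of theta-band (4-12 Hz) spectral power lying within ±0.5 Hz of
#' the stimulation frequency: a 10 Hz stimulation has fidelity 0.6 when 60%
#' of theta-band power falls between 9.5 and 10.5 Hz. Invariant under
#' amplitude rescaling of the whole signal.
#'
#' @param x An [lfp_recording()], a numeric vector (with `fs`), or a PSD
#'   tibble with columns `freq_hz`, `psd`.
#' @param stim_hz Stimulation frequency in Hz; for theta entrainment it
#'   should lie within the reference band.
#' @param fs Sampling rate in Hz (when `x` is a bare vector).
#' @param band Reference band in Hz (default theta, 4-12).
#' @param halfwidth Integration half-width around `stim_hz` (default 0.5).
#' @param nperseg_s Welch segment length in seconds (default 4, for 0.25 Hz
#'   resolution).
#' @return Fidelity as a fraction in \[0, 1\].
#' @export
entrainment_fidelity <- function(x, stim_hz, fs = NULL, band = c(4, 12),
                                 halfwidth = 0.5, nperseg_s = 4) {
  psd <- if (inherits(x, "lfp_recording")) {
    welch_psd(x$samples[1, ], x$fs,
              nperseg = round(min(duration(x), nperseg_s) * x$fs))
  } else if (is.data.frame(x)) {
    stopifnot(all(c("freq_hz", "psd") %in% names(x)))
    x
  } else {
    if (is.null(fs)) stop("fs required for a bare signal", call. = FALSE)
    welch_psd(x, fs, nperseg = round(min(length(x) / fs, nperseg_s) * fs))
  }
  denom <- trapz_band(psd$freq_hz, psd$psd, band[1], band[2])
  if (denom <= 0)
    stop("degenerate input: zero power in the reference band", call. = FALSE)
  num <- trapz_band(psd$freq_hz, psd$psd,
                    stim_hz - halfwidth, stim_hz + halfwidth)
  num / denom
}
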