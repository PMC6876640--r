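# Synthetic LFP, laminar profiles and behavioural tracks with known ground
# truth, so every analysis stage can be checked by parameter recovery.

#' Named frequency bands
#'
#' Canonical hippocampal bands: theta 4-12 Hz, slow gamma 30-60 Hz, fast
#' gamma 60-120 Hz.
#'
#' @param band A name (`"theta"`, `"slow"`, `"fast"`) or a numeric
#'   `c(lo, hi)` pair, returned unchanged.
#' @return Numeric `c(lo, hi)` in Hz.
#' @export
band_range <- function(band) {
  if (is.numeric(band)) {
    stopifnot(length(band) == 2, band[1] < band[2])
    return(band)
  }
  switch(match.arg(band, c("theta", "slow", "fast")),
         theta = c(4, 12), slow = c(30, 60), fast = c(60, 120))
}

#' Specification of a synthetic theta-nested-gamma LFP
#'
#' Describes the generative model: a (possibly asymmetric) theta oscillation
#' whose amplitude can follow a slow locomotor state, gamma components whose
#' envelopes are modulated by theta phase with coupling strength `kappa` and
#' preferred phase `phi0_deg`, and a 1/f background.
#'
#' Asymmetric theta is produced by phase-warping a sinusoid:
#' `psi = theta + asymmetry * sin(theta)`, a monotone reparameterisation for
#' `asymmetry < 1` that sharpens the rise and stretches the fall while
#' keeping the true instantaneous phase available analytically. The gamma
#' envelope is `A * (1 + kappa * cos(psi - phi0)) / (1 + kappa)`, which is
#' non-negative and phase-independent at `kappa = 0`.
#'
#' @param theta List: `freq_hz` in \[4, 12\], `amp_uv`, `asymmetry` in
#'   \[0, 1), and optionally `freq_drift_sd_hz` / `drift_tau_s`: a slow
#'   Ornstein-Uhlenbeck wander of the instantaneous theta frequency (SD in
#'   Hz, correlation time in s) emulating the natural cycle-to-cycle
#'   frequency variability of theta; 0 disables it.
#' @param gamma List of components, each a list with `band` (`"slow"`,
#'   `"fast"` or `c(lo, hi)`), `amp_uv`, `kappa` (>= 0), `phi0_deg`,
#'   optional `carrier` (`"noise"` narrowband-filtered white noise, the
#'   bursty default, or `"tone"` at the band centre).
#' @param noise List: `exponent` of the 1/f background, `sd_uv`.
#' @param state Optional locomotor-state modulation of theta amplitude:
#'   `mean_on_s`, `mean_off_s` (exponential bout/pause durations),
#'   `low_gain` (theta amplitude multiplier outside bouts).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(theta = list(freq_hz = 8, amp_uv = 100,
                                    asymmetry = 0),
                       gamma = list(),
                       noise = list(exponent = 1, sd_uv = 10),
                       state = NULL) {
  theta <- utils::modifyList(list(freq_hz = 8, amp_uv = 100, asymmetry = 0,
                                  freq_drift_sd_hz = 0, drift_tau_s = 2),
                             theta)
  if (theta$freq_hz < 4 || theta$freq_hz > 12)
    stop("theta frequency must lie in 4-12 Hz", call. = FALSE)
  if (theta$asymmetry < 0 || theta$asymmetry >= 1)
    stop("asymmetry must lie in [0, 1)", call. = FALSE)
  gamma <- purrr::map(gamma, function(g) {
    g <- utils::modifyList(list(band = "slow", amp_uv = 20, kappa = 0,
                                phi0_deg = 0, carrier = "noise"), g)
    g$band <- band_range(g$band)
    if (g$kappa < 0) stop("kappa must be >= 0", call. = FALSE)
    g
  })
  noise <- utils::modifyList(list(exponent = 1, sd_uv = 10), noise)
  if (!is.null(state))
    state <- utils::modifyList(list(mean_on_s = 15, mean_off_s = 60,
                                    low_gain = 0.2), state)
  structure(list(theta = theta, gamma = gamma, noise = noise, state = state),
            class = "synth_spec")
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483647)
}

onef_noise <- function(n, fs, exponent, sd_uv, seed) {
  set.seed(seed)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                 # avoid 0; DC handled below
  f <- pmin(f, n - f + 1) * fs / n          # two-sided frequency magnitudes
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(W * shape, inverse = TRUE) / n)
  x <- x - mean(x)
  x / stats::sd(x) * sd_uv
}

state_gain <- function(n, fs, state, seed) {
  set.seed(seed)
  on <- logical(0)
  while (length(on) < n) {
    off_len <- max(1, round(stats::rexp(1, 1 / state$mean_off_s) * fs))
    on_len <- max(1, round(stats::rexp(1, 1 / state$mean_on_s) * fs))
    on <- c(on, rep(FALSE, off_len), rep(TRUE, on_len))
  }
  on <- on[seq_len(n)]
  # smooth the gate with a short raised-cosine so theta amplitude ramps
  k <- hann_window(max(3, round(0.25 * fs)))
  k <- k / sum(k)
  g <- stats::filter(as.numeric(on), k, sides = 2)
  g[is.na(g)] <- as.numeric(on)[is.na(g)]
  list(gain = state$low_gain + (1 - state$low_gain) * as.numeric(g),
       on = on)
}

#' Generate a synthetic LFP recording
#'
#' Deterministic for a fixed seed; independent random streams are derived
#' from the master seed for the background, each gamma carrier and the
#' locomotor state, so changing one component leaves the others untouched.
#'
#' @param spec A [synth_spec()].
#' @param duration_s Length in seconds (at least 10 theta cycles).
#' @param fs Sampling rate in Hz.
#' @param seed Master seed (required).
#' @param stim Optional stimulation-locked component:
#'   `list(schedule = stim_schedule, amp_uv = ..., ramp_ms = 20)` adds a
#'   sinusoid at the schedule's `stim_hz` during ON epochs with raised-cosine
#'   on/off ramps.
#' @return An [lfp_recording()] (single channel) with a `ground_truth`
#'   attribute: the true theta phase in degrees per sample
#'   (`theta_phase_deg`), the locomotor-state gate (`state_on`), and the
#'   gamma component table.
#' @export
generate_lfp <- function(spec, duration_s, fs = 1000, seed, stim = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  n <- round(duration_s * fs)
  if (n / fs * spec$theta$freq_hz < 10)
    stop("duration must cover at least 10 theta cycles", call. = FALSE)
  t <- (0:(n - 1)) / fs
  if (spec$theta$freq_drift_sd_hz > 0) {
    set.seed(derive_seed(seed, 6))
    a <- exp(-1 / (spec$theta$drift_tau_s * fs))
    innov <- stats::rnorm(n, sd = spec$theta$freq_drift_sd_hz *
                            sqrt(1 - a^2))
    drift <- as.numeric(stats::filter(innov, a, method = "recursive"))
    f_inst <- spec$theta$freq_hz + drift
    theta_lin <- 2 * pi * cumsum(f_inst) / fs
  } else {
    theta_lin <- 2 * pi * spec$theta$freq_hz * t
  }
  psi <- theta_lin + spec$theta$asymmetry * sin(theta_lin)

  gate <- list(gain = rep(1, n), on = rep(TRUE, n))
  if (!is.null(spec$state))
    gate <- state_gain(n, fs, spec$state, derive_seed(seed, 1))
  x <- spec$theta$amp_uv * gate$gain * cos(psi)

  comps <- list()
  for (i in seq_along(spec$gamma)) {
    g <- spec$gamma[[i]]
    if (g$amp_uv <= 0) {
      if (g$kappa > 0)
        warning("gamma component with zero amplitude dropped", call. = FALSE)
      next
    }
    env <- g$amp_uv * (1 + g$kappa * cos(psi - g$phi0_deg * pi / 180)) /
      (1 + g$kappa)
    if (g$carrier == "tone") {
      set.seed(derive_seed(seed, 10 + i))
      ph <- stats::runif(1, 0, 2 * pi)
      carrier <- cos(2 * pi * mean(g$band) * t + ph)
    } else {
      set.seed(derive_seed(seed, 10 + i))
      carrier <- bandpass(stats::rnorm(n), fs, g$band[1], g$band[2])
      carrier <- carrier / stats::sd(carrier) / sqrt(2)  # RMS of unit tone
    }
    x <- x + env * carrier
    comps[[length(comps) + 1]] <-
      tibble::tibble(band_lo = g$band[1], band_hi = g$band[2],
                     amp_uv = g$amp_uv, kappa = g$kappa,
                     phi0_deg = g$phi0_deg, carrier = g$carrier)
  }
  if (spec$noise$sd_uv > 0)
    x <- x + onef_noise(n, fs, spec$noise$exponent, spec$noise$sd_uv,
                        derive_seed(seed, 2))
  if (!is.null(stim))
    x <- x + stim_component(n, fs, stim)

  rec <- lfp_recording(x, fs = fs)
  attr(rec, "ground_truth") <- list(
    theta_phase_deg = wrap_deg(psi * 180 / pi),
    state_on = gate$on,
    theta = spec$theta,
    gamma = if (length(comps)) dplyr::bind_rows(comps) else NULL)
  rec
}

stim_component <- function(n, fs, stim) {
  stim <- utils::modifyList(list(amp_uv = 0, ramp_ms = 20), stim)
  sched <- stim$schedule
  out <- numeric(n)
  if (stim$amp_uv <= 0) return(out)
  t <- (0:(n - 1)) / fs
  ramp_n <- max(1, round(stim$ramp_ms / 1000 * fs))
  on <- sched[sched$state == "ON", ]
  for (j in seq_len(nrow(on))) {
    i0 <- max(1, floor(on$start_s[j] * fs) + 1)
    i1 <- min(n, floor(on$end_s[j] * fs))
    if (i1 <= i0) next
    if (stim$ramp_ms / 1000 >= (i1 - i0) / fs)
      stop("ramp must be shorter than the epoch", call. = FALSE)
    idx <- i0:i1
    envl <- rep(1, length(idx))
    r <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2
    envl[seq_len(ramp_n)] <- r
    envl[length(envl) - ramp_n + seq_len(ramp_n)] <- rev(r)
    out[idx] <- out[idx] +
      stim$amp_uv * envl * sin(2 * pi * on$stim_hz[j] * t[idx])
  }
  out
}

# ---- laminar ---------------------------------------------------------------

#' Specification of a synthetic laminar (multi-channel) recording
#'
#' A common theta+gamma signal is projected across depth: a Gaussian dipole
#' kernel carries the gamma-rich component (known analytic second spatial
#' derivative, the CSD ground truth); theta flips sign at `reversal_um`,
#' emulating the radiatum-to-lacunosum-moleculare phase reversal; a
#' ripple-band component has a Gaussian depth profile peaking at the putative
#' pyramidal layer.
#'
#' @param n_channels Number of channels (>= 3; default 16).
#' @param spacing_um Inter-channel spacing in µm (default 50).
#' @param dipole List: `sink_um`, `source_um` (`NA` for a monopolar sink),
#'   `width_um`, `amp` (gain applied to the gamma-rich component).
#' @param ripple List: `peak_um` depth of maximal ripple amplitude,
#'   `width_um`, `amp_uv`, `band` (default 100-250 Hz).
#' @param reversal_um Depth of the theta phase reversal (`NA` for none).
#' @param theta_amp_uv Theta amplitude common to all channels.
#' @param noise_sd_uv Per-channel independent white noise.
#' @return A list of class `laminar_spec`.
#' @export
laminar_spec <- function(n_channels = 16, spacing_um = 50,
                         dipole = list(sink_um = 350, source_um = NA,
                                       width_um = 100, amp = 1),
                         ripple = list(peak_um = 100, width_um = 75,
                                       amp_uv = 20, band = c(100, 250)),
                         reversal_um = NA, theta_amp_uv = 50,
                         noise_sd_uv = 2) {
  if (n_channels < 3)
    stop("CSD-untestable: need at least 3 channels", call. = FALSE)
  if (spacing_um <= 0) stop("spacing must be positive", call. = FALSE)
  dipole <- utils::modifyList(list(sink_um = 350, source_um = NA,
                                   width_um = 100, amp = 1), dipole)
  if (!is.na(dipole$source_um) &&
      isTRUE(all.equal(dipole$sink_um, dipole$source_um)))
    stop("sink and source depths must differ", call. = FALSE)
  ripple <- utils::modifyList(list(peak_um = 100, width_um = 75,
                                   amp_uv = 20, band = c(100, 250)), ripple)
  structure(list(n_channels = n_channels, spacing_um = spacing_um,
                 dipole = dipole, ripple = ripple,
                 reversal_um = reversal_um, theta_amp_uv = theta_amp_uv,
                 noise_sd_uv = noise_sd_uv),
            class = "laminar_spec")
}

dipole_kernel <- function(depths, dipole) {
  k <- exp(-(depths - dipole$sink_um)^2 / (2 * dipole$width_um^2))
  if (!is.na(dipole$source_um))
    k <- k - exp(-(depths - dipole$source_um)^2 / (2 * dipole$width_um^2))
  dipole$amp * k
}

#' Generate a synthetic laminar recording
#'
#' @param lspec A [laminar_spec()].
#' @param base A [synth_spec()] supplying the depth-projected theta/gamma
#'   signal (its noise is applied per channel by `lspec$noise_sd_uv`
#'   instead).
#' @param duration_s,fs,seed As in [generate_lfp()].
#' @return A multichannel [lfp_recording()] with ground truth in the
#'   `ground_truth` attribute: the dipole kernel per channel, its exact
#'   discrete second difference at interior channels
#'   (`kernel_second_diff`, already divided by spacing squared), the ripple
#'   amplitude profile and the theta sign per channel.
#' @export
generate_laminar <- function(lspec, base = synth_spec(), duration_s,
                             fs = 1000, seed) {
  stopifnot(inherits(lspec, "laminar_spec"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  depths <- (seq_len(lspec$n_channels) - 1) * lspec$spacing_um
  n <- round(duration_s * fs)
  t <- (0:(n - 1)) / fs

  base_noise <- base$noise
  base$noise$sd_uv <- 0
  mono <- generate_lfp(base, duration_s, fs, seed = seed)
  gt_base <- attr(mono, "ground_truth")
  theta_sig <- lspec$theta_amp_uv *
    cos(gt_base$theta_phase_deg * pi / 180)
  gamma_sig <- mono$samples[1, ] - base$theta$amp_uv *
    cos(gt_base$theta_phase_deg * pi / 180)

  kern <- dipole_kernel(depths, lspec$dipole)
  theta_sign <- if (is.na(lspec$reversal_um)) rep(1, lspec$n_channels)
                else ifelse(depths < lspec$reversal_um, 1, -1)
  ripple_amp <- lspec$ripple$amp_uv *
    exp(-(depths - lspec$ripple$peak_um)^2 / (2 * lspec$ripple$width_um^2))
  set.seed(derive_seed(seed, 3))
  ripple_sig <- bandpass(stats::rnorm(n), fs, lspec$ripple$band[1],
                         min(lspec$ripple$band[2], fs / 2 - 1))
  ripple_sig <- ripple_sig / stats::sd(ripple_sig)

  sam <- matrix(0, lspec$n_channels, n)
  set.seed(derive_seed(seed, 4))
  for (i in seq_len(lspec$n_channels)) {
    sam[i, ] <- kern[i] * gamma_sig + theta_sign[i] * theta_sig +
      ripple_amp[i] * ripple_sig +
      stats::rnorm(n, sd = lspec$noise_sd_uv)
  }
  rec <- lfp_recording(sam, fs = fs, channel_depths = depths)
  interior <- 2:(lspec$n_channels - 1)
  d2 <- (2 * kern[interior] - kern[interior + 1] - kern[interior - 1]) /
    lspec$spacing_um^2
  attr(rec, "ground_truth") <- list(
    kernel = kern, kernel_second_diff = d2, ripple_amp = ripple_amp,
    theta_sign = theta_sign, depths = depths, base = gt_base)
  rec
}

# ---- behaviour -------------------------------------------------------------

#' Generate a synthetic behaviour track
#'
#' Gaussian-step random walk with reflecting boundaries on a circular
#' platform or square open field. In `"uniform"` mode the long-run occupancy
#' converges to uniform over the arena (the chance condition for quadrant
#' statistics). In `"object-biased"` mode a smooth attraction toward one
#' named landmark concentrates dwell time near it. The nose leads the body
#' by `nose_lead_cm` along the heading; near an attended object it points at
#' the object.
#'
#' @param arena `list(shape = "circle", radius_cm = ...)` or
#'   `list(shape = "square", side_cm = ...)`.
#' @param mode `"uniform"` or `"object-biased"`.
#' @param duration_s Track length in seconds; 0 yields an empty track.
#' @param fs Position sampling rate in Hz (default 10, a typical camera
#'   rate).
#' @param seed Master seed.
#' @param step_sd_cm Per-sample step standard deviation; must be smaller
#'   than the arena.
#' @param landmarks Named list of `c(x, y)` points in cm.
#' @param bias_to Landmark name attracting the walk in object-biased mode.
#' @param bias_strength Drift gain (cm per sample at the attraction peak).
#' @param nose_lead_cm Nose-ahead-of-body distance.
#' @return A [behavior_track()] with nose positions.
#' @export
generate_track <- function(arena, mode = c("uniform", "object-biased"),
                           duration_s, fs = 10, seed,
                           step_sd_cm = 3, landmarks = list(),
                           bias_to = NULL, bias_strength = 2.5,
                           nose_lead_cm = 2) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  half <- arena_halfwidth(arena)
  if (step_sd_cm >= 2 * half)
    stop("parameter error: step size must be smaller than the arena",
         call. = FALSE)
  n <- round(duration_s * fs)
  if (n == 0)
    return(behavior_track(numeric(0), matrix(numeric(0), ncol = 2),
                          matrix(numeric(0), ncol = 2), arena = arena,
                          landmarks = landmarks))
  if (mode == "object-biased") {
    if (is.null(bias_to) || is.null(landmarks[[bias_to]]))
      stop("object-biased mode needs `bias_to` naming a landmark",
           call. = FALSE)
    obj <- landmarks[[bias_to]]
  }
  set.seed(derive_seed(seed, 5))
  steps <- matrix(stats::rnorm(2 * n, sd = step_sd_cm), ncol = 2)
  pos <- matrix(0, n, 2)
  p <- c(0, 0)
  for (k in seq_len(n)) {
    d <- steps[k, ]
    if (mode == "object-biased") {
      v <- obj - p
      dist <- sqrt(sum(v^2))
      if (dist > 1e-6)
        d <- d + bias_strength * v / dist * exp(-dist^2 / (2 * 15^2))
    }
    p <- reflect_into(p + d, arena)
    pos[k, ] <- p
  }
  heading <- rbind(pos[2, ] - pos[1, ], diff(pos))
  hn <- sqrt(rowSums(heading^2))
  hn[hn < 1e-9] <- 1
  nose <- pos + heading / hn * nose_lead_cm
  # the nose orients toward the nearest landmark when the animal is close,
  # emulating investigative approach regardless of walk mode
  if (length(landmarks)) {
    lmx <- do.call(rbind, landmarks)
    for (k in seq_len(n)) {
      d2 <- (lmx[, 1] - pos[k, 1])^2 + (lmx[, 2] - pos[k, 2])^2
      j <- which.min(d2)
      dist <- sqrt(d2[j])
      if (dist < 6 && dist > 1e-6) {
        v <- c(lmx[j, 1], lmx[j, 2]) - pos[k, ]
        nose[k, ] <- pos[k, ] + v / dist * min(nose_lead_cm, dist)
      }
    }
  }
  nose[, 1] <- pmin(pmax(nose[, 1], -half), half)
  nose[, 2] <- pmin(pmax(nose[, 2], -half), half)
  if (arena$shape == "circle") {
    r <- sqrt(rowSums(nose^2))
    out <- r > half
    nose[out, ] <- nose[out, ] * (half / r[out])
  }
  behavior_track((0:(n - 1)) / fs, pos, nose, arena = arena,
                 landmarks = landmarks)
}

reflect_into <- function(p, arena) {
  half <- arena_halfwidth(arena)
  if (arena$shape == "square") {
    for (i in 1:2) {
      while (p[i] > half || p[i] < -half) {
        if (p[i] > half) p[i] <- 2 * half - p[i]
        if (p[i] < -half) p[i] <- -2 * half - p[i]
      }
    }
  } else {
    r <- sqrt(sum(p^2))
    while (r > half) {
      p <- p * (2 * half - r) / r
      r <- sqrt(sum(p^2))
    }
  }
  p
}
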