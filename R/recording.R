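#' Construct an LFP recording
#'
#' The central container for continuous extracellular recordings. Samples are
#' stored as a channel-by-time matrix in microvolts. Laminar probes declare a
#' monotone per-channel depth (channel 1 = most superficial); single
#' microelectrodes use a single depth entry. Gaps are represented by an
#' explicit validity mask, never by `NA`, so that filtering stays well
#' defined; downstream windowed analyses drop windows that touch an invalid
#' sample.
#'
#' @param samples Numeric matrix, channels in rows, time in columns (µV). A
#'   plain vector is treated as a single channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start time in seconds.
#' @param channel_depths Per-channel depth in µm; length must equal the number
#'   of channels.
#' @param labels Optional per-channel layer tag: `"pyr"`, `"rad"`, `"lm"` or
#'   `"unknown"`.
#' @param valid Optional logical vector (one entry per time sample), `TRUE`
#'   where the signal is usable.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, fs, t0 = 0, channel_depths = NULL,
                          labels = NULL, valid = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (anyNA(samples))
    stop("samples must not contain NA; mark gaps with the `valid` mask",
         call. = FALSE)
  n_ch <- nrow(samples)
  if (is.null(channel_depths)) channel_depths <- seq_len(n_ch) * 0
  if (length(channel_depths) != n_ch)
    stop("`channel_depths` must have one entry per channel", call. = FALSE)
  if (is.null(labels)) labels <- rep("unknown", n_ch)
  labels <- match.arg(labels, c("pyr", "rad", "lm", "unknown"),
                      several.ok = TRUE)
  if (length(labels) == 1) labels <- rep(labels, n_ch)
  if (is.null(valid)) valid <- rep(TRUE, ncol(samples))
  if (length(valid) != ncol(samples) || !is.logical(valid))
    stop("`valid` must be a logical vector with one entry per time sample",
         call. = FALSE)
  structure(
    list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0),
         channel_depths = as.numeric(channel_depths), labels = labels,
         valid = valid),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              n_channels(x), n_samples(x), x$fs, duration(x)))
  if (n_channels(x) > 1)
    cat(sprintf("  depths: %g..%g um (spacing %g um)\n",
                min(x$channel_depths), max(x$channel_depths),
                channel_spacing(x)))
  invisible(x)
}

#' @rdname lfp_recording
#' @param rec An `lfp_recording`.
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' @rdname lfp_recording
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' @rdname lfp_recording
#' @export
duration <- function(rec) n_samples(rec) / rec$fs

#' @rdname lfp_recording
#' @export
rec_times <- function(rec) rec$t0 + (seq_len(n_samples(rec)) - 1) / rec$fs

channel_spacing <- function(rec) {
  d <- diff(rec$channel_depths)
  if (length(d) == 0) return(NA_real_)
  mean(d)
}

#' Tidy an LFP recording into a long tibble
#'
#' One row per (channel, time sample): columns `t_s`, `channel`, `depth_um`,
#' `uv`, `valid`. Intended for small excerpts and plotting; for long
#' recordings subset first.
#'
#' @param x An `lfp_recording`.
#' @param ... Unused.
#' @export
tidy.lfp_recording <- function(x, ...) {
  t <- rec_times(x)
  tibble::tibble(
    t_s = rep(t, each = n_channels(x)),
    channel = rep(seq_len(n_channels(x)), times = n_samples(x)),
    depth_um = rep(x$channel_depths, times = n_samples(x)),
    uv = as.vector(x$samples),
    valid = rep(x$valid, each = n_channels(x)))
}

# ---- container I/O: flat binary payload + JSON sidecar ----------------------

sidecar_path <- function(path) paste0(path, ".json")

#' Write an LFP recording to disk
#'
#' Stores the sample payload as flat binary (channel-interleaved,
#' little-endian) next to a JSON sidecar (`<path>.json`) declaring sampling
#' rate, geometry and encoding. `int16` encoding applies the declared
#' µV-per-bit scale; `float64` is lossless.
#'
#' @param rec An [lfp_recording()].
#' @param path Payload file path; the sidecar is written at `<path>.json`.
#' @param encoding `"int16"` (with `scale_uv` µV/bit) or `"float64"`.
#' @param scale_uv Scale in µV per bit for `int16` encoding.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, encoding = c("float64", "int16"),
                            scale_uv = 0.195) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(rec, "lfp_recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  x <- as.vector(rec$samples)           # channel-interleaved (column major)
  if (encoding == "int16") {
    q <- as.integer(round(x / scale_uv))
    if (any(abs(q) > 32767))
      stop("samples exceed int16 range at this scale", call. = FALSE)
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.double(x), con, size = 8, endian = "little")
  }
  invalid <- invalid_runs(rec$valid)
  meta <- list(
    fs = rec$fs, t0 = rec$t0,
    n_channels = n_channels(rec), n_samples = n_samples(rec),
    channel_depths_um = rec$channel_depths, labels = rec$labels,
    encoding = encoding, byte_order = "little",
    invalid_runs = invalid)
  if (encoding == "int16") meta$scale_uv <- scale_uv
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

invalid_runs <- function(valid) {
  r <- rle(!valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(list())
  purrr::map2(starts[keep], ends[keep], ~ c(.x, .y))
}

#' Read an LFP recording from disk
#'
#' Counterpart of [write_recording()]. The sidecar is authoritative: a payload
#' shorter than `n_channels * n_samples` raises an integrity error, missing
#' required fields a format error.
#'
#' @param path Payload file path (sidecar expected at `<path>.json`).
#' @return An [lfp_recording()].
#' @export
read_recording <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(path)) stop("payload not found: ", path, call. = FALSE)
  if (!file.exists(sc)) stop("format error: sidecar not found: ", sc,
                             call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  required <- c("fs", "n_channels", "n_samples", "encoding")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("format error: sidecar lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  if (meta$encoding == "int16") {
    raw_vals <- readBin(con, integer(), n = n, size = 2, endian = "little")
    if (length(raw_vals) < n)
      stop("integrity error: payload truncated (", length(raw_vals), " of ",
           n, " samples)", call. = FALSE)
    if (is.null(meta$scale_uv))
      stop("format error: int16 encoding requires scale_uv", call. = FALSE)
    x <- raw_vals * meta$scale_uv
  } else if (meta$encoding == "float64") {
    x <- readBin(con, double(), n = n, size = 8, endian = "little")
    if (length(x) < n)
      stop("integrity error: payload truncated (", length(x), " of ", n,
           " samples)", call. = FALSE)
  } else {
    stop("format error: unknown encoding ", meta$encoding, call. = FALSE)
  }
  valid <- rep(TRUE, meta$n_samples)
  if (!is.null(meta$invalid_runs) && length(meta$invalid_runs)) {
    runs <- meta$invalid_runs
    if (is.matrix(runs)) runs <- split(runs, seq_len(nrow(runs)))
    for (r in runs) valid[r[[1]]:r[[2]]] <- FALSE
  }
  depths <- meta$channel_depths_um
  if (is.null(depths)) depths <- rep(0, meta$n_channels)
  labels <- meta$labels
  if (is.null(labels)) labels <- rep("unknown", meta$n_channels)
  lfp_recording(matrix(x, nrow = meta$n_channels), fs = meta$fs,
                t0 = meta$t0 %||% 0, channel_depths = depths,
                labels = labels, valid = valid)
}

# ---- stimulation schedules --------------------------------------------------

#' Build a stimulation schedule tibble
#'
#' Ordered, non-overlapping ON/OFF epochs driving epoching and entrainment
#' metrics. `duty_cycle` defaults to 0.5: stimulation pulses occupy half of
#' each period, so total illumination is frequency-independent.
#'
#' @param start_s,end_s Epoch boundaries in seconds.
#' @param state `"ON"` or `"OFF"` per epoch.
#' @param stim_hz Stimulation frequency in Hz (required > 0 for ON epochs).
#' @param duty_cycle Fraction of each stimulation period with light on, in
#'   (0, 1].
#' @param wavelength_nm Nominal light wavelength (metadata only).
#' @return A tibble of class `stim_schedule` with columns
#'   `start_s, end_s, state, stim_hz, duty_cycle`.
#' @export
stim_schedule <- function(start_s, end_s, state, stim_hz = NA_real_,
                          duty_cycle = 0.5, wavelength_nm = NA_real_) {
  sched <- tibble::tibble(
    start_s = as.numeric(start_s), end_s = as.numeric(end_s),
    state = toupper(as.character(state)),
    stim_hz = as.numeric(stim_hz),
    duty_cycle = as.numeric(duty_cycle))
  if (!all(sched$state %in% c("ON", "OFF")))
    stop("state must be ON or OFF", call. = FALSE)
  if (any(sched$end_s <= sched$start_s))
    stop("epochs must have end_s > start_s", call. = FALSE)
  o <- order(sched$start_s)
  sched <- sched[o, ]
  if (nrow(sched) > 1 &&
      any(sched$start_s[-1] < sched$end_s[-nrow(sched)] - 1e-9))
    stop("epochs must be non-overlapping and time-ordered", call. = FALSE)
  if (any(sched$state == "ON" &
            (is.na(sched$stim_hz) | sched$stim_hz <= 0)))
    stop("ON epochs require stim_hz > 0", call. = FALSE)
  if (any(!is.na(sched$duty_cycle) &
          (sched$duty_cycle <= 0 | sched$duty_cycle > 1)))
    stop("duty_cycle must lie in (0, 1]", call. = FALSE)
  attr(sched, "wavelength_nm") <- wavelength_nm
  class(sched) <- c("stim_schedule", class(sched))
  sched
}

#' Alternating ON/OFF schedule
#'
#' Convenience constructor for the alternating paradigms used with
#' optogenetic drive: e.g. 2 s of 40 Hz stimulation alternating with 2 s
#' without, or a 5 s ON / 5 s OFF input-output schedule. The session starts
#' with an OFF epoch so every ON epoch has a preceding within-session
#' baseline.
#'
#' @param duration_s Total schedule length in seconds.
#' @param on_s,off_s ON and OFF epoch durations in seconds.
#' @param stim_hz Stimulation frequency in Hz.
#' @inheritParams stim_schedule
#' @return A `stim_schedule` tibble.
#' @export
alternating_schedule <- function(duration_s, on_s = 2, off_s = 2,
                                 stim_hz = 40, duty_cycle = 0.5,
                                 wavelength_nm = NA_real_) {
  starts <- c()
  ends <- c()
  states <- c()
  t <- 0
  state <- "OFF"
  while (t < duration_s - 1e-9) {
    len <- if (state == "ON") on_s else off_s
    end <- min(t + len, duration_s)
    if (end - t >= len - 1e-9) {        # only full epochs
      starts <- c(starts, t); ends <- c(ends, end); states <- c(states, state)
    }
    t <- t + len
    state <- if (state == "ON") "OFF" else "ON"
  }
  stim_schedule(starts, ends, states,
                stim_hz = ifelse(states == "ON", stim_hz, NA_real_),
                duty_cycle = duty_cycle, wavelength_nm = wavelength_nm)
}

#' Read / write a stimulation schedule as CSV
#'
#' Interoperable tabular format with columns
#' `start_s,end_s,state,stim_hz,duty_cycle`.
#'
#' @param path CSV file path.
#' @export
read_schedule <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("start_s", "end_s", "state")
  if (!all(need %in% names(df)))
    stop("schedule CSV must have columns start_s,end_s,state", call. = FALSE)
  stim_schedule(df$start_s, df$end_s, df$state,
                stim_hz = df$stim_hz %||% NA_real_,
                duty_cycle = df$duty_cycle %||% 0.5)
}

#' @rdname read_schedule
#' @param sched A `stim_schedule`.
#' @export
write_schedule <- function(sched, path) {
  readr::write_csv(as.data.frame(sched), path)
  invisible(path)
}

# ---- epochs -----------------------------------------------------------------

#' Cut a recording into labeled epochs
#'
#' One labeled epoch per schedule entry, expressed in the recording's time
#' base. Equal ON and OFF durations yield equal sample counts per epoch.
#'
#' @param rec An [lfp_recording()].
#' @param schedule A [stim_schedule()] (or any tibble with
#'   `start_s,end_s,state`).
#' @return A tibble of class `epoch_set`: `start_s, end_s, label, i0, i1`
#'   where `i0:i1` are sample indices into `rec`.
#' @export
extract_epochs <- function(rec, schedule) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (nrow(schedule) == 0) {
    out <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                          label = character(), i0 = integer(), i1 = integer())
    class(out) <- c("epoch_set", class(out))
    return(out)
  }
  t_end <- rec$t0 + duration(rec)
  if (any(schedule$start_s < rec$t0 - 1e-9) ||
      any(schedule$end_s > t_end + 1e-9))
    stop("bounds error: schedule exceeds recording duration", call. = FALSE)
  i0 <- as.integer(floor((schedule$start_s - rec$t0) * rec$fs)) + 1L
  i1 <- as.integer(floor((schedule$end_s - rec$t0) * rec$fs - 1e-9)) + 1L
  i1 <- pmin(i1, n_samples(rec))
  out <- tibble::tibble(start_s = schedule$start_s, end_s = schedule$end_s,
                        label = schedule$state, i0 = i0, i1 = i1)
  class(out) <- c("epoch_set", class(out))
  out
}

# ---- behaviour tracks -------------------------------------------------------

#' Construct a behaviour track
#'
#' Tabular animal position over time with optional nose position, the arena
#' geometry and named landmarks (objects, baited cup, target quadrant).
#'
#' @param t Time in seconds, strictly increasing.
#' @param body_xy Two-column matrix (cm) of body-centre positions.
#' @param nose_xy Optional two-column matrix (cm) of nose positions.
#' @param arena A list: `list(shape = "circle", radius_cm = ...)` or
#'   `list(shape = "square", side_cm = ...)`, centred on the origin.
#' @param landmarks Optional named list of `c(x, y)` points in cm.
#' @return A tibble of class `behavior_track` with columns
#'   `t_s, body_x_cm, body_y_cm[, nose_x_cm, nose_y_cm]` and the arena and
#'   landmarks in attributes.
#' @export
behavior_track <- function(t, body_xy, nose_xy = NULL, arena,
                           landmarks = list()) {
  t <- as.numeric(t)
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("t must be strictly increasing", call. = FALSE)
  body_xy <- matrix(as.numeric(body_xy), ncol = 2)
  stopifnot(nrow(body_xy) == length(t))
  tol <- 1e-6
  r <- arena_halfwidth(arena)
  if (length(t) && max(arena_dist(body_xy, arena)) > r + tol + 0.5)
    stop("positions fall outside arena bounds", call. = FALSE)
  out <- tibble::tibble(t_s = t, body_x_cm = body_xy[, 1],
                        body_y_cm = body_xy[, 2])
  if (!is.null(nose_xy)) {
    nose_xy <- matrix(as.numeric(nose_xy), ncol = 2)
    stopifnot(nrow(nose_xy) == length(t))
    out$nose_x_cm <- nose_xy[, 1]
    out$nose_y_cm <- nose_xy[, 2]
  }
  attr(out, "arena") <- arena
  attr(out, "landmarks") <- landmarks
  class(out) <- c("behavior_track", class(out))
  out
}

arena_halfwidth <- function(arena) {
  switch(arena$shape,
         circle = arena$radius_cm,
         square = arena$side_cm / 2,
         stop("unknown arena shape: ", arena$shape, call. = FALSE))
}

# distance from centre in the arena's natural norm (radial for circle,
# Chebyshev for square), so `<= halfwidth` means inside
arena_dist <- function(xy, arena) {
  switch(arena$shape,
         circle = sqrt(xy[, 1]^2 + xy[, 2]^2),
         square = pmax(abs(xy[, 1]), abs(xy[, 2])))
}

#' Read / write a behaviour track as CSV
#'
#' Columns `t_s,body_x_cm,body_y_cm[,nose_x_cm,nose_y_cm]`, as exported by
#' common video-tracking tools.
#'
#' @param path CSV file path.
#' @param arena,landmarks See [behavior_track()].
#' @export
read_track <- function(path, arena, landmarks = list()) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("t_s", "body_x_cm", "body_y_cm")
  if (!all(need %in% names(df)))
    stop("track CSV must have columns t_s,body_x_cm,body_y_cm",
         call. = FALSE)
  nose <- NULL
  if (all(c("nose_x_cm", "nose_y_cm") %in% names(df)))
    nose <- cbind(df$nose_x_cm, df$nose_y_cm)
  behavior_track(df$t_s, cbind(df$body_x_cm, df$body_y_cm), nose,
                 arena = arena, landmarks = landmarks)
}

#' @rdname read_track
#' @param track A `behavior_track`.
#' @export
write_track <- function(track, path) {
  readr::write_csv(as.data.frame(track), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
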