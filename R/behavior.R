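# Behavioural scoring: object-place recognition, Barnes maze, delayed
# non-match to place, and the repeated-measures effect size.

track_dt <- function(track) {
  if (nrow(track) < 2) return(NA_real_)
  stats::median(diff(track$t_s))
}

# maximal runs of `inside`, returning start/end indices and duration
runs_of <- function(inside, dt) {
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(i0 = starts[keep], i1 = ends[keep],
                 dur_s = r$lengths[keep] * dt)
}

#' Object exploration and discrimination index
#'
#' An exploration epoch is a maximal run of samples with the nose within
#' `radius_cm` (1 cm by default) of an object; runs shorter than
#' `min_epoch_s` are discarded as tracking jitter. When nose positions are
#' missing the body centre is used with a warning. The discrimination index
#' is `t_displaced / (t_displaced + t_familiar)`, so 0.5 is chance for a
#' two-object task.
#'
#' @param track A [behavior_track()] whose landmarks (or `objects`) name
#'   the object positions.
#' @param objects Named list of object positions in cm; defaults to the
#'   track's landmarks.
#' @param radius_cm Nose-to-object criterion distance.
#' @param displaced,familiar Object names entering the discrimination
#'   index (default `"D"` and `"F"`).
#' @param min_epoch_s Minimum epoch duration in seconds.
#' @param wall_margin_cm Distance from the wall defining thigmotaxis.
#' @return An object of class `exploration_summary`: `$times` (tibble
#'   `object, time_s, n_epochs`), `$epochs`, `$discrimination_index`,
#'   `$thigmotaxis`, `$total_exploration_s`.
#' @export
object_exploration <- function(track, objects = NULL, radius_cm = 1,
                               displaced = "D", familiar = "F",
                               min_epoch_s = 0.1, wall_margin_cm = 5) {
  stopifnot(inherits(track, "behavior_track"))
  if (is.null(objects)) objects <- attr(track, "landmarks")
  if (!length(objects)) stop("no objects given", call. = FALSE)
  if (all(c("nose_x_cm", "nose_y_cm") %in% names(track))) {
    xy <- cbind(track$nose_x_cm, track$nose_y_cm)
  } else {
    warning("nose positions missing; using body centre", call. = FALSE)
    xy <- cbind(track$body_x_cm, track$body_y_cm)
  }
  dt <- track_dt(track)
  all_epochs <- list()
  times <- purrr::imap(objects, function(p, nm) {
    d <- sqrt((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2)
    ep <- runs_of(d <= radius_cm, dt)
    ep <- ep[ep$dur_s >= min_epoch_s, , drop = FALSE]
    all_epochs[[nm]] <<- dplyr::mutate(ep, object = nm)
    tibble::tibble(object = nm, time_s = sum(ep$dur_s),
                   n_epochs = nrow(ep))
  }) |> dplyr::bind_rows()
  td <- times$time_s[match(displaced, times$object)]
  tf <- times$time_s[match(familiar, times$object)]
  di <- if (!is.na(td) && !is.na(tf) && td + tf > 0) td / (td + tf)
        else NA_real_
  arena <- attr(track, "arena")
  half <- arena_halfwidth(arena)
  body <- cbind(track$body_x_cm, track$body_y_cm)
  thig <- mean(arena_dist(body, arena) >= half - wall_margin_cm)
  structure(list(times = times,
                 epochs = dplyr::bind_rows(all_epochs),
                 discrimination_index = di,
                 thigmotaxis = thig,
                 total_exploration_s = sum(times$time_s)),
            class = "exploration_summary")
}

#' @export
print.exploration_summary <- function(x, ...) {
  cat(sprintf("<exploration_summary> DI = %.3f, total exploration %.1f s\n",
              x$discrimination_index, x$total_exploration_s))
  invisible(x)
}

#' @export
tidy.exploration_summary <- function(x, ...) x$times

#' @export
glance.exploration_summary <- function(x, ...) {
  tibble::tibble(discrimination_index = x$discrimination_index,
                 total_exploration_s = x$total_exploration_s,
                 thigmotaxis = x$thigmotaxis)
}

#' Default cup layout for the circular-platform maze
#'
#' Twenty equally spaced cup positions on a circle, matching the 20-location
#' platform (1 m diameter by default, cups centred 40 cm from the middle).
#'
#' @param n_cups Number of cups.
#' @param ring_radius_cm Radius of the cup ring in cm.
#' @return A `n_cups` x 2 matrix of cup centres in cm.
#' @export
barnes_cups <- function(n_cups = 20, ring_radius_cm = 40) {
  ang <- 2 * pi * (seq_len(n_cups) - 1) / n_cups
  cbind(ring_radius_cm * cos(ang), ring_radius_cm * sin(ang))
}

#' Spatial errors on the cup-platform maze
#'
#' A spatial error is the exploration of an unbaited cup — body centre
#' within `visit_radius_cm` of the cup for at least `min_visit_s` — counted
#' at most once per cup per trial, so with 20 cups the maximum is 19.
#'
#' @param track A [behavior_track()].
#' @param cups A cups x 2 matrix of cup centres (default [barnes_cups()]).
#' @param baited Index of the baited cup.
#' @param visit_radius_cm Visit criterion distance (default 3 cm for ~2 cm
#'   cups).
#' @param min_visit_s Minimum dwell to count a visit.
#' @return Integer error count in \[0, n_cups - 1\].
#' @export
barnes_errors <- function(track, cups = barnes_cups(), baited = 1,
                          visit_radius_cm = 3, min_visit_s = 0.2) {
  stopifnot(inherits(track, "behavior_track"))
  if (baited < 1 || baited > nrow(cups))
    stop("parameter error: baited index out of range", call. = FALSE)
  dt <- track_dt(track)
  if (nrow(track) == 0) return(0L)
  xy <- cbind(track$body_x_cm, track$body_y_cm)
  visited <- vapply(seq_len(nrow(cups)), function(k) {
    d <- sqrt((xy[, 1] - cups[k, 1])^2 + (xy[, 2] - cups[k, 2])^2)
    ep <- runs_of(d <= visit_radius_cm, dt)
    any(ep$dur_s >= min_visit_s)
  }, logical(1))
  sum(visited[-baited])
}

#' Time fraction in the target quadrant
#'
#' Quadrants partition the arena by the position angle about the centre
#' (quadrant 1: \[0, 90) degrees, counter-clockwise); boundary samples are
#' assigned deterministically by the half-open intervals. Chance occupancy
#' of any quadrant is 25%.
#'
#' @param track A [behavior_track()].
#' @param target_quadrant Quadrant index 1-4.
#' @return Fraction of samples in the target quadrant.
#' @export
quadrant_occupancy <- function(track, target_quadrant = 1) {
  stopifnot(inherits(track, "behavior_track"))
  if (!target_quadrant %in% 1:4)
    stop("parameter error: quadrant must be 1-4", call. = FALSE)
  if (nrow(track) == 0) return(NA_real_)
  ang <- wrap_deg(atan2(track$body_y_cm, track$body_x_cm) * 180 / pi)
  q <- pmin(floor(ang / 90) + 1, 4)
  mean(q == target_quadrant)
}

#' Daily success rate in a delayed non-match-to-place task
#'
#' A trial is successful when the test choice differs from the sample arm
#' (alternation); the rate is successes over trials.
#'
#' @param trials A data frame with columns `sample` and `choice` (arm
#'   identifiers).
#' @return Success rate in \[0, 1\].
#' @export
alternation_success <- function(trials) {
  if (is.null(nrow(trials)) || nrow(trials) == 0)
    stop("no trials given", call. = FALSE)
  stopifnot(all(c("sample", "choice") %in% names(trials)))
  mean(trials$choice != trials$sample)
}

#' Partial eta squared
#'
#' Effect size for (repeated-measures) ANOVA:
#' `partial eta^2 = SS_effect / (SS_effect + SS_error)`.
#'
#' @param ss_effect,ss_error Sums of squares (non-negative, not both zero).
#' @return A tibble of class `effect_size`: `ss_effect, ss_error,
#'   partial_eta_sq`.
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  if (ss_effect < 0 || ss_error < 0)
    stop("sums of squares must be non-negative", call. = FALSE)
  if (ss_effect == 0 && ss_error == 0)
    stop("degenerate input: both sums of squares are zero", call. = FALSE)
  out <- tibble::tibble(ss_effect = ss_effect, ss_error = ss_error,
                        partial_eta_sq = ss_effect / (ss_effect + ss_error))
  class(out) <- c("effect_size", class(out))
  out
}
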