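# Conjugate saccade detection.
#
# Saccades are detected on head-centered (leftward-positive) normalized
# pupil position traces: the per-frame first difference is the pupil speed
# in % of eye width per frame; an event requires BOTH eyes' absolute speed
# to cross the threshold with the same sign within a +/-1 frame conjugacy
# window; and any train of supra-threshold events with inter-event
# intervals shorter than the refractory window is treated as a processing
# artifact and discarded in full (optionally keeping the first event of a
# train for sensitivity analyses). Frames with missing positions (e.g.
# failed ellipse fits, occlusions) cannot seed events.

#' Pupil speed
#'
#' First difference of the normalized position trace, in % of eye width per
#' frame, aligned to the later frame (`speed[i]` is the movement landing on
#' frame `i + 1`).
#'
#' @param positions Normalized pupil positions.
#' @param units `"fraction"` (default, multiplied by 100) or `"percent"`.
#' @return Numeric vector of length `length(positions) - 1`.
#' @export
eye_speed <- function(positions, units = c("fraction", "percent")) {
  units <- match.arg(units)
  if (length(positions) < 2L) fit_error("eye_speed: need >= 2 samples")
  d <- diff(positions)
  if (units == "fraction") d <- d * 100
  d
}

#' Detect conjugate saccades
#'
#' @param left_pos,right_pos Head-centered (leftward-positive) normalized
#'   pupil positions, fraction of eye width, on the eye clock.
#' @param eye_rate Eye frame rate, frames/s.
#' @param threshold Speed threshold, % of eye width per frame.
#' @param refractory_ms Trains of supra-threshold events closer than this
#'   are discarded as artifacts.
#' @param conjugacy_frames The two eyes' crossings must co-occur within this
#'   many frames.
#' @param keep_first Keep the first event of each sub-refractory train
#'   instead of discarding the whole train.
#' @return data.frame of class `saccade_events`, one row per retained
#'   event: `frame` (1-based eye frame the movement lands on), `time_s`,
#'   `direction` (`leftward`/`rightward`), `amplitude` (net two-eye mean
#'   displacement, % eye width), `peak_speed` (mean-eye), `speed_left`,
#'   `speed_right` (per-eye speeds at the peak frame).
#' @export
detect_saccades <- function(left_pos, right_pos, eye_rate = 100,
                            threshold = 0.1, refractory_ms = 250,
                            conjugacy_frames = 1L, keep_first = FALSE) {
  if (length(left_pos) != length(right_pos))
    format_error("detect_saccades: mismatched trace lengths")
  sl <- eye_speed(left_pos); sr <- eye_speed(right_pos)
  ns <- length(sl)
  ok <- function(v) !is.na(v)
  # same-signed supra-threshold crossing, right eye allowed +/- conjugacy_frames
  cross <- logical(ns)
  for (k in -conjugacy_frames:conjugacy_frames) {
    idx <- seq_len(ns)
    j <- idx + k
    valid <- j >= 1 & j <= ns
    cand <- rep(FALSE, ns)
    cand[valid] <- ok(sl[idx[valid]]) & ok(sr[j[valid]]) &
      abs(sl[idx[valid]]) > threshold & abs(sr[j[valid]]) > threshold &
      sign(sl[idx[valid]]) == sign(sr[j[valid]])
    cross <- cross | cand
  }
  if (!any(cross)) return(empty_saccades())

  # group consecutive crossing frames into candidate events
  runs <- rle(cross)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep_runs <- which(runs$values)
  events <- do.call(rbind, lapply(keep_runs, function(ri) {
    s <- starts[ri]; e <- ends[ri]
    mean_speed <- (sl[s:e] + sr[s:e]) / 2
    pk <- s + which.max(abs(mean_speed)) - 1L
    disp <- sum(mean_speed)  # net mean-eye displacement across the run, %
    data.frame(frame = pk + 1L, time_s = pk / eye_rate,
               direction = if (disp > 0) "leftward" else "rightward",
               amplitude = abs(disp),
               peak_speed = mean_speed[pk - s + 1L],
               speed_left = sl[pk], speed_right = sr[pk])
  }))
  events <- events[order(events$frame), , drop = FALSE]

  # refractory rule: discard entire sub-interval trains
  if (nrow(events) > 1) {
    gap_s <- diff(events$time_s)
    close_pair <- gap_s < refractory_ms / 1000
    in_train <- c(close_pair, FALSE) | c(FALSE, close_pair)
    if (keep_first) {
      drop <- rep(FALSE, nrow(events))
      i <- 1L
      while (i <= nrow(events)) {
        j <- i
        while (j < nrow(events) && close_pair[j]) j <- j + 1L
        if (j > i) drop[(i + 1L):j] <- TRUE
        i <- j + 1L
      }
      events <- events[!drop, , drop = FALSE]
    } else {
      events <- events[!in_train, , drop = FALSE]
    }
  }
  rownames(events) <- NULL
  class(events) <- c("saccade_events", "data.frame")
  events
}

empty_saccades <- function() {
  structure(data.frame(frame = integer(), time_s = numeric(),
                       direction = character(), amplitude = numeric(),
                       peak_speed = numeric(), speed_left = numeric(),
                       speed_right = numeric()),
            class = c("saccade_events", "data.frame"))
}

#' Per-epoch saccade histogram
#'
#' Assigns each event to its enclosing annotated epoch, normalizes its time
#' within the epoch, and counts events in `n_bins` equal normalized-time
#' bins per state, split by event direction and by trial (cue) direction.
#' Turn epochs of either direction are pooled under `"turn"`. Events outside
#' any annotated epoch are counted separately as `unassigned`.
#'
#' @param events A `saccade_events` data.frame.
#' @param trials List of `trial_record`s (behavior clock).
#' @param behavior_rate Behavior clock rate, frames/s.
#' @param n_bins Number of normalized-time bins (10 as in the epoch
#'   histograms).
#' @param states Generic states covered by the histogram.
#' @return List: `counts`, a 4-d array `[state, bin, event_direction,
#'   trial_direction]`; `unassigned`, the number of events outside covered
#'   epochs; `events`, the per-event assignment table.
#' @export
saccade_histogram <- function(events, trials, behavior_rate = 200, n_bins = 10L,
                              states = c("end_of_lane", "backward", "turn", "forward")) {
  counts <- array(0L, dim = c(length(states), n_bins, 2L, 2L),
                  dimnames = list(state = states, bin = seq_len(n_bins),
                                  event_direction = c("leftward", "rightward"),
                                  trial_direction = c("left", "right")))
  unassigned <- 0L
  rows <- list()
  for (i in seq_len(nrow(events))) {
    beh_f <- events$time_s[i] * behavior_rate  # 0-based fractional frame
    hit <- NULL
    for (tr in trials) {
      ep <- tr$epochs
      sel <- which(beh_f >= ep$start_frame & beh_f < ep$end_frame)
      if (length(sel) > 0) {
        st <- ep$state[sel[1]]
        stg <- if (st %in% c("turn_left", "turn_right")) "turn" else st
        if (stg %in% states) {
          frac <- (beh_f - ep$start_frame[sel[1]]) /
            (ep$end_frame[sel[1]] - ep$start_frame[sel[1]])
          bin <- min(n_bins, floor(frac * n_bins) + 1L)
          hit <- list(state = stg, bin = bin, trial_dir = tr$cued_direction,
                      trial = tr$trial_id)
        }
        break
      }
    }
    if (is.null(hit)) {
      unassigned <- unassigned + 1L
    } else {
      counts[hit$state, hit$bin, events$direction[i], hit$trial_dir] <-
        counts[hit$state, hit$bin, events$direction[i], hit$trial_dir] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        frame = events$frame[i], time_s = events$time_s[i],
        direction = events$direction[i], state = hit$state, bin = hit$bin,
        trial = hit$trial, trial_direction = hit$trial_dir)
    }
  }
  list(counts = counts, unassigned = unassigned,
       events = if (length(rows)) do.call(rbind, rows) else NULL)
}
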