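# Normalized behavioral variables.
#
# Whisker angles are centered on the session median ("provisional zero") and
# expressed per trial as a percentage of the full range of deviation within
# that trial (0% = trial minimum, 100% = trial maximum). Whisker asymmetry
# is the difference of the two sides' normalized positions, signed toward
# the cued turn. Pupil positions are mapped into a head-centered
# leftward-positive axis (one eye's nasal->temporal axis is flipped) and
# deviation is the two-eye average relative to the session median, signed
# toward the cued turn. Epoch traces are compared on a resampled [0, 1]
# time base.

#' Linear interpolation over missing samples
#'
#' @param trace Numeric vector with NA for missing samples.
#' @param max_missing_frac Error if more than this fraction is missing.
#' @return List `values` (filled trace, edges held at the nearest
#'   observation) and `n_filled`.
#' @export
interpolate_missing <- function(trace, max_missing_frac = 0.5) {
  na <- is.na(trace)
  if (all(na)) fit_error("interpolate_missing: all samples missing")
  frac <- mean(na)
  if (frac > max_missing_frac)
    fit_error(sprintf("interpolate_missing: %.0f%% missing exceeds limit %.0f%%",
                      100 * frac, 100 * max_missing_frac))
  if (!any(na)) return(list(values = trace, n_filled = 0L))
  idx <- seq_along(trace)
  filled <- stats::approx(idx[!na], trace[!na], xout = idx, rule = 2)$y
  list(values = filled, n_filled = sum(na))
}

trial_frames_1based <- function(trial) {
  sp <- trial_span(trial)
  (sp[["start"]] + 1L):sp[["end"]]
}

#' Trial-range normalized whisker trace
#'
#' Centers the session trace on its median angle, then rescales each trial
#' to `[0, 100]`% between the trial minimum and maximum. Frames outside any
#' trial are NA.
#'
#' @param angles Whisker angle trace, degrees, behavior clock.
#' @param trials List of `trial_record`s.
#' @return Object of class `normalized_trace`: `values` (%), `clock` = NA
#'   (set by callers), and `normalization_meta` (session median, per-trial
#'   min/max of the centered angles).
#' @export
normalize_whisker <- function(angles, trials) {
  if (length(trials) == 0) config_error("no trials", "trials")
  med <- stats::median(angles, na.rm = TRUE)
  centered <- angles - med
  values <- rep(NA_real_, length(angles))
  meta <- data.frame(trial = integer(), min = numeric(), max = numeric())
  for (tr in trials) {
    fr <- trial_frames_1based(tr)
    if (max(fr) > length(angles)) format_error("trial bounds exceed trace")
    rng <- range(centered[fr], na.rm = TRUE)
    if (!all(is.finite(rng)) || diff(rng) <= sqrt(.Machine$double.eps))
      fit_error(sprintf("trial %d: degenerate (constant) whisker trace", tr$trial_id))
    values[fr] <- 100 * (centered[fr] - rng[1]) / diff(rng)
    meta <- rbind(meta, data.frame(trial = tr$trial_id, min = rng[1], max = rng[2]))
  }
  structure(list(values = values, clock = NA_real_,
                 normalization_meta = list(session_median = med, trial_range = meta)),
            class = "normalized_trace")
}

#' Whisker asymmetry trace
#'
#' Difference of the two sides' normalized whisker positions. The raw
#' convention is right minus left (positive when the right whisker is the
#' more protracted, the pattern preceding left turns); when `signed` the
#' difference is flipped on right-turn trials so positive always points
#' toward the cued turn (right - left for left turns, left - right for
#' right turns).
#'
#' @param w_left,w_right `normalized_trace`s on the same clock.
#' @param trials List of `trial_record`s.
#' @param signed Sign toward the cued turn (default) or keep raw
#'   right-minus-left.
#' @return Object of class `asymmetry_trace`: `values` (percentage points,
#'   NA where either side is missing), `direction_convention`.
#' @export
asymmetry <- function(w_left, w_right, trials, signed = TRUE) {
  stopifnot(inherits(w_left, "normalized_trace"), inherits(w_right, "normalized_trace"))
  if (length(w_left$values) != length(w_right$values))
    format_error("asymmetry: traces must share a clock and length")
  values <- w_right$values - w_left$values
  if (signed) {
    for (tr in trials) {
      if (tr$cued_direction == "right") {
        fr <- trial_frames_1based(tr)
        values[fr] <- -values[fr]
      }
    }
  }
  structure(list(values = values,
                 direction_convention = if (signed)
                   "right-minus-left on left turns, left-minus-right on right turns"
                 else "right minus left"),
            class = "asymmetry_trace")
}

#' Head-centered pupil positions and turn-signed deviation
#'
#' Converts per-eye normalized pupil positions (fraction of eye width, 0 =
#' nasal corner) into a common head-centered leftward-positive axis: for the
#' left eye temporal = leftward so its axis is kept; for the right eye
#' nasal = leftward so its axis is flipped. Deviation is the two-eye mean
#' displacement from the session median, in % of eye width, and is
#' additionally signed toward the cued turn per trial when `trials` is
#' given.
#'
#' @param left_eye,right_eye Numeric normalized pupil position traces
#'   (fraction), eye clock.
#' @param trials Optional list of `trial_record`s (behavior clock) used with
#'   `step` to sign deviation toward the turn.
#' @param step Behavior-to-eye clock ratio (frames), required with `trials`.
#' @return List: `head_left`, `head_right` (per-eye leftward-positive
#'   positions, %), `deviation_leftward` (two-eye mean, %),
#'   `deviation_signed` (toward cued turn; NULL without `trials`).
#' @export
pupil_deviation <- function(left_eye, right_eye, trials = NULL, step = 2L) {
  if (length(left_eye) != length(right_eye))
    format_error("pupil_deviation: eye traces differ in length")
  hl <- 100 * (left_eye - stats::median(left_eye, na.rm = TRUE))
  hr <- -100 * (right_eye - stats::median(right_eye, na.rm = TRUE))
  dev <- (hl + hr) / 2
  signed <- NULL
  if (!is.null(trials)) {
    signed <- rep(NA_real_, length(dev))
    for (tr in trials) {
      sp <- trial_span(tr)
      fr <- (sp[["start"]] %/% step + 1L):(sp[["end"]] %/% step)
      s <- if (tr$cued_direction == "left") 1 else -1
      signed[fr] <- s * dev[fr]
    }
  }
  list(head_left = hl, head_right = hr,
       deviation_leftward = dev, deviation_signed = signed)
}

#' Resample an epoch onto a normalized time base
#'
#' Linear-interpolated resampling of an epoch's samples onto `n_points`
#' equally spaced points of `[0, 1]`, endpoints preserved.
#'
#' @param trace Numeric vector (the epoch's samples, >= 2).
#' @param n_points Number of output samples.
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(trace, n_points = 101L) {
  n <- length(trace)
  if (n < 2L) fit_error("time_normalize: epoch must have >= 2 samples")
  stats::approx(seq(0, 1, length.out = n), trace,
                xout = seq(0, 1, length.out = n_points))$y
}

#' Per-state epoch summaries on normalized time
#'
#' Groups epochs by behavioral state and cue direction, resamples each onto
#' `[0, 1]`, and returns the per-time-point median with the 25th-75th
#' percentile band, plus per-epoch averages for box-plot style statistics.
#'
#' @param trace Numeric session trace.
#' @param trials List of `trial_record`s.
#' @param states Generic state names to include (turn matches both
#'   directions).
#' @param n_points Resampling resolution.
#' @param clock_step Divide epoch behavior-clock frames by this to index
#'   `trace` (use 2 for eye-clock traces at half the behavior rate).
#' @param split_halves Also report per-epoch means over the first and
#'   second halves of each epoch (`half` column in `epoch_means`), the
#'   grouping used when a quiet reference period is the first half of the
#'   end-of-lane epoch. The halving boundary is `floor(n/2)`.
#' @return data.frame-based list: `bands` (state, direction, time, median,
#'   q25, q75, n) and `epoch_means` (state, direction, trial, mean, and
#'   with `split_halves` also half-wise rows flagged by `half`).
#' @export
epoch_summary <- function(trace, trials, states = c("end_of_lane", "backward",
                                                    "turn", "forward",
                                                    "expect_reward", "lick"),
                          n_points = 101L, clock_step = 1L,
                          split_halves = FALSE) {
  rows <- list(); means <- list()
  for (st in states) {
    for (dir in c("left", "right")) {
      mats <- list()
      for (tr in trials) {
        if (tr$cued_direction != dir) next
        ep <- tr$epochs
        sel <- ep$state == st | ep$state == paste0(st, "_", dir)
        if (!any(sel)) next
        r <- ep[sel, ][1, ]
        fr <- (r$start_frame %/% clock_step + 1L):(r$end_frame %/% clock_step)
        seg <- trace[fr]
        if (all(is.na(seg))) next
        mats[[length(mats) + 1L]] <- time_normalize(seg, n_points)
        means[[length(means) + 1L]] <- data.frame(
          state = st, direction = dir, trial = tr$trial_id,
          half = NA_integer_, mean = mean(seg, na.rm = TRUE))
        if (split_halves) {
          cut <- floor(length(seg) / 2)
          means[[length(means) + 1L]] <- data.frame(
            state = st, direction = dir, trial = tr$trial_id, half = 1:2,
            mean = c(mean(seg[seq_len(cut)], na.rm = TRUE),
                     mean(seg[(cut + 1L):length(seg)], na.rm = TRUE)))
        }
      }
      if (length(mats) == 0) next
      m <- do.call(rbind, mats)
      rows[[length(rows) + 1L]] <- data.frame(
        state = st, direction = dir,
        time = seq(0, 1, length.out = n_points),
        median = apply(m, 2, stats::median, na.rm = TRUE),
        q25 = apply(m, 2, stats::quantile, probs = 0.25, na.rm = TRUE, names = FALSE),
        q75 = apply(m, 2, stats::quantile, probs = 0.75, na.rm = TRUE, names = FALSE),
        n = nrow(m))
    }
  }
  list(bands = if (length(rows)) do.call(rbind, rows) else NULL,
       epoch_means = if (length(means)) do.call(rbind, means) else NULL)
}

#' Derived kinematic traces for one session
#'
#' Runs the standard kinematics chain: missing-value interpolation,
#' session-median centering with trial-range normalization per side, raw
#' and turn-signed whisker asymmetry, head-centered pupil positions and
#' turn-signed deviation, and the whisker traces downsampled to the eye
#' clock by 2-frame averaging for joint analyses.
#'
#' @param session A `session_record`.
#' @return List of traces: `w_left`, `w_right` (`normalized_trace`s),
#'   `asym_signed`, `asym_raw` (behavior clock, %), `asym_raw_eye` (eye
#'   clock), `eye` (output of [pupil_deviation()]), `step`.
#' @export
session_kinematics <- function(session) {
  stopifnot(inherits(session, "session_record"))
  step <- as.integer(session$behavior_rate / session$eye_rate)
  wl <- interpolate_missing(session$whisker_traces$left)$values
  wr <- interpolate_missing(session$whisker_traces$right)$values
  nl <- normalize_whisker(wl, session$trials)
  nr <- normalize_whisker(wr, session$trials)
  nl$clock <- session$behavior_rate; nr$clock <- session$behavior_rate
  a_signed <- asymmetry(nl, nr, session$trials, signed = TRUE)
  a_raw <- asymmetry(nl, nr, session$trials, signed = FALSE)
  a_raw_eye <- downsample2(a_raw$values)
  pl <- interpolate_missing(session$pupil_traces$left)$values
  pr <- interpolate_missing(session$pupil_traces$right)$values
  eye <- pupil_deviation(pl, pr, session$trials, step = step)
  list(w_left = nl, w_right = nr, asym_signed = a_signed, asym_raw = a_raw,
       asym_raw_eye = a_raw_eye, eye = eye, step = step)
}
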