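# On-disk formats.
#
# Keypoint tables use the wide "scorer / bodyparts / coords" CSV dialect that
# common pose trackers export (three header rows, first column = frame
# index). Behavioral-state annotations are JSON with explicit 0-based,
# end-exclusive frame indices on the behavior clock. Results and session
# metadata are JSON. All readers validate and reject rather than coerce.

TRIAL_STATES <- c("end_of_lane", "backward", "turn_left", "turn_right",
                  "forward", "expect_reward", "lick")

#' Construct and validate a trial record
#'
#' @param trial_id Integer trial identifier.
#' @param cued_direction `"left"` or `"right"`.
#' @param epochs data.frame with columns `state`, `start_frame`, `end_frame`
#'   (behavior clock, 0-based, end-exclusive), ordered, non-overlapping.
#' @return Object of class `trial_record`.
#' @export
trial_record <- function(trial_id, cued_direction, epochs) {
  if (!cued_direction %in% c("left", "right"))
    format_error(sprintf("trial %s: unknown cued_direction '%s'", trial_id, cued_direction))
  epochs <- as.data.frame(epochs)
  need <- c("state", "start_frame", "end_frame")
  if (!all(need %in% names(epochs)))
    format_error(sprintf("trial %s: epochs need columns %s", trial_id,
                         paste(need, collapse = ", ")))
  bad <- setdiff(epochs$state, TRIAL_STATES)
  if (length(bad) > 0)
    format_error(sprintf("trial %s: unknown state label '%s'", trial_id, bad[1]))
  if (any(epochs$end_frame <= epochs$start_frame))
    format_error(sprintf("trial %s: non-monotone epoch frames", trial_id))
  if (nrow(epochs) > 1) {
    s <- epochs$start_frame[-1]; e <- epochs$end_frame[-nrow(epochs)]
    if (any(s < e))
      format_error(sprintf("trial %s: overlapping or out-of-order epochs", trial_id))
  }
  turn <- epochs$state[epochs$state %in% c("turn_left", "turn_right")]
  if (length(turn) > 0 && any(turn != paste0("turn_", cued_direction)))
    format_error(sprintf("trial %s: turn epoch direction inconsistent with cue", trial_id))
  structure(list(trial_id = as.integer(trial_id),
                 cued_direction = cued_direction,
                 epochs = epochs[, need]),
            class = "trial_record")
}

trial_span <- function(trial) {
  c(start = min(trial$epochs$start_frame), end = max(trial$epochs$end_frame))
}

#' Construct and validate a session record
#'
#' The pipeline's unit of work: whisker angle traces on the behavior clock,
#' normalized pupil traces on the eye clock, trial annotations and per-eye
#' geometry.
#'
#' @param animal_id,session_id Text identifiers.
#' @param behavior_rate,eye_rate Frame rates (behavior must be an integer
#'   multiple of eye).
#' @param trials List of `trial_record`s with disjoint frame ranges.
#' @param whisker_traces List with numeric elements `left`, `right`
#'   (angles in degrees, behavior clock).
#' @param pupil_traces List with numeric elements `left`, `right`
#'   (normalized pupil position, fraction of eye width, eye clock).
#' @param eye_geometry Optional list with `eye_geometry` elements `left`,
#'   `right`.
#' @return Object of class `session_record`.
#' @export
session_record <- function(animal_id, session_id, behavior_rate, eye_rate,
                           trials, whisker_traces, pupil_traces,
                           eye_geometry = NULL) {
  check_scalar(behavior_rate, "behavior_rate", positive = TRUE)
  check_scalar(eye_rate, "eye_rate", positive = TRUE)
  if (behavior_rate %% eye_rate != 0)
    config_error("behavior_rate must be an integer multiple of eye_rate", "behavior_rate")
  for (side in c("left", "right")) {
    if (is.null(whisker_traces[[side]]))
      format_error(sprintf("missing whisker trace for side '%s'", side))
    if (is.null(pupil_traces[[side]]))
      format_error(sprintf("missing pupil trace for eye '%s'", side))
  }
  n_beh <- length(whisker_traces$left)
  if (length(whisker_traces$right) != n_beh)
    format_error("whisker trace lengths differ between sides")
  n_eye <- length(pupil_traces$left)
  if (length(pupil_traces$right) != n_eye)
    format_error("pupil trace lengths differ between eyes")
  if (abs(n_beh / behavior_rate - n_eye / eye_rate) > 2 / eye_rate)
    format_error("trace durations inconsistent with their clocks")
  spans <- t(vapply(trials, trial_span, numeric(2)))
  if (length(trials) > 0) {
    ord <- order(spans[, 1])
    spans <- spans[ord, , drop = FALSE]
    trials <- trials[ord]
    if (any(spans[, 2] > n_beh))
      format_error("trial frame range exceeds trace bounds")
    if (nrow(spans) > 1 && any(spans[-1, 1] < spans[-nrow(spans), 2]))
      format_error("trial frame ranges overlap")
  }
  structure(list(animal_id = animal_id, session_id = session_id,
                 behavior_rate = behavior_rate, eye_rate = eye_rate,
                 trials = trials, whisker_traces = whisker_traces,
                 pupil_traces = pupil_traces, eye_geometry = eye_geometry),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("session %s/%s: %d trials, %d behavior frames @ %g Hz, %d eye frames @ %g Hz\n",
              x$animal_id, x$session_id, length(x$trials),
              length(x$whisker_traces$left), x$behavior_rate,
              length(x$pupil_traces$left), x$eye_rate))
  invisible(x)
}

# keypoint tables ------------------------------------------------------------

#' Write a keypoint table in the scorer/bodyparts/coords CSV dialect
#'
#' @param keypoints Long data.frame with columns `frame` (0-based),
#'   `bodypart`, `x`, `y` and optionally `likelihood`.
#' @param path Output CSV path.
#' @param scorer Scorer name placed in the first header row.
#' @export
write_keypoints <- function(keypoints, path, scorer = "synthetic") {
  kp <- as.data.frame(keypoints)
  need <- c("frame", "bodypart", "x", "y")
  if (!all(need %in% names(kp))) format_error("keypoints need frame/bodypart/x/y")
  has_like <- "likelihood" %in% names(kp)
  parts <- unique(kp$bodypart)
  frames <- sort(unique(kp$frame))
  coords <- if (has_like) c("x", "y", "likelihood") else c("x", "y")
  wide <- matrix(NA_real_, nrow = length(frames),
                 ncol = length(parts) * length(coords))
  fi <- match(kp$frame, frames)
  for (j in seq_along(parts)) {
    rows <- kp$bodypart == parts[j]
    base <- (j - 1) * length(coords)
    wide[fi[rows], base + 1] <- kp$x[rows]
    wide[fi[rows], base + 2] <- kp$y[rows]
    if (has_like) wide[fi[rows], base + 3] <- kp$likelihood[rows]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("scorer",    rep(scorer, ncol(wide))), collapse = ","), con)
  writeLines(paste(c("bodyparts", rep(parts, each = length(coords))), collapse = ","), con)
  writeLines(paste(c("coords",    rep(coords, length(parts))), collapse = ","), con)
  utils::write.table(cbind(frames, wide), con, sep = ",", col.names = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a keypoint table
#'
#' Parses the three-header-row scorer/bodyparts/coords CSV dialect into a
#' long frame-indexed table. Frames absent between the minimum and maximum
#' frame index are preserved as missing rows (NA coordinates), not dropped.
#'
#' @param path CSV path.
#' @param layout_spec Column convention; only `"scorer_bodyparts_coords"`
#'   (the pose-tracker default) is currently defined.
#' @return Long data.frame `frame`, `bodypart`, `x`, `y`, `likelihood`
#'   (NA if absent from file), with attribute `missing_frames`.
#' @export
read_keypoints <- function(path, layout_spec = "scorer_bodyparts_coords") {
  if (!identical(layout_spec, "scorer_bodyparts_coords"))
    format_error(sprintf("unknown layout_spec '%s'", layout_spec))
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L) format_error("keypoint file too short for 3 header rows")
  h1 <- strsplit(hdr[1], ",")[[1]]
  h2 <- strsplit(hdr[2], ",")[[1]]
  h3 <- strsplit(hdr[3], ",")[[1]]
  if (h1[1] != "scorer" || h2[1] != "bodyparts" || h3[1] != "coords")
    format_error(sprintf("malformed header: expected scorer/bodyparts/coords, got '%s/%s/%s'",
                         h1[1], h2[1], h3[1]))
  if (length(h2) != length(h3) || length(h2) < 3L)
    format_error("malformed header: bodyparts/coords rows differ in length")
  if (!all(h3[-1] %in% c("x", "y", "likelihood")))
    format_error(sprintf("malformed header: unknown coord column '%s'",
                         setdiff(h3[-1], c("x", "y", "likelihood"))[1]))
  dat <- utils::read.csv(path, skip = 3L, header = FALSE)
  if (ncol(dat) != length(h2)) format_error("data row width differs from header")
  frames <- dat[[1]]
  if (anyDuplicated(frames)) {
    format_error(sprintf("duplicated frame index %s", frames[duplicated(frames)][1]))
  }
  all_frames <- seq(min(frames), max(frames))
  missing_frames <- setdiff(all_frames, frames)
  parts <- h2[-1]; coords <- h3[-1]
  out <- do.call(rbind, lapply(unique(parts), function(bp) {
    cols <- which(parts == bp) + 1L
    cc <- coords[cols - 1L]
    df <- data.frame(frame = all_frames, bodypart = bp,
                     x = NA_real_, y = NA_real_, likelihood = NA_real_,
                     stringsAsFactors = FALSE)
    ri <- match(frames, all_frames)
    if ("x" %in% cc) df$x[ri] <- dat[[cols[cc == "x"]]]
    if ("y" %in% cc) df$y[ri] <- dat[[cols[cc == "y"]]]
    if ("likelihood" %in% cc) df$likelihood[ri] <- dat[[cols[cc == "likelihood"]]]
    df
  }))
  rownames(out) <- NULL
  attr(out, "missing_frames") <- missing_frames
  out
}

# annotations ----------------------------------------------------------------

#' Write behavioral-state annotations to JSON
#'
#' @param trials List of `trial_record`s.
#' @param path Output JSON path.
#' @export
write_annotations <- function(trials, path) {
  payload <- list(
    format = "whiskeye-annotations",
    frame_convention = "0-based, end-exclusive, behavior clock",
    trials = lapply(trials, function(tr) list(
      trial_id = tr$trial_id,
      cued_direction = tr$cued_direction,
      epochs = tr$epochs
    ))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read behavioral-state annotations
#'
#' Validates each trial (known state labels, monotone non-overlapping
#' epochs, turn epoch consistent with the cue) and rejects invalid input.
#'
#' @param path JSON path written by [write_annotations()] (or compatible).
#' @return List of `trial_record`s.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyVector = TRUE)
  trs <- payload$trials
  if (is.null(trs)) format_error("annotation file has no 'trials' field")
  if (is.data.frame(trs)) {
    trs <- lapply(seq_len(nrow(trs)), function(i)
      list(trial_id = trs$trial_id[i], cued_direction = trs$cued_direction[i],
           epochs = trs$epochs[[i]]))
  }
  lapply(trs, function(tr)
    trial_record(tr$trial_id, tr$cued_direction, tr$epochs))
}

# session + results ----------------------------------------------------------

#' Write a session to a directory of plain-text files
#'
#' Layout: `meta.json` (ids, rates), `annotations.json`, and one
#' `frame,value` CSV per trace (`whisker_left/right.csv` in degrees,
#' `pupil_left/right.csv` as normalized fractions).
#'
#' @param session A `session_record`.
#' @param dir Output directory (created if needed).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    format = "whiskeye-session",
    animal_id = session$animal_id, session_id = session$session_id,
    behavior_rate = session$behavior_rate, eye_rate = session$eye_rate
  ), file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_annotations(session$trials, file.path(dir, "annotations.json"))
  wr <- function(x, f) utils::write.csv(
    data.frame(frame = seq_along(x) - 1L, value = x),
    file.path(dir, f), row.names = FALSE)
  wr(session$whisker_traces$left, "whisker_left.csv")
  wr(session$whisker_traces$right, "whisker_right.csv")
  wr(session$pupil_traces$left, "pupil_left.csv")
  wr(session$pupil_traces$right, "pupil_right.csv")
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Session directory.
#' @return A `session_record`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  rd <- function(f) utils::read.csv(file.path(dir, f))$value
  session_record(
    meta$animal_id, meta$session_id, meta$behavior_rate, meta$eye_rate,
    trials = read_annotations(file.path(dir, "annotations.json")),
    whisker_traces = list(left = rd("whisker_left.csv"), right = rd("whisker_right.csv")),
    pupil_traces = list(left = rd("pupil_left.csv"), right = rd("pupil_right.csv"))
  )
}

#' Write analysis results to JSON
#'
#' Serializes saccade event lists, binned predictor tables, ROC/fidelity and
#' correlogram outputs (any list of data.frames / numeric structures) to a
#' re-readable JSON layout.
#'
#' @param results Named list.
#' @param path Output JSON path.
#' @export
write_results <- function(results, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    suppressWarnings(jsonlite::write_json(results, path, auto_unbox = TRUE,
                                          digits = NA, pretty = TRUE,
                                          na = "null", force = TRUE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) format_error(sprintf("cannot write results to '%s'", path))
  invisible(path)
}

#' Read analysis results written by [write_results()]
#'
#' @param path JSON path.
#' @return Named list (data.frames simplified back where possible).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
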