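# Saccade-triggered whisker-asymmetry correlograms during backward movement.
#
# Each retained saccade inside a backward epoch contributes one lag-aligned
# asymmetry trace (asymmetry signed toward the event's direction so left-
# and rightward events pool); the null redraws each event's time uniformly
# within its own trial's backward epoch, preserving directions and per-trial
# event counts. Real and shuffled traces are summarized by per-lag medians
# with 25th-75th percentile bands and compared bin-to-bin (100 ms bins of
# per-trace medians) with the Mann-Whitney U test. One designated shuffle
# set carries the test (exchangeable with the real events under no
# coupling); the remaining sets stabilize the displayed null medians.

backward_epoch_eye <- function(trial, step) {
  r <- trial$epochs[trial$epochs$state == "backward", ]
  if (nrow(r) == 0) return(NULL)
  c(start = r$start_frame[1] %/% step + 1L, end = r$end_frame[1] %/% step)
}

# events restricted to backward epochs, annotated with their parent trial
assign_backward_events <- function(events, trials, step) {
  if (nrow(events) == 0) return(cbind(events, trial = integer(0)))
  rows <- list()
  for (tr in trials) {
    be <- backward_epoch_eye(tr, step)
    if (is.null(be)) next
    sel <- events$frame >= be[["start"]] & events$frame <= be[["end"]]
    if (any(sel)) {
      ev <- events[sel, , drop = FALSE]
      ev$trial <- tr$trial_id
      rows[[length(rows) + 1L]] <- ev
    }
  }
  if (length(rows) == 0) return(cbind(events[0, ], trial = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Saccade-triggered asymmetry traces
#'
#' @param asym_eye Raw (right-minus-left, leftward-positive) whisker
#'   asymmetry on the eye clock, %.
#' @param events `saccade_events` restricted (internally) to backward
#'   epochs.
#' @param trials List of `trial_record`s.
#' @param window Lag window in seconds around each event.
#' @param eye_rate Eye clock rate.
#' @param step Behavior-to-eye clock ratio.
#' @param sign_by_direction Sign each trace toward its event's direction
#'   (leftward events keep the raw sign, rightward events are negated).
#' @return List: `traces` (events x lags matrix, NA where the lag leaves
#'   the event's backward epoch), `lags` (seconds), `events` (the retained
#'   event table with parent trials).
#' @export
triggered_traces <- function(asym_eye, events, trials, window = c(-0.5, 0.8),
                             eye_rate = 100, step = 2L, sign_by_direction = TRUE) {
  ev <- assign_backward_events(events, trials, step)
  lag_f <- seq(round(window[1] * eye_rate), round(window[2] * eye_rate))
  lags <- lag_f / eye_rate
  tr_map <- stats::setNames(trials, vapply(trials, function(t) as.character(t$trial_id), ""))
  M <- matrix(NA_real_, nrow(ev), length(lags))
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      be <- backward_epoch_eye(tr_map[[as.character(ev$trial[i])]], step)
      f <- ev$frame[i] + lag_f
      ok <- f >= be[["start"]] & f <= be[["end"]] & f >= 1 & f <= length(asym_eye)
      M[i, ok] <- asym_eye[f[ok]]
      if (sign_by_direction && ev$direction[i] == "rightward") M[i, ] <- -M[i, ]
    }
  }
  list(traces = M, lags = lags, events = ev)
}

#' Shuffle saccade event times within their backward epochs
#'
#' Each surrogate set redraws every event's time uniformly within its own
#' trial's backward epoch (snapped to the eye clock), preserving event
#' directions and per-trial counts.
#'
#' @param events Event table with a `trial` column (as produced by
#'   [triggered_traces()]).
#' @param trials List of `trial_record`s.
#' @param n_shuffles Number of surrogate sets.
#' @param seed Seed for the shuffle stream.
#' @param step Behavior-to-eye clock ratio.
#' @param eye_rate Eye clock rate.
#' @return List of event tables, one per surrogate set.
#' @export
shuffle_event_times <- function(events, trials, n_shuffles = 100L, seed = 1L,
                                step = 2L, eye_rate = 100) {
  tr_map <- stats::setNames(trials, vapply(trials, function(t) as.character(t$trial_id), ""))
  with_seed(seed, {
    lapply(seq_len(n_shuffles), function(k) {
      ev <- events
      if (nrow(ev) > 0) {
        for (i in seq_len(nrow(ev))) {
          be <- backward_epoch_eye(tr_map[[as.character(ev$trial[i])]], step)
          ev$frame[i] <- sample(be[["start"]]:be[["end"]], 1L)
        }
        ev$time_s <- (ev$frame - 1) / eye_rate
      }
      ev
    })
  })
}

per_bin_medians <- function(M, lags, bin_s) {
  edges <- seq(min(lags) - 1e-9, max(lags) + bin_s, by = bin_s)
  bin <- findInterval(lags, edges)
  nb <- max(bin)
  out <- matrix(NA_real_, nrow(M), nb)
  for (b in seq_len(nb)) {
    cols <- which(bin == b)
    if (length(cols) == 0) next
    out[, b] <- apply(M[, cols, drop = FALSE], 1, stats::median, na.rm = TRUE)
  }
  list(medians = out, starts = edges[seq_len(nb)])
}

#' Saccade-triggered correlogram with a shuffled-timing null
#'
#' @param asym_eye Raw leftward-positive asymmetry on the eye clock, %.
#' @param events Detected `saccade_events` for the session.
#' @param trials List of `trial_record`s.
#' @param window Lag window, seconds.
#' @param bin_s Width of the quantification bins, seconds.
#' @param n_shuffles Surrogate sets (set 1 carries the bin-wise tests).
#' @param seed Shuffle seed.
#' @param eye_rate,step Clock parameters.
#' @param min_count Per-lag minimum trace count for the median curves.
#' @param alpha Significance level used by [estimate_lead()] callers.
#' @return List of class `correlogram_result`: `lags`, `real` / `null`
#'   (per-lag `median`, `q25`, `q75`, `n`), `bins` (data.frame: start, end,
#'   real/null medians, Mann-Whitney p, Bonferroni-adjusted p, elevated
#'   flag), `n_events`, `traces`, `null_traces_test`.
#' @export
correlogram <- function(asym_eye, events, trials, window = c(-0.5, 0.8),
                        bin_s = 0.1, n_shuffles = 100L, seed = 1L,
                        eye_rate = 100, step = 2L, min_count = 5L,
                        alpha = 0.05) {
  real <- triggered_traces(asym_eye, events, trials, window, eye_rate, step)
  if (nrow(real$events) == 0)
    fit_error("correlogram: no saccade events within backward epochs")
  surr <- shuffle_event_times(real$events, trials, n_shuffles, seed, step, eye_rate)
  surr_traces <- lapply(surr, function(ev)
    triggered_traces(asym_eye, ev, trials, window, eye_rate, step)$traces)

  curve_stats <- function(M) {
    n <- colSums(!is.na(M))
    med <- apply(M, 2, stats::median, na.rm = TRUE)
    q25 <- apply(M, 2, stats::quantile, probs = 0.25, na.rm = TRUE, names = FALSE)
    q75 <- apply(M, 2, stats::quantile, probs = 0.75, na.rm = TRUE, names = FALSE)
    med[n < min_count] <- NA; q25[n < min_count] <- NA; q75[n < min_count] <- NA
    list(median = med, q25 = q25, q75 = q75, n = n)
  }
  null_pool <- do.call(rbind, surr_traces)

  rb <- per_bin_medians(real$traces, real$lags, bin_s)
  nb_test <- per_bin_medians(surr_traces[[1L]], real$lags, bin_s)
  nbins <- ncol(rb$medians)
  bins <- do.call(rbind, lapply(seq_len(nbins), function(b) {
    x <- rb$medians[, b]; y <- nb_test$medians[, b]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    pv <- if (length(x) >= 1 && length(y) >= 1)
      mann_whitney_u(x, y)$p_value else NA_real_
    data.frame(start = rb$starts[b], end = rb$starts[b] + bin_s,
               real_median = stats::median(x), null_median = stats::median(y),
               n_real = length(x), n_null = length(y), p_value = pv)
  }))
  bins$p_adjusted <- bonferroni(bins$p_value, sum(is.finite(bins$p_value)))
  bins$elevated <- bins$real_median > bins$null_median

  structure(list(
    lags = real$lags,
    real = curve_stats(real$traces),
    null = curve_stats(null_pool),
    bins = bins,
    n_events = nrow(real$events),
    traces = real$traces,
    null_traces_test = surr_traces[[1L]],
    events = real$events
  ), class = "correlogram_result")
}

#' Pool correlograms across sessions
#'
#' Concatenates the per-event traces (and the designated test surrogate
#' sets) of several sessions' correlograms on a shared lag axis and
#' recomputes the medians, percentile bands and bin-wise statistics, the
#' way multi-session event counts are pooled into one quantification.
#'
#' @param cgs List of `correlogram_result`s with identical lag axes.
#' @param bin_s Quantification bin width, seconds.
#' @param min_count Per-lag minimum trace count for the median curves.
#' @return A `correlogram_result` over the pooled events.
#' @export
pool_correlograms <- function(cgs, bin_s = 0.1, min_count = 5L) {
  cgs <- cgs[!vapply(cgs, is.null, TRUE)]
  if (length(cgs) == 0) fit_error("pool_correlograms: no correlograms to pool")
  lags <- cgs[[1]]$lags
  for (cg in cgs) if (!isTRUE(all.equal(cg$lags, lags)))
    format_error("pool_correlograms: lag axes differ")
  traces <- do.call(rbind, lapply(cgs, `[[`, "traces"))
  null_test <- do.call(rbind, lapply(cgs, `[[`, "null_traces_test"))
  curve_stats <- function(M) {
    n <- colSums(!is.na(M))
    med <- apply(M, 2, stats::median, na.rm = TRUE)
    q25 <- apply(M, 2, stats::quantile, probs = 0.25, na.rm = TRUE, names = FALSE)
    q75 <- apply(M, 2, stats::quantile, probs = 0.75, na.rm = TRUE, names = FALSE)
    med[n < min_count] <- NA; q25[n < min_count] <- NA; q75[n < min_count] <- NA
    list(median = med, q25 = q25, q75 = q75, n = n)
  }
  rb <- per_bin_medians(traces, lags, bin_s)
  nb <- per_bin_medians(null_test, lags, bin_s)
  bins <- do.call(rbind, lapply(seq_len(ncol(rb$medians)), function(b) {
    x <- rb$medians[, b]; y <- nb$medians[, b]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    pv <- if (length(x) >= 1 && length(y) >= 1)
      mann_whitney_u(x, y)$p_value else NA_real_
    data.frame(start = rb$starts[b], end = rb$starts[b] + bin_s,
               real_median = stats::median(x), null_median = stats::median(y),
               n_real = length(x), n_null = length(y), p_value = pv)
  }))
  bins$p_adjusted <- bonferroni(bins$p_value, sum(is.finite(bins$p_value)))
  bins$elevated <- bins$real_median > bins$null_median
  structure(list(lags = lags, real = curve_stats(traces),
                 null = curve_stats(null_test), bins = bins,
                 n_events = nrow(traces), traces = traces,
                 null_traces_test = null_test,
                 events = do.call(rbind, lapply(cgs, `[[`, "events"))),
            class = "correlogram_result")
}

#' Estimated asymmetry lead from a correlogram
#'
#' Scans the pre-saccadic bins backward from saccade onset and returns the
#' start (in seconds, negative) of the earliest bin in the contiguous run
#' of significantly elevated bins ending at onset; NA if the bin adjacent
#' to onset is not significantly elevated.
#'
#' @param cg A `correlogram_result`.
#' @param alpha Significance level applied to the Bonferroni-adjusted
#'   bin-wise p-values.
#' @return Lead bin start in seconds (e.g. -0.2), or NA.
#' @export
estimate_lead <- function(cg, alpha = 0.05) {
  b <- cg$bins
  pre <- which(b$end <= 1e-9)
  if (length(pre) == 0) return(NA_real_)
  pre <- pre[order(b$start[pre], decreasing = TRUE)]  # nearest to onset first
  lead <- NA_real_
  for (i in pre) {
    sig <- is.finite(b$p_adjusted[i]) && b$p_adjusted[i] < alpha && b$elevated[i]
    if (!sig) break
    lead <- b$start[i]
  }
  lead
}
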