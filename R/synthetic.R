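# Synthetic behavioral sessions with known ground truth.
#
# A session is a sequence of self-paced trials, each running through the
# state machine end_of_lane -> backward -> turn -> forward -> expect_reward
# -> lick, separated by short inter-trial gaps. The generator injects:
#   * mirror-image, turn-direction-dependent whisker asymmetry that ramps up
#     during backward movement, reverses during the turn and unwinds during
#     forward movement (so per-trial range normalization leaves a zero
#     baseline outside the asymmetric phases);
#   * conjugate, stepwise pupil deviation toward the turn built from
#     saccadic steps (plus a slow sub-threshold deviation ramp);
#   * saccade times concentrated in the latter half of backward movement;
#   * a whisker-asymmetry rise with its onset a fixed lead time before each
#     backward saccade, so saccade-triggered correlograms recover the lead.
# All randomness is drawn from a private stream seeded by `seed`; cue
# directions only flip signs and never consume randomness, which makes the
# left/right mirror property exact at zero noise.

#' Generator configuration
#'
#' Builds and validates the configuration for [generate_session()].
#' Defaults state the emulated world: 200 Hz whisker / 100 Hz eye clocks,
#' self-paced epochs of a few seconds, whisking at 10 Hz, peak whisker
#' asymmetry of 30% of the trial range rising through most of the backward
#' epoch, eye deviation of 5% of eye width appearing late, about one saccade
#' of ~2.5% eye width per two seconds of active movement weighted toward the
#' latter half of backward movement, and an asymmetry rise leading saccades
#' by 150 ms.
#'
#' @param n_trials Number of trials.
#' @param p_left Probability of a left-turn cue.
#' @param epoch_duration_ranges Named list of `c(min, max)` second ranges for
#'   `end_of_lane`, `backward`, `turn`, `forward`, `expect_reward`, `lick`.
#' @param behavior_rate,eye_rate Frame rates in frames/s; `behavior_rate`
#'   must be an integer multiple of `eye_rate`.
#' @param asymmetry_effect Peak base whisker asymmetry, % of trial range.
#' @param asymmetry_ramp Fraction of the backward epoch over which the base
#'   asymmetry ramps from 0 to peak (ramp occupies the LAST such fraction).
#' @param eye_effect Peak slow pupil-deviation ramp, % of eye width.
#' @param eye_ramp Fraction of the backward epoch occupied by the eye ramp
#'   (also its last part).
#' @param saccade_rate Saccadic events per second during backward movement
#'   (turn and forward epochs use 0.7 and 0.5 of this rate).
#' @param saccade_amplitude Mean and sd of saccade amplitude, % eye width.
#' @param p_saccade_toward Probability a saccade is directed toward the cued
#'   turn.
#' @param saccade_late_weight Weighting of backward-epoch saccade times
#'   toward the epoch end (0 = uniform; w gives density proportional to
#'   normalized time to the power w).
#' @param asymmetry_lead Seconds by which the coupled asymmetry rise onset
#'   precedes each backward saccade.
#' @param coupling_effect Size of the per-saccade asymmetry increment, % of
#'   trial range (0 disables saccade-whisker coupling).
#' @param coupling_hold Seconds the increment is held after the saccade
#'   before decaying.
#' @param noise_sd_whisker Additive white noise on whisker angles, degrees.
#' @param noise_sd_eye Additive white noise on normalized pupil position,
#'   % of eye width.
#' @param whisk_freq Whisking frequency, Hz.
#' @param whisk_amplitude Whisking sinusoid amplitude, degrees.
#' @param min_saccade_interval Minimum spacing between injected saccades,
#'   seconds (kept above the detector's 250 ms refractory window).
#' @param gap_s Inter-trial gap, seconds.
#' @param directions Optional explicit character vector of cued directions
#'   (`"left"`/`"right"`, length `n_trials`); overrides `p_left` without
#'   consuming randomness.
#' @param seed Integer seed for the generator's private RNG stream.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_trials = 20,
                             p_left = 0.5,
                             epoch_duration_ranges = list(
                               end_of_lane = c(1.5, 3), backward = c(2.5, 4.5),
                               turn = c(1.5, 3), forward = c(2, 4),
                               expect_reward = c(1, 2), lick = c(1, 2)),
                             behavior_rate = 200,
                             eye_rate = 100,
                             asymmetry_effect = 30,
                             asymmetry_ramp = 0.9,
                             eye_effect = 5,
                             eye_ramp = 0.4,
                             saccade_rate = 0.5,
                             saccade_amplitude = c(mean = 2.5, sd = 0.8),
                             p_saccade_toward = 0.8,
                             saccade_late_weight = 1,
                             asymmetry_lead = 0.15,
                             coupling_effect = 15,
                             coupling_hold = 0.4,
                             noise_sd_whisker = 0.5,
                             noise_sd_eye = 0.02,
                             whisk_freq = 10,
                             whisk_amplitude = 15,
                             min_saccade_interval = 0.35,
                             gap_s = 1,
                             directions = NULL,
                             seed = 1L) {
  check_scalar(n_trials, "n_trials", positive = TRUE, integer = TRUE)
  check_scalar(p_left, "p_left", lo = 0, hi = 1)
  check_scalar(behavior_rate, "behavior_rate", positive = TRUE)
  check_scalar(eye_rate, "eye_rate", positive = TRUE)
  if (behavior_rate %% eye_rate != 0)
    config_error("field 'behavior_rate' must be an integer multiple of eye_rate",
                 "behavior_rate")
  need_states <- c("end_of_lane", "backward", "turn", "forward", "expect_reward", "lick")
  if (!all(need_states %in% names(epoch_duration_ranges)))
    config_error("field 'epoch_duration_ranges' must name all six states",
                 "epoch_duration_ranges")
  for (st in need_states) {
    rg <- epoch_duration_ranges[[st]]
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[1] <= 0 || rg[2] < rg[1])
      config_error(sprintf("field 'epoch_duration_ranges$%s' must be 0 < min <= max", st),
                   "epoch_duration_ranges")
  }
  check_scalar(asymmetry_effect, "asymmetry_effect", nonneg = TRUE, hi = 70)
  check_scalar(asymmetry_ramp, "asymmetry_ramp", lo = 0.05, hi = 1)
  check_scalar(eye_effect, "eye_effect", nonneg = TRUE)
  check_scalar(eye_ramp, "eye_ramp", lo = 0.05, hi = 1)
  check_scalar(saccade_rate, "saccade_rate", nonneg = TRUE)
  if (length(saccade_amplitude) != 2 || any(saccade_amplitude < 0))
    config_error("field 'saccade_amplitude' must be c(mean, sd) >= 0", "saccade_amplitude")
  check_scalar(p_saccade_toward, "p_saccade_toward", lo = 0, hi = 1)
  check_scalar(saccade_late_weight, "saccade_late_weight", nonneg = TRUE)
  check_scalar(asymmetry_lead, "asymmetry_lead", nonneg = TRUE)
  check_scalar(coupling_effect, "coupling_effect", nonneg = TRUE, hi = 70)
  check_scalar(coupling_hold, "coupling_hold", nonneg = TRUE)
  check_scalar(noise_sd_whisker, "noise_sd_whisker", nonneg = TRUE)
  check_scalar(noise_sd_eye, "noise_sd_eye", nonneg = TRUE)
  check_scalar(whisk_freq, "whisk_freq", positive = TRUE)
  check_scalar(whisk_amplitude, "whisk_amplitude", positive = TRUE)
  check_scalar(min_saccade_interval, "min_saccade_interval", positive = TRUE)
  check_scalar(gap_s, "gap_s", positive = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  if (!is.null(directions)) {
    if (length(directions) != n_trials || !all(directions %in% c("left", "right")))
      config_error("field 'directions' must be length n_trials of left/right", "directions")
  }
  cfg <- list(n_trials = as.integer(n_trials), p_left = p_left,
              epoch_duration_ranges = epoch_duration_ranges,
              behavior_rate = behavior_rate, eye_rate = eye_rate,
              asymmetry_effect = asymmetry_effect, asymmetry_ramp = asymmetry_ramp,
              eye_effect = eye_effect, eye_ramp = eye_ramp,
              saccade_rate = saccade_rate,
              saccade_amplitude = c(mean = unname(saccade_amplitude[1]),
                                    sd = unname(saccade_amplitude[2])),
              p_saccade_toward = p_saccade_toward,
              saccade_late_weight = saccade_late_weight,
              asymmetry_lead = asymmetry_lead, coupling_effect = coupling_effect,
              coupling_hold = coupling_hold,
              noise_sd_whisker = noise_sd_whisker, noise_sd_eye = noise_sd_eye,
              whisk_freq = whisk_freq, whisk_amplitude = whisk_amplitude,
              min_saccade_interval = min_saccade_interval, gap_s = gap_s,
              directions = directions, seed = as.integer(seed))
  structure(cfg, class = "generator_config")
}

# helper: even frame count on the behavior clock (keeps eye clock aligned)
even_frames <- function(dur_s, rate, step) {
  n <- round(dur_s * rate / step) * step
  max(n, 2L * step)
}

#' Generate a synthetic session
#'
#' @param config A `generator_config`.
#' @return List with elements `session` (a `session_record`) and `truth`
#'   (class `ground_truth`: cue directions, epoch boundaries, injected
#'   saccades, per-trial injected asymmetry profiles, scaling constants and
#'   the full configuration).
#' @export
generate_session <- function(config) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  cfg <- config
  step <- as.integer(cfg$behavior_rate / cfg$eye_rate)
  rate <- cfg$behavior_rate
  states <- c("end_of_lane", "backward", "turn", "forward", "expect_reward", "lick")

  with_seed(cfg$seed, {
    # 1. cue directions (never consume RNG when forced)
    directions <- cfg$directions %||%
      ifelse(stats::runif(cfg$n_trials) < cfg$p_left, "left", "right")

    # 2. epoch durations -> frame layout
    durs <- matrix(0, cfg$n_trials, length(states), dimnames = list(NULL, states))
    for (st in states) {
      rg <- cfg$epoch_duration_ranges[[st]]
      durs[, st] <- stats::runif(cfg$n_trials, rg[1], rg[2])
    }
    gap_frames <- even_frames(cfg$gap_s, rate, step)
    epoch_frames <- apply(durs, c(1, 2), even_frames, rate = rate, step = step)

    epochs <- list(); cursor <- 0L
    for (i in seq_len(cfg$n_trials)) {
      for (st in states) {
        nfr <- epoch_frames[i, st]
        lab <- if (st == "turn") paste0("turn_", directions[i]) else st
        epochs[[length(epochs) + 1L]] <- data.frame(
          trial = i, state = lab, state_generic = st,
          start_frame = cursor, end_frame = cursor + nfr)
        cursor <- cursor + nfr
      }
      cursor <- cursor + gap_frames
    }
    epochs <- do.call(rbind, epochs)
    n_beh <- cursor
    n_eye <- n_beh %/% step

    trial_bounds <- do.call(rbind, lapply(seq_len(cfg$n_trials), function(i) {
      e <- epochs[epochs$trial == i, ]
      data.frame(trial = i, start_frame = min(e$start_frame), end_frame = max(e$end_frame))
    }))

    # 3. saccade injection
    state_rate <- c(backward = 1, turn = 0.7, forward = 0.5)
    sac <- list()
    for (i in seq_len(cfg$n_trials)) {
      for (st in names(state_rate)) {
        e <- epochs[epochs$trial == i & epochs$state_generic == st, ]
        dur <- (e$end_frame - e$start_frame) / rate
        lam <- cfg$saccade_rate * state_rate[[st]] * dur
        n_ev <- stats::rpois(1, lam)
        if (n_ev == 0) next
        u <- stats::runif(n_ev)
        frac <- if (st == "backward" && cfg$saccade_late_weight > 0)
          u^(1 / (1 + cfg$saccade_late_weight)) else u
        t_beh <- e$start_frame + frac * (e$end_frame - e$start_frame)
        amp <- pmax(0.3, stats::rnorm(n_ev, cfg$saccade_amplitude["mean"],
                                      cfg$saccade_amplitude["sd"]))
        toward <- stats::runif(n_ev) < cfg$p_saccade_toward
        dir_ev <- ifelse(toward, directions[i],
                         ifelse(directions[i] == "left", "right", "left"))
        sac[[length(sac) + 1L]] <- data.frame(
          trial = i, state = st, beh_frame = t_beh, direction = dir_ev, amplitude = amp)
      }
    }
    sac <- if (length(sac)) do.call(rbind, sac) else
      data.frame(trial = integer(), state = character(), beh_frame = numeric(),
                 direction = character(), amplitude = numeric())
    if (nrow(sac) > 0) {
      # snap to the eye clock and keep clear of epoch edges
      sac$eye_frame <- pmax(2L, as.integer(round(sac$beh_frame / step)))
      sac <- sac[order(sac$eye_frame), , drop = FALSE]
      sac <- sac[!duplicated(sac$eye_frame), , drop = FALSE]
      # enforce the minimum inter-saccade interval by sequential thinning
      keep <- logical(nrow(sac)); last <- -Inf
      min_gap <- cfg$min_saccade_interval * cfg$eye_rate
      for (j in seq_len(nrow(sac))) {
        if (sac$eye_frame[j] - last >= min_gap) { keep[j] <- TRUE; last <- sac$eye_frame[j] }
      }
      sac <- sac[keep, , drop = FALSE]
      sac$time_s <- (sac$eye_frame - 1) / cfg$eye_rate
      sac$beh_frame <- sac$eye_frame * step  # aligned behavior-clock frame
      rownames(sac) <- NULL
    } else {
      sac$eye_frame <- integer(); sac$time_s <- numeric()
    }

    # 4. eye traces (lambda = head-centered deviation, % eye width, leftward +)
    lam <- numeric(n_eye)
    impulses <- numeric(n_eye)
    if (nrow(sac) > 0) {
      sgn <- ifelse(sac$direction == "left", 1, -1)
      impulses[sac$eye_frame] <- sgn * sac$amplitude
    }
    tau_f <- 2.5 * cfg$eye_rate  # inter-trial relaxation time constant, frames
    lam0 <- 0
    for (i in seq_len(cfg$n_trials)) {
      ts <- trial_bounds$start_frame[i] %/% step + 1L
      te <- trial_bounds$end_frame[i] %/% step
      lam[ts:te] <- lam0 + cumsum(impulses[ts:te])
      lam0 <- lam[te]
      ge <- if (i < cfg$n_trials) trial_bounds$start_frame[i + 1L] %/% step else n_eye
      if (ge > te) {
        gl <- seq_len(ge - te)
        lam[te + gl] <- lam0 * exp(-gl / tau_f)
        lam0 <- lam[ge]
      }
    }
    # slow deviation ramp toward the turn (sub-threshold by construction)
    ramp_eye <- numeric(n_eye)
    for (i in seq_len(cfg$n_trials)) {
      s_turn <- if (directions[i] == "left") 1 else -1
      e <- epochs[epochs$trial == i, ]
      for (st in c("backward", "turn", "forward")) {
        r <- e[e$state_generic == st, ]
        fs <- (r$start_frame %/% step + 1L):(r$end_frame %/% step)
        frac <- seq(0, 1, length.out = length(fs))
        ramp_eye[fs] <- s_turn * switch(st,
          backward = cfg$eye_effect * pmax(0, (frac - (1 - cfg$eye_ramp)) / cfg$eye_ramp),
          turn = cfg$eye_effect,
          forward = cfg$eye_effect * (1 - frac))
      }
    }
    lam <- lam + ramp_eye
    pupil_left  <- 0.5 + lam / 100 + stats::rnorm(n_eye, 0, cfg$noise_sd_eye / 100)
    pupil_right <- 0.5 - lam / 100 + stats::rnorm(n_eye, 0, cfg$noise_sd_eye / 100)

    # 5. whisker traces
    W <- cfg$whisk_amplitude
    t_beh_s <- (seq_len(n_beh) - 1) / rate
    phases <- stats::runif(cfg$n_trials, 0, 2 * pi)
    noise_l <- stats::rnorm(n_beh, 0, cfg$noise_sd_whisker)
    noise_r <- stats::rnorm(n_beh, 0, cfg$noise_sd_whisker)

    asym_profiles <- vector("list", cfg$n_trials)
    k_trial <- numeric(cfg$n_trials)
    setpt <- numeric(n_beh)   # d(t)/2 in degrees, applied +/- per side
    amp_lvl <- rep(0.2, n_beh)  # whisking amplitude level (quiet default)
    phase_vec <- numeric(n_beh)

    for (i in seq_len(cfg$n_trials)) {
      s_turn <- if (directions[i] == "left") 1 else -1
      tb <- trial_bounds[i, ]
      fs <- (tb$start_frame + 1L):tb$end_frame
      a <- numeric(length(fs))
      e <- epochs[epochs$trial == i, ]
      seg <- function(st) {
        r <- e[e$state_generic == st, ]
        list(sel = (r$start_frame + 1L):r$end_frame - tb$start_frame,
             dur = (r$end_frame - r$start_frame) / rate)
      }
      # The base profile rises to +peak inside the backward ramp window
      # with a plateau of hold_s seconds. Saccade-coupled increments are
      # added next (backward saccades only; logistic rise with onset
      # asymmetry_lead seconds before the event, held for coupling_hold,
      # then decaying). The turn epoch then reverses the profile down to
      # MINUS the realized backward maximum with a hold of the same
      # duration, and forward movement unwinds it to zero. Symmetric
      # extremes with equal dwell TIME matter: per-trial min/max
      # normalization is sensitive to the extremes and their occupancy,
      # and any asymmetry would leak the cue direction into the flat
      # early-backward baseline.
      hold_s <- 0.3
      bw <- seg("backward")
      hb <- min(hold_s / bw$dur, 0.5 * cfg$asymmetry_ramp)
      lo <- 1 - cfg$asymmetry_ramp
      frac <- seq(0, 1, length.out = length(bw$sel))
      a[bw$sel] <- s_turn * cfg$asymmetry_effect *
        pmin(1, pmax(0, (frac - lo) / (1 - hb - lo)))
      # whisking active during movement epochs
      for (st in c("backward", "turn", "forward")) {
        r <- e[e$state_generic == st, ]
        amp_lvl[(r$start_frame + 1L):r$end_frame] <- 1
      }
      # saccade-coupled asymmetry increments (backward saccades only)
      if (cfg$coupling_effect > 0 && nrow(sac) > 0) {
        ev <- sac[sac$trial == i & sac$state == "backward", , drop = FALSE]
        if (nrow(ev) > 0) {
          tt <- t_beh_s[fs]
          for (j in seq_len(nrow(ev))) {
            s_ev <- if (ev$direction[j] == "left") 1 else -1
            onset <- ev$time_s[j] - cfg$asymmetry_lead
            rise <- stats::plogis((tt - onset) / 0.01)
            fall <- stats::plogis(-(tt - ev$time_s[j] - cfg$coupling_hold) / 0.05)
            a <- a + s_ev * cfg$coupling_effect * rise * fall
          }
        }
      }
      m_peak <- max(abs(a[bw$sel]))
      tu <- seg("turn")
      ht <- min(hold_s / tu$dur, 0.5)
      frac <- seq(0, 1, length.out = length(tu$sel))
      a[tu$sel] <- a[tu$sel] + s_turn * (cfg$asymmetry_effect +
        (-m_peak - cfg$asymmetry_effect) * pmin(1, frac / (1 - ht)))
      fw <- seg("forward")
      frac <- seq(0, 1, length.out = length(fw$sel))
      a[fw$sel] <- a[fw$sel] - s_turn * m_peak * pmax(0, 1 - 2 * frac)
      span_a <- max(a) - min(a)
      if (span_a >= 160)
        config_error("combined asymmetry effects too large for range normalization",
                     "asymmetry_effect")
      k <- 2 * W / (100 - span_a / 2)
      asym_profiles[[i]] <- a
      k_trial[i] <- k
      setpt[fs] <- k * a / 2
      phase_vec[fs] <- phases[i]
    }

    whisk <- W * amp_lvl * sin(2 * pi * cfg$whisk_freq * t_beh_s + phase_vec)
    whisker_right <- setpt + whisk + noise_r
    whisker_left  <- -setpt + whisk + noise_l

    # 6. assemble records
    trials <- lapply(seq_len(cfg$n_trials), function(i) {
      e <- epochs[epochs$trial == i, ]
      trial_record(i, directions[i],
                   data.frame(state = e$state, start_frame = e$start_frame,
                              end_frame = e$end_frame))
    })
    session <- session_record(
      animal_id = "SYN", session_id = sprintf("syn-seed%d", cfg$seed),
      behavior_rate = rate, eye_rate = cfg$eye_rate,
      trials = trials,
      whisker_traces = list(left = whisker_left, right = whisker_right),
      pupil_traces = list(left = pupil_left, right = pupil_right),
      eye_geometry = list(left = canonical_eye_geometry(),
                          right = canonical_eye_geometry())
    )
    truth <- structure(list(
      directions = directions,
      trial_bounds = trial_bounds,
      epochs = epochs,
      saccades = sac,
      asym_profiles = asym_profiles,
      k_trial = k_trial,
      lambda = lam,
      config = cfg
    ), class = "ground_truth")
    list(session = session, truth = truth)
  })
}

# The synthetic eye camera frame: 192 x 200 px, eyelid parabolas crossing at
# (40, 100) and (152, 100), i.e. an eye width of 112 px.
canonical_eye_geometry <- function() {
  a <- 40 / 56^2
  top <- c(a = a, b = -2 * a * 96, c = a * 96^2 + 60)
  bottom <- c(a = -a, b = 2 * a * 96, c = -a * 96^2 + 140)
  structure(list(
    top = top, bottom = bottom,
    corners = rbind(nasal = c(x = 40, y = 100), temporal = c(x = 152, y = 100)),
    width = 112
  ), class = "eye_geometry")
}

#' Generate raw keypoint tables for a synthetic session
#'
#' Emits the pixel-level inputs the geometry stage consumes: per eye and
#' frame, 8 points on an ellipse centered at the true pupil position;
#' per-eye eyelid point sets on the two known parabolas; and per-side 2D
#' whisker positions on a known circular arc at the true whisking angle.
#' With `noise_px = 0` the geometry stage recovers the injected truth to
#' machine precision.
#'
#' @param session,truth Output of [generate_session()].
#' @param noise_px Gaussian pixel noise added to every emitted point.
#' @param seed Seed for the keypoint noise stream.
#' @return List with `pupil` (per eye: long keypoint data.frame of 8 edge
#'   points), `eyelids` (per eye: `top`/`bottom` point matrices),
#'   `whisker` (per side: long keypoint data.frame), and `arcs` (the true
#'   whisker circle parameters: center, radius, base angle per side).
#' @export
generate_keypoints <- function(session, truth, noise_px = 0, seed = 1L) {
  stopifnot(inherits(session, "session_record"))
  geom <- canonical_eye_geometry()
  n_eye <- length(session$pupil_traces$left)
  n_beh <- length(session$whisker_traces$left)
  semi <- c(15, 11); theta <- 0.25
  arcs <- list(center = c(x = 600, y = 350), radius = 250,
               base_angle = c(left = 120, right = 60))
  with_seed(seed, {
    pupil <- lapply(c(left = "left", right = "right"), function(eye) {
      pos <- session$pupil_traces[[eye]]
      cx <- geom$corners[1, 1] + pos * (geom$corners[2, 1] - geom$corners[1, 1])
      cy <- geom$corners[1, 2] + pos * (geom$corners[2, 2] - geom$corners[1, 2])
      ang <- 2 * pi * (0:7) / 8
      do.call(rbind, lapply(1:8, function(k) {
        px <- cx + semi[1] * cos(ang[k]) * cos(theta) - semi[2] * sin(ang[k]) * sin(theta)
        py <- cy + semi[1] * cos(ang[k]) * sin(theta) + semi[2] * sin(ang[k]) * cos(theta)
        data.frame(frame = seq_len(n_eye) - 1L, bodypart = sprintf("pupil_%d", k),
                   x = px + stats::rnorm(n_eye, 0, noise_px),
                   y = py + stats::rnorm(n_eye, 0, noise_px),
                   likelihood = 1)
      }))
    })
    eyelids <- lapply(c(left = "left", right = "right"), function(eye) {
      xs <- seq(geom$corners[1, 1], geom$corners[2, 1], length.out = 11)
      lapply(list(top = geom$top, bottom = geom$bottom), function(co) {
        cbind(x = xs + stats::rnorm(11, 0, noise_px),
              y = co[1] * xs^2 + co[2] * xs + co[3] + stats::rnorm(11, 0, noise_px))
      })
    })
    whisker <- lapply(c(left = "left", right = "right"), function(side) {
      ang <- (arcs$base_angle[[side]] + session$whisker_traces[[side]]) * pi / 180
      data.frame(frame = seq_len(n_beh) - 1L, bodypart = paste0("whisker_", side),
                 x = arcs$center[1] + arcs$radius * cos(ang) + stats::rnorm(n_beh, 0, noise_px),
                 y = arcs$center[2] + arcs$radius * sin(ang) + stats::rnorm(n_beh, 0, noise_px),
                 likelihood = 1)
    })
    list(pupil = pupil, eyelids = eyelids, whisker = whisker, arcs = arcs)
  })
}
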