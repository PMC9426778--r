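test_that("interpolate_missing fills linear gaps and enforces limits", {
  expect_equal(interpolate_missing(c(1, NA, 3))$values, c(1, 2, 3))
  expect_equal(interpolate_missing(c(1, NA, 3))$n_filled, 1L)
  x <- c(2, 4, 6)
  expect_equal(interpolate_missing(x)$values, x)
  expect_equal(interpolate_missing(c(NA, 5, 6))$values, c(5, 5, 6))  # edge hold
  expect_error(interpolate_missing(c(NA, NA)), class = "whiskeye_fit_error")
  expect_error(interpolate_missing(c(1, NA, NA, NA), max_missing_frac = 0.5),
               class = "whiskeye_fit_error")
})

one_trial <- function(n) list(trial_record(1, "left", data.frame(
  state = "backward", start_frame = 0, end_frame = n)))

test_that("normalize_whisker centers on the session median and rescales per trial", {
  tr <- one_trial(3)
  n <- normalize_whisker(c(10, 20, 30), tr)
  expect_equal(n$values, c(0, 50, 100))
  expect_equal(n$normalization_meta$session_median, 20)
  # median of the centered full-session trace is zero by construction
  x <- c(rnorm(50), rnorm(50, 3))
  nx <- normalize_whisker(x, one_trial(100))
  expect_equal(median(x - nx$normalization_meta$session_median), 0)
  # per-trial min/max pinned to 0 and 100
  expect_equal(range(nx$values), c(0, 100))
  expect_error(normalize_whisker(rep(5, 10), one_trial(10)),
               class = "whiskeye_fit_error")
  # frames outside trials stay NA
  tr2 <- list(trial_record(1, "left", data.frame(
    state = "backward", start_frame = 2, end_frame = 8)))
  n2 <- normalize_whisker(1:10, tr2)
  expect_true(all(is.na(n2$values[c(1, 2, 9, 10)])))
  expect_false(anyNA(n2$values[3:8]))
})

mk_nt <- function(v) structure(list(values = v, clock = 200,
                                    normalization_meta = NULL),
                               class = "normalized_trace")

test_that("asymmetry applies the turn-direction sign rule", {
  trL <- list(trial_record(1, "left", data.frame(
    state = "backward", start_frame = 0, end_frame = 1)))
  trR <- list(trial_record(1, "right", data.frame(
    state = "backward", start_frame = 0, end_frame = 1)))
  expect_equal(asymmetry(mk_nt(20), mk_nt(60), trL)$values, 40)   # w_R - w_L
  expect_equal(asymmetry(mk_nt(20), mk_nt(60), trR)$values, -40)  # w_L - w_R
  expect_equal(asymmetry(mk_nt(35), mk_nt(35), trL)$values, 0)
  expect_equal(asymmetry(mk_nt(35), mk_nt(35), trR)$values, 0)
  expect_equal(asymmetry(mk_nt(20), mk_nt(60), trR, signed = FALSE)$values, 40)
  expect_error(asymmetry(mk_nt(c(1, 2)), mk_nt(1), trL),
               class = "whiskeye_format_error")
})

test_that("pupil_deviation averages head-centered eyes and signs toward the turn", {
  # constant baseline plus a symmetric conjugate 2% leftward deviation
  base <- rep(0.5, 100)
  dev <- c(rep(0, 50), rep(0.02, 50))
  left <- base + dev        # left eye: temporal (leftward) = increasing
  right <- base - dev       # right eye: nasal (leftward) = decreasing
  trL <- list(trial_record(1, "left", data.frame(
    state = "backward", start_frame = 0, end_frame = 200)))
  trR <- list(trial_record(1, "right", data.frame(
    state = "backward", start_frame = 0, end_frame = 200)))
  pd <- pupil_deviation(left, right, trL)
  expect_equal(pd$deviation_leftward[100] - pd$deviation_leftward[1], 2)
  expect_equal(pd$deviation_signed[100] - pd$deviation_signed[1], 2)
  pdR <- pupil_deviation(left, right, trR)
  expect_equal(pdR$deviation_signed[100] - pdR$deviation_signed[1], -2)
  # unequal eyes average before signing: +3% and +1% -> mean 2%
  pd2 <- pupil_deviation(base + c(rep(0, 50), rep(0.03, 50)),
                         base - c(rep(0, 50), rep(0.01, 50)))
  expect_equal(pd2$deviation_leftward[100] - pd2$deviation_leftward[1], 2)
})

test_that("time_normalize resamples linearly and preserves endpoints", {
  expect_equal(time_normalize(rep(3, 10), 21), rep(3, 21))
  ramp <- seq(0, 1, length.out = 50)
  expect_equal(time_normalize(ramp, 11), seq(0, 1, length.out = 11))
  # linearity oracle: downsample then upsample of a line is exact
  line <- seq(-2, 5, length.out = 81)
  down <- time_normalize(line, 21)
  expect_equal(time_normalize(down, 81), line, tolerance = 1e-12)
  # min/max of monotone traces preserved exactly (endpoints)
  mono <- cumsum(runif(40))
  tn <- time_normalize(mono, 17)
  expect_equal(range(tn), range(mono))
  expect_error(time_normalize(1), class = "whiskeye_fit_error")
})

test_that("epoch_summary produces median and interquartile bands", {
  s <- tiny_session()
  # single epoch per group: band collapses onto the median
  es <- epoch_summary(seq_len(2600), s$trials, states = "backward")
  b <- es$bands[es$bands$direction == "left", ]
  expect_equal(b$median, b$q25)
  expect_equal(b$median, b$q75)
  # symmetric +/- c epochs have median 0: build a trace +c on trial 1, -c on trial 2
  tr3 <- list(
    trial_record(1, "left", data.frame(state = "backward", start_frame = 0, end_frame = 100)),
    trial_record(2, "left", data.frame(state = "backward", start_frame = 100, end_frame = 200)))
  tra <- c(rep(4, 100), rep(-4, 100))
  es2 <- epoch_summary(tra, tr3, states = "backward")
  expect_equal(unique(es2$bands$median), 0)
  # percentile oracle: quartiles match sorting-based quantile on the columns
  set.seed(31)
  tr4 <- lapply(1:5, function(i) trial_record(i, "left", data.frame(
    state = "backward", start_frame = (i - 1) * 100, end_frame = i * 100)))
  vals <- rnorm(500)
  es3 <- epoch_summary(vals, tr4, states = "backward", n_points = 11)
  m <- t(sapply(1:5, function(i) time_normalize(vals[((i - 1) * 100 + 1):(i * 100)], 11)))
  expect_equal(es3$bands$q25, apply(m, 2, quantile, 0.25, names = FALSE))
  expect_equal(es3$bands$median, apply(m, 2, median))
})

test_that("the injected asymmetry effect is recovered from noiseless sessions", {
  g <- generate_session(quick_config(n_trials = 8, seed = 44, noise_sd_whisker = 0,
                                     noise_sd_eye = 0, coupling_effect = 0,
                                     asymmetry_effect = 30))
  kin <- session_kinematics(g$session)
  es <- epoch_summary(kin$asym_signed$values, g$session$trials, states = "backward")
  plateau <- median(es$bands$median[es$bands$time > 0.95])
  expect_lt(abs(plateau - 30) / 30, 0.15)
  # mirror antisymmetry: mean signed asymmetry positive toward turn for BOTH cues
  for (d in c("left", "right")) {
    bd <- es$bands[es$bands$direction == d & es$bands$time > 0.9, ]
    if (nrow(bd) > 0) expect_gt(mean(bd$median), 15)
  }
})

test_that("session_kinematics downsamples whiskers to the eye clock by 2-frame averaging", {
  g <- generate_session(quick_config(n_trials = 2, seed = 9))
  kin <- session_kinematics(g$session)
  expect_equal(length(kin$asym_raw_eye), length(g$session$pupil_traces$left))
  v <- kin$asym_raw$values
  expect_equal(kin$asym_raw_eye[3], mean(v[5:6]))
})

test_that("epoch_summary can split epochs into halves for reference statistics", {
  tr <- list(trial_record(1, "left", data.frame(
    state = "end_of_lane", start_frame = 0, end_frame = 100)))
  trace <- c(rep(1, 50), rep(3, 50))
  es <- epoch_summary(trace, tr, states = "end_of_lane", split_halves = TRUE)
  em <- es$epoch_means
  expect_equal(em$mean[is.na(em$half)], 2)
  expect_equal(em$mean[!is.na(em$half) & em$half == 1], 1)
  expect_equal(em$mean[!is.na(em$half) & em$half == 2], 3)
})
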