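test_that("generator configuration errors name the offending field", {
  expect_error(generator_config(n_trials = 0), class = "whiskeye_config_error",
               regexp = "n_trials")
  expect_error(generator_config(p_left = 1.5), class = "whiskeye_config_error",
               regexp = "p_left")
  expect_error(generator_config(behavior_rate = 150, eye_rate = 100),
               class = "whiskeye_config_error", regexp = "behavior_rate")
  expect_error(generator_config(epoch_duration_ranges = list(backward = c(1, 2))),
               class = "whiskeye_config_error", regexp = "epoch_duration_ranges")
  expect_error(generator_config(saccade_rate = -1), class = "whiskeye_config_error",
               regexp = "saccade_rate")
  expect_error(generator_config(directions = c("left", "up")),
               class = "whiskeye_config_error", regexp = "directions")
})

test_that("identical seeds give identical sessions at every stage", {
  g1 <- generate_session(quick_config(seed = 1))
  g2 <- generate_session(quick_config(seed = 1))
  expect_identical(g1, g2)
  g3 <- generate_session(quick_config(seed = 2))
  expect_false(identical(g1$session$whisker_traces$left,
                         g3$session$whisker_traces$left))
  # downstream stages are deterministic too
  a1 <- analyze_session(g1$session, list(seed = 7, n_shuffles = 5))
  a2 <- analyze_session(g2$session, list(seed = 7, n_shuffles = 5))
  expect_identical(a1$events, a2$events)
  expect_identical(a1$table_epoch, a2$table_epoch)
})

test_that("annotations match the injected state machine and truth is consistent", {
  g <- generate_session(quick_config(n_trials = 4, seed = 3))
  expect_equal(length(g$session$trials), 4L)
  for (i in 1:4) {
    tr <- g$session$trials[[i]]
    expect_equal(tr$cued_direction, g$truth$directions[i])
    expect_equal(tr$epochs$state[2], "backward")
    expect_equal(tr$epochs$state[3], paste0("turn_", tr$cued_direction))
    # contiguous, strictly increasing boundaries
    expect_true(all(diff(tr$epochs$start_frame) > 0))
    expect_equal(tr$epochs$start_frame[-1], tr$epochs$end_frame[-6])
  }
  # injected saccades lie within their trial bounds
  sac <- g$truth$saccades
  if (nrow(sac) > 0) {
    for (j in seq_len(nrow(sac))) {
      tb <- g$truth$trial_bounds[sac$trial[j], ]
      expect_gte(sac$beh_frame[j], tb$start_frame)
      expect_lte(sac$beh_frame[j], tb$end_frame)
    }
  }
})

test_that("zero-effect configuration yields chance-level prediction", {
  tabs <- lapply(1:3, function(i) {
    g <- generate_session(quick_config(
      n_trials = 12, seed = 400 + i, asymmetry_effect = 0, eye_effect = 0,
      coupling_effect = 0, p_saccade_toward = 0.5))
    bin_predictors(g$session)
  })
  tab <- do.call(rbind, tabs)
  aucs <- sapply(1:5, function(b) {
    tb <- tab[tab$bin == b, ]
    roc_curve(tb$whisker, tb$label)$auc
  })
  expect_true(all(abs(aucs - 0.5) < 0.2))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("injected saccades are all recovered on noiseless traces (seeded example)", {
  g <- generate_session(generator_config(n_trials = 20, seed = 7, saccade_rate = 0.5,
                                         noise_sd_eye = 0))
  an <- analyze_session(g$session)
  truth <- g$truth$saccades
  expect_gt(nrow(truth), 0)
  expect_setequal(an$events$frame, truth$eye_frame)
  got_dir <- an$events$direction[order(an$events$frame)]
  want_dir <- ifelse(truth$direction[order(truth$eye_frame)] == "left",
                     "leftward", "rightward")
  expect_equal(got_dir, want_dir)
})

test_that("mirroring the cue directions mirrors the traces exactly at zero noise", {
  dirs <- c("left", "right", "left", "left", "right", "right")
  base <- list(n_trials = 6, seed = 5, noise_sd_whisker = 0, noise_sd_eye = 0)
  gA <- generate_session(do.call(quick_config, c(base, list(directions = dirs))))
  flip <- ifelse(dirs == "left", "right", "left")
  gB <- generate_session(do.call(quick_config, c(base, list(directions = flip))))
  expect_equal(gB$session$whisker_traces$left, gA$session$whisker_traces$right,
               tolerance = 1e-12)
  expect_equal(gB$session$whisker_traces$right, gA$session$whisker_traces$left,
               tolerance = 1e-12)
  expect_equal(gB$session$pupil_traces$left, gA$session$pupil_traces$right,
               tolerance = 1e-12)
  expect_equal(gB$truth$lambda, -gA$truth$lambda, tolerance = 1e-12)
})

test_that("bin-5 AUC is non-decreasing in the asymmetry effect size", {
  grid <- c(0, 10, 30)
  med <- sapply(grid, function(eff) {
    aucs <- sapply(1:4, function(i) {
      g <- generate_session(quick_config(n_trials = 12, seed = 600 + i,
                                         asymmetry_effect = eff,
                                         coupling_effect = 0))
      tab <- bin_predictors(g$session)
      tb <- tab[tab$bin == 5, ]
      roc_curve(tb$whisker, tb$label)$auc
    })
    median(aucs)
  })
  expect_true(all(diff(med) >= -1e-9))
  expect_gt(med[3], med[1])
})

test_that("generated keypoints encode the injected geometry", {
  g <- generate_session(quick_config(n_trials = 1, seed = 21))
  kp <- generate_keypoints(g$session, g$truth, noise_px = 0)
  # ellipse fit on one frame recovers the injected pupil center exactly
  fr0 <- kp$pupil$left[kp$pupil$left$frame == 0, ]
  f <- fit_ellipse(cbind(fr0$x, fr0$y))
  geom <- fit_eye_geometry(kp$eyelids$left$top, kp$eyelids$left$bottom)
  expect_equal(normalize_pupil(f$center, geom), g$session$pupil_traces$left[1],
               tolerance = 1e-9)
  # eyelid corners at the canonical analytic intersections
  expect_equal(unname(geom$corners["nasal", ]), c(40, 100), tolerance = 1e-9)
  expect_equal(unname(geom$corners["temporal", ]), c(152, 100), tolerance = 1e-9)
  # whisker circle-fit polar angle equals the injected angle (30 degree check)
  arc <- kp$arcs
  ang_inj <- 30
  pt <- c(arc$center[1] + arc$radius * cos((arc$base_angle[["left"]] + ang_inj) * pi / 180),
          arc$center[2] + arc$radius * sin((arc$base_angle[["left"]] + ang_inj) * pi / 180))
  wf <- fit_circle(cbind(kp$whisker$left$x, kp$whisker$left$y))
  expect_equal(to_polar_angle(pt, wf) - arc$base_angle[["left"]], ang_inj,
               tolerance = 1e-6)
})
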