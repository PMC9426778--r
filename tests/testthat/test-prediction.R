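test_that("bin_predictors lays out one row per epoch-bin with bin means", {
  g <- generate_session(quick_config(n_trials = 6, seed = 51))
  kin <- session_kinematics(g$session)
  tab <- bin_predictors(g$session, kin)
  expect_equal(nrow(tab), 6 * 5)
  expect_equal(sort(unique(tab$trial)), 1:6)
  # oracle: recompute one epoch's bin means directly from the traces
  tr <- g$session$trials[[3]]
  r <- tr$epochs[tr$epochs$state == "backward", ]
  fe <- (r$start_frame %/% 2 + 1):(r$end_frame %/% 2)
  w <- kin$asym_raw_eye[fe]
  cuts <- floor((seq_along(fe) - 1) / length(fe) * 5) + 1
  want <- sapply(1:5, function(b) mean(w[cuts == b]))
  expect_equal(tab$whisker[tab$trial == 3], want)
  # timepoint mode returns every eye-clock sample of the epoch
  tt <- bin_predictors(g$session, kin, per = "timepoint")
  expect_equal(sum(tt$trial == 3), length(fe))
})

test_that("roc_curve sweeps thresholds and equals the pairwise-comparison oracle", {
  # perfect separation
  r <- roc_curve(c(0.8, 0.6, -0.5, -0.7), c("left", "left", "right", "right"))
  expect_equal(r$auc, 1)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  # chance level at large n
  set.seed(52)
  v <- rnorm(2000); lab <- sample(c("left", "right"), 2000, replace = TRUE)
  expect_lt(abs(roc_curve(v, lab)$auc - 0.5), 0.05)
  # AUC equals U / (n1 n2) on arbitrary small samples with ties
  for (i in 1:50) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    x <- sample(1:6, n1, replace = TRUE); y <- sample(1:6, n2, replace = TRUE)
    got <- roc_curve(c(x, y), rep(c("left", "right"), c(n1, n2)))$auc
    expect_equal(got, oracle_auc_pairwise(x, y), tolerance = 1e-12)
  }
  expect_error(roc_curve(1:3, rep("left", 3)), class = "whiskeye_config_error")
})

test_that("roc_analysis nulls are centred and mirror label flips", {
  g <- generate_session(quick_config(n_trials = 12, seed = 53))
  tab <- bin_predictors(g$session)
  res <- roc_analysis(list(tab), n_shuffles = 400, seed = 3)
  # median of shuffled AUCs is within 0.05 of chance
  for (b in 1:5)
    expect_lt(abs(median(res$null_auc[1, b, "whisker", ]) - 0.5), 0.05)
  # relabeling left<->right with value negation leaves AUC unchanged
  tb <- tab[tab$bin == 5, ]
  flip <- ifelse(tb$label == "left", "right", "left")
  expect_equal(roc_curve(-tb$whisker, flip)$auc, roc_curve(tb$whisker, tb$label)$auc)
  # deterministic under the seed
  res2 <- roc_analysis(list(tab), n_shuffles = 400, seed = 3)
  expect_identical(res$null_auc, res2$null_auc)
})

test_that("whisker predicts earlier than the eye when its ramp starts earlier", {
  # asymmetry ramp spans most of the epoch, eye effect confined to the end
  tabs <- lapply(1:6, function(i) {
    g <- generate_session(quick_config(n_trials = 12, seed = 540 + i,
                                       asymmetry_ramp = 0.9, eye_ramp = 0.3,
                                       coupling_effect = 0, saccade_rate = 0.3,
                                       p_saccade_toward = 0.5))
    bin_predictors(g$session)
  })
  res <- roc_analysis(tabs, n_shuffles = 20, seed = 4)
  med <- apply(res$auc, c(2, 3), median, na.rm = TRUE)
  expect_gt(med[2, "whisker"], med[2, "eye"] + 0.1)
  expect_gt(med[3, "whisker"], med[3, "eye"] + 0.1)
})

test_that("fit_separator meets its fidelity anchors and bounds", {
  set.seed(55)
  X <- rbind(matrix(rnorm(60, 3, 0.5), ncol = 2),
             matrix(rnorm(60, -3, 0.5), ncol = 2))
  lab <- rep(c("left", "right"), each = 30)
  fs <- fit_separator(X, lab)
  expect_equal(fs$fidelity, 1)
  expect_equal(fs$predictions, lab)
  # duplicated points with both labels: exactly 0.5
  P <- matrix(rnorm(60), ncol = 2)
  fs2 <- fit_separator(rbind(P, P), rep(c("left", "right"), each = 30))
  expect_equal(fs2$fidelity, 0.5)
  # fidelity never below the majority-class frequency
  for (i in 1:20) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    X3 <- matrix(rnorm(2 * (n1 + n2), sd = sample(c(0.1, 1, 5), 1)), ncol = 2)
    lab3 <- rep(c("left", "right"), c(n1, n2))
    expect_gte(fit_separator(X3, lab3)$fidelity, max(n1, n2) / (n1 + n2) - 1e-12)
  }
  # fidelity in [0.5, 1] for balanced classes
  for (i in 1:10) {
    X4 <- matrix(rnorm(40), ncol = 2)
    f4 <- fit_separator(X4, rep(c("left", "right"), each = 10))$fidelity
    expect_gte(f4, 0.5); expect_lte(f4, 1)
  }
  expect_error(fit_separator(matrix(rnorm(8), ncol = 2), rep("left", 4)),
               class = "whiskeye_config_error")
  # the returned line reproduces the reported predictions
  pr <- ifelse(as.vector(X %*% fs$weights) + fs$intercept > 0, "left", "right")
  expect_equal(pr, fs$predictions)
})

test_that("contribution analysis null fidelity sits near chance for iid points", {
  set.seed(56)
  tabs <- lapply(1:3, function(s) {
    structure(data.frame(trial = rep(1:20, each = 20), label = rep(
      rep(c("left", "right"), 10), each = 20), bin = 1L,
      whisker = rnorm(400), eye = rnorm(400)),
      class = c("predictor_table", "data.frame"))
  })
  ca <- contribution_analysis(tabs, n_shuffles = 10, seed = 2, n_bins = 1)
  nulls <- ca$fidelity$value[ca$fidelity$model == "null"]
  expect_true(all(nulls >= 0.5))
  expect_lt(median(nulls), 0.58)  # small-sample optimism only
  # full model on iid noise is not significantly better than null
  expect_gt(ca$tests$dunn_p_adjusted[ca$tests$model == "null"], 0.05)
})

test_that("the circular-shift null variant is centred and seeded", {
  g <- generate_session(quick_config(n_trials = 12, seed = 57))
  tab <- bin_predictors(g$session)
  r1 <- roc_analysis(list(tab), n_shuffles = 50, seed = 6,
                     null_method = "circular_shift")
  r2 <- roc_analysis(list(tab), n_shuffles = 50, seed = 6,
                     null_method = "circular_shift")
  expect_identical(r1$null_auc, r2$null_auc)
  expect_lt(abs(median(r1$null_auc[1, 3, "whisker", ]) - 0.5), 0.15)
})
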