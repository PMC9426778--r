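# Independent oracles used to freeze expected values. These deliberately
# re-derive quantities by brute force / closed form, not via package code.

# probability a random x exceeds a random y, ties counted half (AUC identity)
oracle_auc_pairwise <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); N <- length(pooled)
  mu <- n1 * length(y) / 2
  u_obs <- oracle_auc_pairwise(x, y) * n1 * length(y)
  idx <- utils::combn(N, n1)
  us <- apply(idx, 2, function(i)
    oracle_auc_pairwise(pooled[i], pooled[-i]) * n1 * length(y))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# closed-form circumcircle of three points
oracle_circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# points on an ellipse, optionally rotated
ellipse_points <- function(cx, cy, a, b, theta = 0, n = 8) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + a * cos(t) * cos(theta) - b * sin(t) * sin(theta),
        cy + a * cos(t) * sin(theta) + b * sin(t) * cos(theta))
}

# small generator shortcut (short epochs, overridable defaults)
quick_config <- function(...) {
  args <- utils::modifyList(list(
    n_trials = 6, epoch_duration_ranges = list(
      end_of_lane = c(1, 1.5), backward = c(1.5, 2.5), turn = c(1, 1.5),
      forward = c(1, 2), expect_reward = c(0.8, 1), lick = c(0.8, 1))),
    list(...))
  do.call(generator_config, args)
}

# a handmade two-trial session with analytically simple traces
tiny_session <- function() {
  states <- c("end_of_lane", "backward", "turn_left", "forward",
              "expect_reward", "lick")
  mk_epochs <- function(off) data.frame(
    state = states, start_frame = off + seq(0, 1000, by = 200),
    end_frame = off + seq(200, 1200, by = 200))
  tr1 <- trial_record(1, "left", mk_epochs(0))
  ep2 <- mk_epochs(1400); ep2$state[3] <- "turn_right"
  tr2 <- trial_record(2, "right", ep2)
  n_beh <- 2600; n_eye <- 1300
  set.seed(99)
  w <- 10 * sin(2 * pi * 10 * (0:(n_beh - 1)) / 200)
  session_record("T", "tiny", 200, 100, list(tr1, tr2),
                 whisker_traces = list(left = w + rnorm(n_beh, 0, 0.3),
                                       right = w + rnorm(n_beh, 0, 0.3)),
                 pupil_traces = list(left = 0.5 + rnorm(n_eye, 0, 2e-4),
                                     right = 0.5 + rnorm(n_eye, 0, 2e-4)))
}
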