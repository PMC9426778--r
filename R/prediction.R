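# Predicting turn direction from whisker asymmetry and eye position during
# backward movement.
#
# The backward epoch is divided into five equal normalized-time bins. Each
# classifier input is a signed raw predictor: whisker asymmetry as right
# whisker protraction minus left (positive preceding left turns), and eye
# position as head-centered deviation with positive = leftward. Per-bin
# prediction quality is measured two ways: single-variable ROC curves
# ("value above threshold -> predict left") summarized by AUC against
# label-shuffled nulls, and a two-variable deterministic linear separator
# whose separation fidelity is the fraction of points on their own side of
# the fitted line, with shuffle-based unique contributions per variable.

#' Per-bin predictor table for backward epochs
#'
#' @param session A `session_record`.
#' @param kin Optional precomputed [session_kinematics()] output.
#' @param n_bins Number of equal normalized-time bins of the backward epoch.
#' @param per `"epoch"` returns one row per epoch and bin holding bin means
#'   (the unit for ROC analysis); `"timepoint"` returns every eye-clock
#'   sample (the unit for the linear separator).
#' @return data.frame of class `predictor_table`: `trial`, `label` (cued
#'   direction), `bin`, `whisker` (raw right-minus-left asymmetry, %),
#'   `eye` (leftward-positive deviation, % eye width).
#' @export
bin_predictors <- function(session, kin = NULL, n_bins = 5L,
                           per = c("epoch", "timepoint")) {
  per <- match.arg(per)
  kin <- kin %||% session_kinematics(session)
  step <- kin$step
  rows <- list()
  for (tr in session$trials) {
    ep <- tr$epochs
    r <- ep[ep$state == "backward", ]
    if (nrow(r) == 0) next
    fe <- (r$start_frame[1] %/% step + 1L):(r$end_frame[1] %/% step)
    w <- kin$asym_raw_eye[fe]
    e <- kin$eye$deviation_leftward[fe]
    frac <- (seq_along(fe) - 1) / length(fe)
    bin <- pmin(n_bins, floor(frac * n_bins) + 1L)
    if (per == "epoch") {
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr$trial_id, label = tr$cued_direction, bin = seq_len(n_bins),
        whisker = tapply(w, bin, mean, na.rm = TRUE)[as.character(seq_len(n_bins))],
        eye = tapply(e, bin, mean, na.rm = TRUE)[as.character(seq_len(n_bins))])
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr$trial_id, label = tr$cued_direction, bin = bin,
        whisker = w, eye = e)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("predictor_table", "data.frame")
  out
}

#' ROC curve by threshold sweep
#'
#' Sweeps a decision threshold over all observed values (the model predicts
#' a left turn when the value exceeds the threshold); tied values cross
#' simultaneously. The trapezoid area under the resulting curve equals the
#' Mann-Whitney `U / (n1 n2)` with midrank tie handling.
#'
#' @param values Numeric predictor values.
#' @param labels Character/factor labels; `positive` marks the left class.
#' @param positive Label treated as positive (left turn).
#' @return List of class `roc_curve`: `fpr`, `tpr` (monotone from (0,0) to
#'   (1,1)), `thresholds`, `auc`.
#' @export
roc_curve <- function(values, labels, positive = "left") {
  labels <- as.character(labels)
  pos <- labels == positive
  if (!any(pos) || all(pos))
    config_error("roc_curve: need at least one example of each class", "labels")
  if (any(is.na(values))) config_error("roc_curve: NA values", "values")
  thr <- sort(unique(values), decreasing = TRUE)
  n1 <- sum(pos); n2 <- sum(!pos)
  tp <- vapply(thr, function(t) sum(values[pos] > t), numeric(1))
  fp <- vapply(thr, function(t) sum(values[!pos] > t), numeric(1))
  tpr <- c(0, tp / n1, 1)
  fpr <- c(0, fp / n2, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = c(Inf, thr, -Inf), auc = auc),
            class = "roc_curve")
}

# fast AUC via midranks (identical to roc_curve()$auc)
auc_value <- function(values, labels, positive = "left") {
  pos <- as.character(labels) == positive
  r <- rank(values)
  n1 <- sum(pos); n2 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Per-bin ROC analysis with shuffled nulls
#'
#' For each session, predictor and time bin, computes the AUC for
#' predicting the cued direction, plus a null distribution of AUCs obtained
#' by permuting the epoch-to-label assignment within the session. Statistical
#' comparisons across sessions use the Mann-Whitney U test: real versus
#' null per bin (the null group holds one independently drawn shuffled AUC
#' per session, which makes the test exchangeable under no effect),
#' whisker- versus eye-based AUCs per bin, and Bonferroni-corrected
#' pairwise bin comparisons per predictor.
#'
#' @param tables List of per-session `predictor_table`s (per = "epoch").
#' @param n_shuffles Label permutations per session.
#' @param seed Seed for the shuffle stream.
#' @param n_bins Number of time bins.
#' @param null_method `"permute_labels"` (default) permutes the
#'   epoch-to-label assignment within the session; `"circular_shift"`
#'   rotates the label vector by a random offset, preserving the serial
#'   order of labels relative to each other.
#' @return List of class `roc_result`: `auc` (session x bin x predictor
#'   array), `null_auc` (session x bin x predictor x shuffle), `p_vs_null`,
#'   `p_whisker_vs_eye`, `p_pairwise_bins` data.frames.
#' @export
roc_analysis <- function(tables, n_shuffles = 200L, seed = 1L, n_bins = 5L,
                         null_method = c("permute_labels", "circular_shift")) {
  null_method <- match.arg(null_method)
  if (inherits(tables, "predictor_table")) tables <- list(tables)
  S <- length(tables)
  preds <- c("whisker", "eye")
  auc <- array(NA_real_, c(S, n_bins, 2), dimnames = list(NULL, NULL, preds))
  null_auc <- array(NA_real_, c(S, n_bins, 2, n_shuffles),
                    dimnames = list(NULL, NULL, preds, NULL))
  with_seed(seed, {
    for (s in seq_len(S)) {
      tab <- tables[[s]]
      for (b in seq_len(n_bins)) {
        tb <- tab[tab$bin == b, ]
        labs <- tb$label
        if (length(unique(labs)) < 2) next
        for (p in preds) {
          v <- tb[[p]]
          sel <- !is.na(v)
          auc[s, b, p] <- auc_value(v[sel], labs[sel])
        }
        for (k in seq_len(n_shuffles)) {
          pl <- if (null_method == "permute_labels") sample(labs) else {
            off <- sample(length(labs) - 1L, 1L)
            labs[c((off + 1L):length(labs), 1L:off)]
          }
          for (p in preds) {
            v <- tb[[p]]
            sel <- !is.na(v)
            null_auc[s, b, p, k] <- auc_value(v[sel], pl[sel])
          }
        }
      }
    }
  })
  # per-session empirical p: rank of the real AUC within its own null draws
  p_empirical <- array(NA_real_, c(S, n_bins, 2), dimnames = list(NULL, NULL, preds))
  for (s in seq_len(S)) for (b in seq_len(n_bins)) for (p in preds) {
    re <- auc[s, b, p]
    if (!is.finite(re)) next
    nu <- null_auc[s, b, p, ]
    p_empirical[s, b, p] <- (1 + sum(nu >= re, na.rm = TRUE)) / (1 + sum(is.finite(nu)))
  }
  p_vs_null <- do.call(rbind, lapply(preds, function(p) {
    do.call(rbind, lapply(seq_len(n_bins), function(b) {
      re <- auc[, b, p]; nu <- null_auc[, b, p, 1L]
      ok <- is.finite(re) & is.finite(nu)
      pv <- if (sum(ok) >= 1)
        mann_whitney_u(re[ok], nu[ok])$p_value else NA_real_
      data.frame(predictor = p, bin = b, median_auc = stats::median(re, na.rm = TRUE),
                 median_null = stats::median(null_auc[, b, p, ], na.rm = TRUE),
                 p_value = pv)
    }))
  }))
  p_wve <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    w <- auc[, b, "whisker"]; e <- auc[, b, "eye"]
    ok <- is.finite(w) & is.finite(e)
    data.frame(bin = b, p_value = if (sum(ok) >= 1)
      mann_whitney_u(w[ok], e[ok])$p_value else NA_real_)
  }))
  pairs <- t(utils::combn(n_bins, 2))
  p_pairs <- do.call(rbind, lapply(preds, function(p) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(j) {
      b1 <- pairs[j, 1]; b2 <- pairs[j, 2]
      x <- auc[, b1, p]; y <- auc[, b2, p]
      ok <- is.finite(x) & is.finite(y)
      pv <- if (sum(ok) >= 1) mann_whitney_u(x[ok], y[ok])$p_value else NA_real_
      data.frame(predictor = p, bin1 = b1, bin2 = b2, p_value = pv)
    }))
  }))
  p_pairs$p_adjusted <- NA_real_
  for (p in preds) {
    sel <- p_pairs$predictor == p
    p_pairs$p_adjusted[sel] <- bonferroni(p_pairs$p_value[sel], sum(sel))
  }
  structure(list(auc = auc, null_auc = null_auc, p_empirical = p_empirical,
                 p_vs_null = p_vs_null, p_whisker_vs_eye = p_wve,
                 p_pairwise_bins = p_pairs),
            class = "roc_result")
}

#' Deterministic linear separator and separation fidelity
#'
#' Fits a line separating left- from right-turning points in the 2D space
#' of whisker asymmetry and eye position. The fit is fully deterministic:
#' columns are standardized, the direction is the (ridge-regularized)
#' Fisher discriminant, and the intercept is chosen by an exhaustive sweep
#' that maximizes classification accuracy along that direction (both
#' orientations, cutpoints at +/-Inf and midpoints of adjacent distinct
#' projections). Separation fidelity is the fraction of points on their own
#' side of the line: 1.0 for a perfectly separating line, exactly 0.5 when
#' every point carries both labels, and never below the majority-class
#' frequency (the +/-Inf cutpoints realize the majority rule).
#'
#' @param points n x 2 numeric matrix (whisker, eye), n >= 2 per class.
#' @param labels Labels with exactly two classes; `positive` = left class.
#' @param positive Positive (left) class label.
#' @param seed Unused (kept for interface stability); the fit has no
#'   stochastic component.
#' @return List of class `linear_separator`: `weights`, `intercept` (in
#'   original units; predict left when `w . x + b > 0`), `fidelity`,
#'   `predictions`.
#' @export
fit_separator <- function(points, labels, positive = "left", seed = NULL) {
  X <- as.matrix(points)
  if (ncol(X) != 2L) config_error("fit_separator: points must be n x 2", "points")
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2L)
    config_error("fit_separator: need exactly two classes", "labels")
  if (!positive %in% cls)
    config_error("fit_separator: positive class absent", "labels")
  y <- labels == positive
  if (sum(y) < 1L || sum(!y) < 1L)
    config_error("fit_separator: need examples of both classes", "labels")
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; y <- y[keep]

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv <= 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  # Fisher direction with ridge for degenerate pooled covariance
  m1 <- colMeans(Z[y, , drop = FALSE]); m0 <- colMeans(Z[!y, , drop = FALSE])
  S <- (crossprod(sweep(Z[y, , drop = FALSE], 2, m1)) +
        crossprod(sweep(Z[!y, , drop = FALSE], 2, m0))) / max(1, nrow(Z) - 2)
  S <- S + diag(1e-6, 2)
  w <- tryCatch(solve(S, m1 - m0), error = function(e) m1 - m0)
  if (all(abs(w) < 1e-12)) w <- c(1, 0)

  z <- as.vector(Z %*% w)
  sweep_cut <- function(proj, flip) {
    zz <- if (flip) -proj else proj
    ord <- order(zz)
    zs <- zz[ord]; ys <- y[ord]
    # threshold t: predict left when zz > t; candidates between distinct values
    n <- length(zs)
    n1 <- sum(ys)
    left_above <- n1 - cumsum(ys)        # after passing element i
    right_below <- cumsum(!ys)
    acc_mid <- (left_above + right_below) / n
    distinct <- c(zs[-n] < zs[-1], TRUE)
    acc_all_left <- n1 / n               # t = -Inf
    accs <- c(acc_all_left, acc_mid[distinct])
    cuts <- c(-Inf, ifelse(is.finite(zs[distinct]) & distinct,
                           zs[distinct], zs[distinct]))
    best <- which.max(accs)
    thr <- if (best == 1L) -Inf else {
      i <- which(distinct)[best - 1L]
      if (i == n) Inf else (zs[i] + zs[i + 1L]) / 2
    }
    list(acc = accs[best], thr = thr)
  }
  a1 <- sweep_cut(z, FALSE)
  a2 <- sweep_cut(z, TRUE)
  if (a2$acc > a1$acc) { w <- -w; z <- -z; bestcut <- a2 } else bestcut <- a1
  fidelity <- bestcut$acc
  pred <- ifelse(z > bestcut$thr, positive, setdiff(cls, positive))

  # express line in original units: w_s . ((x - mu)/sd) - thr > 0
  w_orig <- w / sdv
  b_orig <- -sum(w * mu / sdv) - bestcut$thr
  structure(list(weights = w_orig, intercept = b_orig, fidelity = fidelity,
                 predictions = pred), class = "linear_separator")
}

#' Separation-fidelity contribution analysis
#'
#' For each time bin compares four separator models: the full model on true
#' data; the null model where both predictors are shuffled across points
#' relative to the labels; and two partial models where a single predictor
#' is shuffled, whose fidelity decrease versus the full model is that
#' variable's unique contribution. Shuffled-model fidelities are summarized
#' per session as the median over `n_shuffles` replicates; group comparison
#' across sessions uses the Kruskal-Wallis test followed by Dunn's test
#' against the full model, Bonferroni-corrected over all four models of all
#' time bins (m = 3 comparisons x bins).
#'
#' @param tables List of per-session `predictor_table`s (per = "timepoint").
#' @param n_shuffles Shuffle replicates per model and session.
#' @param seed Seed for the shuffle stream.
#' @param n_bins Number of time bins.
#' @param max_points Per-session, per-bin cap on time points (deterministic
#'   thinning) to bound runtime.
#' @return List of class `fidelity_result`: `fidelity` (data.frame: session,
#'   bin, model, value), `replicates` (session, bin, model, rep, value),
#'   `contribution` (bin, variable, drop), `tests` (per-bin Kruskal-Wallis
#'   p and Dunn-vs-full adjusted p per model).
#' @export
contribution_analysis <- function(tables, n_shuffles = 50L, seed = 1L,
                                  n_bins = 5L, max_points = 400L) {
  if (inherits(tables, "predictor_table")) tables <- list(tables)
  S <- length(tables)
  models <- c("full", "null", "shuffle_whisker", "shuffle_eye")
  fid_rows <- list(); rep_rows <- list()
  with_seed(seed, {
    for (s in seq_len(S)) {
      tab <- tables[[s]]
      for (b in seq_len(n_bins)) {
        tb <- tab[tab$bin == b & stats::complete.cases(tab[, c("whisker", "eye")]), ]
        if (length(unique(tb$label)) < 2) next
        if (nrow(tb) > max_points) {
          idx <- unique(round(seq(1, nrow(tb), length.out = max_points)))
          tb <- tb[idx, ]
        }
        X <- as.matrix(tb[, c("whisker", "eye")])
        full <- fit_separator(X, tb$label)$fidelity
        reps <- matrix(NA_real_, n_shuffles, 3,
                       dimnames = list(NULL, models[-1]))
        n <- nrow(X)
        for (k in seq_len(n_shuffles)) {
          Xn <- cbind(X[sample(n), 1], X[sample(n), 2])
          reps[k, "null"] <- fit_separator(Xn, tb$label)$fidelity
          Xw <- X; Xw[, 1] <- X[sample(n), 1]
          reps[k, "shuffle_whisker"] <- fit_separator(Xw, tb$label)$fidelity
          Xe <- X; Xe[, 2] <- X[sample(n), 2]
          reps[k, "shuffle_eye"] <- fit_separator(Xe, tb$label)$fidelity
        }
        fid_rows[[length(fid_rows) + 1L]] <- data.frame(
          session = s, bin = b,
          model = models,
          value = c(full, apply(reps, 2, stats::median)))
        for (m in models[-1]) {
          rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            session = s, bin = b, model = m, rep = seq_len(n_shuffles),
            value = reps[, m])
        }
      }
    }
  })
  fid <- do.call(rbind, fid_rows)
  repl <- do.call(rbind, rep_rows)
  m_family <- 3L * n_bins
  tests <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    gr <- lapply(models, function(m) fid$value[fid$bin == b & fid$model == m])
    names(gr) <- models
    gr <- gr[lengths(gr) > 0]
    if (length(gr) < 2) return(NULL)
    kw <- kruskal_wallis(gr)
    dn <- dunn_posthoc(gr, reference = "full", m = m_family)
    data.frame(bin = b, kw_p = kw$p_value, model = dn$group2,
               dunn_p = dn$p_value, dunn_p_adjusted = dn$p_adjusted)
  }))
  contr <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    fb <- fid[fid$bin == b, ]
    if (nrow(fb) == 0) return(NULL)
    full_med <- stats::median(fb$value[fb$model == "full"])
    do.call(rbind, lapply(c("shuffle_whisker", "shuffle_eye"), function(m) {
      data.frame(bin = b, variable = sub("shuffle_", "", m),
                 drop = full_med - stats::median(fb$value[fb$model == m]))
    }))
  }))
  structure(list(fidelity = fid, replicates = repl, contribution = contr,
                 tests = tests),
            class = "fidelity_result")
}
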