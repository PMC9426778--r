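# Nonparametric tests used throughout the pipeline.
#
# These are implemented in-package (rather than wrapping stats::wilcox.test
# etc.) because downstream analyses rely on the exact U/AUC identity and on
# tie-corrected pooled-rank formulas with an explicit, logged Bonferroni m.
# Exact small-sample enumeration provides the oracle path for testing.

new_test_result <- function(statistic, p_value, method, alternative, n,
                            correction = "none", extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(c(list(
    statistic = statistic, p_value = min(1, p_value), method = method,
    alternative = alternative, n = n, correction = correction
  ), extra), class = "whiskeye_test")
}

#' @export
print.whiskeye_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, n = %s)\n",
              x$method, x$statistic, x$p_value, x$alternative,
              paste(x$n, collapse = "/")))
  invisible(x)
}

# U statistic for x vs y with midrank tie handling
u_statistic <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples.
#' Uses exact enumeration of all group assignments when the pooled sample is
#' small (default `n1 + n2 <= 12`, ties handled naturally by enumeration),
#' otherwise a tie-corrected normal approximation with continuity correction.
#'
#' The statistic satisfies `U / (n1 * n2) == AUC(x over y)` with midrank tie
#' handling, the identity exploited by the ROC analysis.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param alternative One of `"two.sided"`, `"greater"` (x tends larger),
#'   `"less"`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` decides by sample size.
#' @return A `whiskeye_test` with fields `statistic` (U for `x`), `p_value`,
#'   `method`, `alternative`, `n`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact two-sided p = 1/3
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "greater", "less"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    config_error("both groups must be non-empty", "x/y")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  u <- u_statistic(x, y)
  mu <- n1 * n2 / 2
  do_exact <- exact %||% (N <= 12L)

  if (do_exact) {
    pooled <- c(x, y)
    idx <- utils::combn(N, n1)
    us <- apply(idx, 2, function(i) u_statistic(pooled[i], pooled[-i]))
    eps <- 1e-9
    p <- switch(alternative,
      two.sided = mean(abs(us - mu) >= abs(u - mu) - eps),
      greater   = mean(us >= u - eps),
      less      = mean(us <= u + eps)
    )
    method <- "Mann-Whitney U (exact)"
  } else {
    tie <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sigma2 <= 0) {  # fully tied data
      p <- 1
    } else {
      z <- (u - mu)
      cc <- 0.5
      p <- switch(alternative,
        two.sided = 2 * stats::pnorm((abs(z) - cc) / sqrt(sigma2), lower.tail = FALSE),
        greater   = stats::pnorm((z - cc) / sqrt(sigma2), lower.tail = FALSE),
        less      = stats::pnorm((z + cc) / sqrt(sigma2))
      )
      p <- min(1, p)
    }
    method <- "Mann-Whitney U (normal approximation)"
  }
  new_test_result(u, p, method, alternative, c(n1, n2))
}

#' Kruskal-Wallis rank test
#'
#' @param groups A list of >= 2 non-empty numeric vectors.
#' @return A `whiskeye_test` with the tie-corrected H statistic and the
#'   chi-square p-value on `k - 1` degrees of freedom. Fully tied data
#'   (every pooled value identical) yield `H = 0`, `p = 1`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    config_error("need a list of >= 2 groups", "groups")
  if (any(lengths(groups) < 1L))
    config_error("all groups must be non-empty", "groups")
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  ni <- lengths(groups)
  gi <- rep(seq_along(groups), ni)
  rbar <- tapply(r, gi, mean)
  H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  tie <- table(pooled)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C <= 0) {
    H <- 0; p <- 1
  } else {
    H <- H / C
    p <- stats::pchisq(H, df = length(groups) - 1L, lower.tail = FALSE)
  }
  new_test_result(H, p, "Kruskal-Wallis", "two.sided", ni)
}

#' Dunn's post hoc test on pooled ranks
#'
#' Pairwise z statistics on pooled midranks with tie correction, following a
#' Kruskal-Wallis test. Either all pairs or every group versus one reference
#' group; the Bonferroni m equals the number of comparisons actually executed
#' (overridable via `m` when a wider family is corrected for).
#'
#' @param groups List of numeric vectors (named names are kept).
#' @param correction `"bonferroni"` or `"none"`.
#' @param reference `NULL` for all pairs, otherwise the index or name of the
#'   reference group (k - 1 comparisons).
#' @param m Number of comparisons in the corrected family; defaults to the
#'   number executed here.
#' @return data.frame with one row per comparison: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`, `m`.
#' @export
dunn_posthoc <- function(groups, correction = c("bonferroni", "none"),
                         reference = NULL, m = NULL) {
  correction <- match.arg(correction)
  k <- length(groups)
  if (k < 2L) config_error("need >= 2 groups", "groups")
  nms <- names(groups) %||% as.character(seq_len(k))
  if (is.null(names(groups))) names(groups) <- nms
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  ni <- lengths(groups)
  gi <- rep(seq_len(k), ni)
  rbar <- tapply(r, gi, mean)
  tie <- table(pooled)
  var_base <- N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))

  if (!is.null(reference)) {
    if (is.character(reference)) reference <- match(reference, nms)
    stopifnot(!is.na(reference), reference >= 1, reference <= k)
    pairs <- cbind(reference, setdiff(seq_len(k), reference))
  } else {
    pairs <- t(utils::combn(k, 2))
  }
  n_comp <- nrow(pairs)
  m <- m %||% n_comp

  res <- do.call(rbind, lapply(seq_len(n_comp), function(j) {
    i1 <- pairs[j, 1]; i2 <- pairs[j, 2]
    se <- sqrt(var_base * (1 / ni[i1] + 1 / ni[i2]))
    z <- if (se > 0) (rbar[i1] - rbar[i2]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = nms[i1], group2 = nms[i2], z = z, p_value = p,
               stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- if (correction == "bonferroni") bonferroni(res$p_value, m) else res$p_value
  res$m <- m
  rownames(res) <- NULL
  res
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector of p-values.
#' @param m Number of comparisons in the family (default `length(p_values)`).
#' @return `pmin(1, m * p_values)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  check_scalar(m, "m", positive = TRUE, integer = TRUE)
  pmin(1, m * p_values)
}
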