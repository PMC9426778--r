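#' @keywords internal
"_PACKAGE"

# condition helpers ----------------------------------------------------------

we_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "whiskeye_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

config_error   <- function(msg, field = NULL) we_error("whiskeye_config_error", msg, field = field)
format_error   <- function(msg, ...) we_error("whiskeye_format_error", msg, ...)
fit_error      <- function(msg, ...) we_error("whiskeye_fit_error", msg, ...)
geometry_error <- function(msg, ...) we_error("whiskeye_geometry_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar checks, error names the offending field
check_scalar <- function(x, field, positive = FALSE, nonneg = FALSE,
                         integer = FALSE, lo = NULL, hi = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error(sprintf("field '%s' must be a finite numeric scalar", field), field)
  if (positive && x <= 0)
    config_error(sprintf("field '%s' must be strictly positive", field), field)
  if (nonneg && x < 0)
    config_error(sprintf("field '%s' must be non-negative", field), field)
  if (integer && x != round(x))
    config_error(sprintf("field '%s' must be an integer", field), field)
  if (!is.null(lo) && x < lo)
    config_error(sprintf("field '%s' must be >= %g", field, lo), field)
  if (!is.null(hi) && x > hi)
    config_error(sprintf("field '%s' must be <= %g", field, hi), field)
  invisible(x)
}

# run code with a private, restored RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed below 2^31 from a parent seed and a stream index
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

# 2-frame average downsampling (exact factor two, anti-aliased)
downsample2 <- function(x) {
  n <- length(x)
  if (n %% 2L == 1L) x <- x[-n]
  colMeans(matrix(x, nrow = 2L))
}
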