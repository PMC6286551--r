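# Internal helpers shared across modules.

#' Nearest-rank percentile
#'
#' Empirical percentile using the nearest-rank definition: the p-th
#' percentile of `x` is the value at position `ceiling(p/100 * n)` of the
#' sorted sample. This definition always returns an observed value, which
#' matters when percentiles are used as cut-offs on heavily tied scales.
#'
#' @param x numeric vector.
#' @param p percentile(s) in (0, 100].
#' @return numeric vector of the same length as `p`.
#' @export
pct_nearest_rank <- function(x, p) {
  if (length(x) == 0L) stop("empty sample")
  if (any(p <= 0 | p > 100)) stop("percentiles must lie in (0, 100]")
  xs <- sort(x)
  xs[pmax(1L, ceiling(p / 100 * length(xs)))]
}

# stop() with sprintf-style formatting, call suppressed
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# single finite number check
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
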