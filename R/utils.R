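#' @keywords internal
"_PACKAGE"

# clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# sample skewness (g1)
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

stop_if <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)

# percentile rank in (0, 1): (r - 0.5)/n with average ranks, NA preserved
percentile_rank <- function(x) {
  r <- rank(x, na.last = "keep", ties.method = "average")
  (r - 0.5) / sum(!is.na(x))
}
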