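## The ten first-order statistics used to aggregate every per-nucleus
## descriptor to the patch level.
first_order_names <- c("mean", "median", "sd", "variance", "min", "max",
                       "range", "min_max_ratio", "skewness", "kurtosis")

#' First-order statistics of a per-nucleus value vector
#'
#' Aggregates one per-nucleus descriptor over a patch. Variance is the
#' population (divide-by-n) convention and `sd = sqrt(variance)`; skewness
#' and kurtosis are standardized moments, kurtosis as excess (normal = 0).
#' A constant vector yields sd/variance 0 and skewness/kurtosis reported
#' as 0 (flagged via the `degenerate` attribute).
#'
#' @param values Numeric vector (NAs dropped).
#' @return Named numeric vector of the 10 statistics.
#' @export
aggregate_first_order <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n == 0L) {
    out <- rep(NA_real_, length(first_order_names))
    names(out) <- first_order_names
    return(out)
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  degenerate <- m2 < 1e-24
  skew <- if (degenerate) 0 else mean((x - m)^3) / m2^1.5
  kurt <- if (degenerate) 0 else mean((x - m)^4) / m2^2 - 3
  mx <- max(x); mn <- min(x)
  out <- c(mean = m, median = median(x), sd = sqrt(m2), variance = m2,
           min = mn, max = mx, range = mx - mn,
           min_max_ratio = if (mx == 0) 0 else mn / mx,
           skewness = skew, kurtosis = kurt)
  attr(out, "degenerate") <- degenerate
  out
}

## Aggregate each column of a descriptor matrix, emitting
## "<prefix>.<descriptor>.<stat>" names.
aggregate_block <- function(desc_mat, prefix) {
  out <- numeric(0)
  for (j in seq_len(ncol(desc_mat))) {
    s <- aggregate_first_order(desc_mat[, j])
    names(s) <- paste(prefix, colnames(desc_mat)[j], first_order_names,
                      sep = ".")
    out <- c(out, s)
  }
  out
}
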