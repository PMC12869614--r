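#' Blended two-kernel median noise filter
#'
#' `filter_spec()` describes the filter; `blended_median_filter()` applies it
#' to a signal or concentration series. Two moving medians are computed over
#' the whole series — a short window that preserves the sharp concentration
#' peak, and a long window that attenuates noise in the slowly varying late
#' phase — and blended pointwise: the short-window median is used up to time
#' `t_a`, the long-window median from `t_b` on, and a linear weight ramps
#' between the two in between. Defaults are windows of 3 and 7 samples and
#' transitions at 5 and 30 minutes on the post-bolus clock.
#'
#' Moving medians use centered windows that shrink (truncate) at the series
#' ends; invalid samples are excluded from every window. The filter is the
#' identity on constant series, never overshoots the local data range, and is
#' deterministic.
#'
#' @param k_small,k_large odd window lengths in samples, `k_small < k_large`.
#' @param t_a,t_b blend transition times (s since bolus), `0 < t_a < t_b`.
#' @return `filter_spec()`: an object of class `filter_spec`.
#' @examples
#' fs <- filter_spec()
#' s <- signal_series(seq(0, 76.5, by = 7.65), c(rep(10, 5), 30, rep(10, 5)), s0 = 10)
#' blended_median_filter(s, fs)
#' @export
filter_spec <- function(k_small = 3, k_large = 7, t_a = 300, t_b = 1800) {
  stopifnot(k_small >= 1, k_large >= 1, k_small %% 2 == 1, k_large %% 2 == 1,
            k_small < k_large, t_a > 0, t_a < t_b)
  structure(list(k_small = as.integer(k_small), k_large = as.integer(k_large),
                 t_a = t_a, t_b = t_b),
            class = "filter_spec")
}

# moving median with shrinking centered windows; invalid samples excluded.
# Samples that are themselves invalid get NA out.
moving_median <- function(values, valid, k) {
  n <- length(values)
  h <- (k - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!valid[i]) next
    j <- max(1L, i - h):min(n, i + h)
    j <- j[valid[j]]
    out[i] <- stats::median(values[j])
  }
  out
}

#' @rdname filter_spec
#' @param series a [signal_series()] or [conc_series()], uniformly sampled.
#' @param spec a `filter_spec`.
#' @return `blended_median_filter()`: a series of the same class with
#'   filtered values; validity flags are preserved.
#' @export
blended_median_filter <- function(series, spec = filter_spec()) {
  stopifnot(inherits(series, "pk_series"), inherits(spec, "filter_spec"))
  frame_interval(series)   # errors on non-uniform sampling
  m_small <- moving_median(series$values, series$valid, spec$k_small)
  m_large <- moving_median(series$values, series$valid, spec$k_large)
  w <- (series$times - spec$t_a) / (spec$t_b - spec$t_a)
  w <- pmin(1, pmax(0, w))
  series_with_values(series, (1 - w) * m_small + w * m_large)
}
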