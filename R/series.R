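#' Time-series containers for DCE-MRI curves
#'
#' `signal_series()` holds an ROI-mean MR signal time course together with its
#' pre-contrast baseline; `conc_series()` holds a gadolinium concentration
#' time course (mM) labelled by compartment. Times are in seconds relative to
#' the contrast bolus (t = 0 at injection), so pre-contrast baseline frames
#' carry negative times. Both carry a per-sample validity mask: samples that
#' cannot be inverted to concentration (possible under noise near the bolus
#' peak) are flagged invalid rather than clamped, and downstream filtering and
#' fitting exclude them.
#'
#' @param times numeric vector of sample times (s), strictly increasing and
#'   uniformly spaced to within 1\% of the frame interval.
#' @param values numeric vector, same length as `times`. Arbitrary units for
#'   signal; mM for concentration.
#' @param s0 mean pre-contrast baseline signal (> 0).
#' @param compartment one of `"Ct"`, `"Ce"`, `"Ci"`, `"Ca"`, `"Cv"`, `"Cp"`.
#' @param valid logical vector of per-sample validity flags.
#' @return An object of class `signal_series` or `conc_series` (both inherit
#'   from `pk_series`): a list with elements `times`, `values`, `valid`, plus
#'   `s0` (signal) or `compartment` (concentration).
#' @examples
#' s <- signal_series(seq(-30, 120, by = 7.65), rep(100, 21), s0 = 100)
#' print(s)
#' @export
signal_series <- function(times, values, s0, valid = rep(TRUE, length(times))) {
  check_series_args(times, values, valid)
  if (!is.numeric(s0) || length(s0) != 1L || !is.finite(s0) || s0 <= 0)
    stop("'s0' must be a single positive number (mean pre-contrast signal)")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 s0 = as.numeric(s0), valid = as.logical(valid)),
            class = c("signal_series", "pk_series"))
}

#' @rdname signal_series
#' @export
conc_series <- function(times, values, compartment,
                        valid = rep(TRUE, length(times))) {
  check_series_args(times, values, valid)
  compartment <- match.arg(compartment, c("Ct", "Ce", "Ci", "Ca", "Cv", "Cp"))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 compartment = compartment, valid = as.logical(valid)),
            class = c("conc_series", "pk_series"))
}

check_series_args <- function(times, values, valid) {
  if (length(times) < 1L) stop("series must contain at least one sample")
  if (length(values) != length(times) || length(valid) != length(times))
    stop("'times', 'values' and 'valid' must have equal lengths")
  if (anyNA(times) || any(!is.finite(times)))
    stop("'times' must be finite")
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("'times' must be strictly increasing")
  }
  invisible(TRUE)
}

#' Frame interval of a uniformly sampled series
#'
#' Returns the common spacing of the time grid, erroring if the spacing
#' deviates from uniform by more than `tol` (a fraction of the median
#' interval). Uniform sampling is assumed by the convolution kernels and the
#' moving-median filter.
#'
#' @param x a `pk_series` or numeric vector of times.
#' @param tol relative tolerance on spacing jitter (default 0.01).
#' @return The frame interval in seconds.
#' @export
frame_interval <- function(x, tol = 0.01) {
  times <- if (inherits(x, "pk_series")) x$times else as.numeric(x)
  if (length(times) < 2L) stop("need at least two samples to infer spacing")
  dt <- diff(times)
  dt0 <- stats::median(dt)
  if (any(abs(dt - dt0) > tol * dt0))
    stop(sprintf("non-uniform sampling: spacing varies by more than %g%% of %g s",
                 100 * tol, dt0))
  dt0
}

#' @export
length.pk_series <- function(x) length(x$times)

#' @export
print.signal_series <- function(x, ...) {
  cat(sprintf("<signal_series> %d samples, t = [%.4g, %.4g] s, s0 = %.4g, %d invalid\n",
              length(x), x$times[1L], x$times[length(x)], x$s0, sum(!x$valid)))
  invisible(x)
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("<conc_series:%s> %d samples, t = [%.4g, %.4g] s, range [%.4g, %.4g] mM, %d invalid\n",
              x$compartment, length(x), x$times[1L], x$times[length(x)],
              min(x$values[x$valid]), max(x$values[x$valid]), sum(!x$valid)))
  invisible(x)
}

#' @export
as.data.frame.pk_series <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values, valid = x$valid)
}

#' @export
plot.pk_series <- function(x, ..., xlab = "time since bolus (s)",
                           ylab = if (inherits(x, "conc_series"))
                             sprintf("%s (mM)", x$compartment) else "signal (a.u.)") {
  graphics::plot(x$times[x$valid], x$values[x$valid], type = "l",
                 xlab = xlab, ylab = ylab, ...)
  if (any(!x$valid))
    graphics::points(x$times[!x$valid], x$values[!x$valid], pch = 4, col = 2)
  invisible(x)
}

# replace values keeping metadata
series_with_values <- function(x, values, valid = x$valid) {
  x$values <- as.numeric(values)
  x$valid <- valid
  x
}

stop_if_grid_mismatch <- function(a, b, what = "series") {
  if (length(a$times) != length(b$times) ||
      any(abs(a$times - b$times) > 1e-9 * max(1, abs(a$times))))
    stop(sprintf("%s are not on the same time grid", what))
  invisible(TRUE)
}
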