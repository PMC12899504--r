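#' Low-pass filter specification
#'
#' The detectors smooth both IMU-derived signals with a low-pass third-order
#' Butterworth filter at 20 Hz before searching for peak patterns; those are
#' the defaults here.  `zero_phase = TRUE` applies the filter forward and
#' backward (filtfilt), which doubles the effective order of the magnitude
#' response but introduces no group delay -- a causal 3rd-order/20 Hz filter
#' at a 60 Hz rate would lag events by several samples and bias every timing
#' offset, so zero-phase is the default.
#'
#' @param cutoff_hz cutoff frequency in Hz; must lie below the Nyquist
#'   frequency of the signal the filter is applied to.
#' @param order filter order (>= 1).
#' @param zero_phase logical; forward-backward filtering when `TRUE`.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 20, order = 3, zero_phase = TRUE) {
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L || cutoff_hz <= 0)
    stop("filter_spec: 'cutoff_hz' must be a single positive number", call. = FALSE)
  if (!is.numeric(order) || length(order) != 1L || order < 1)
    stop("filter_spec: 'order' must be >= 1", call. = FALSE)
  structure(list(cutoff_hz = as.numeric(cutoff_hz),
                 order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Low-pass Butterworth filtering
#'
#' Applies a Butterworth low-pass filter of the stated order and cutoff to a
#' uniform signal.  The signal mean is removed before filtering and restored
#' afterwards, which suppresses start-up transients (the filter states are
#' zero-initialized) without altering the response to fluctuations; the
#' operation remains exactly linear.
#'
#' Boundaries are handled by odd reflection: the signal is extended at both
#' ends with its point-reflection about the end sample before filtering and
#' the extension discarded afterwards, so ramps stay ramps and no spurious
#' extrema appear near the edges.
#'
#' @param x a [uniform_signal()].
#' @param spec a [filter_spec()].
#' @return a [uniform_signal()] with the same length, rate and `t0`.
#' @export
lowpass <- function(x, spec = filter_spec()) {
  stopifnot(inherits(x, "uniform_signal"), inherits(spec, "filter_spec"))
  nyq <- x$rate / 2
  if (spec$cutoff_hz >= nyq)
    stop(sprintf("lowpass: cutoff %g Hz is at or above Nyquist (%g Hz)",
                 spec$cutoff_hz, nyq), call. = FALSE)
  n <- length(x$values)
  if (n <= 3L * spec$order)
    stop(sprintf("lowpass: signal too short (%d samples) for order %d",
                 n, spec$order), call. = FALSE)
  bt <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = "low")
  mu <- mean(x$values)
  v <- x$values - mu
  pad <- min(n - 1L, max(12L, 9L * spec$order))
  v_ext <- c(2 * v[1] - v[(pad + 1L):2], v, 2 * v[n] - v[(n - 1L):(n - pad)])
  y <- if (spec$zero_phase) signal::filtfilt(bt, v_ext)
       else as.numeric(signal::filter(bt, v_ext))
  uniform_signal(y[(pad + 1L):(pad + n)] + mu, rate = x$rate, t0 = x$t0,
                 units = x$units)
}

#' Resultant (Euclidean norm) of a triaxial signal
#'
#' Per-sample magnitude `sqrt(x^2 + y^2 + z^2)` of the three acceleration
#' axes; this is the resultant foot acceleration (RFA) the foot-mounted
#' detector searches.
#'
#' @param acc a [triaxial_signal()].
#' @return a [uniform_signal()] of the per-sample norms.
#' @export
resultant <- function(acc) {
  stopifnot(inherits(acc, "triaxial_signal"))
  uniform_signal(sqrt(acc$x$values^2 + acc$y$values^2 + acc$z$values^2),
                 rate = acc$rate, t0 = acc$t0, units = "m/s^2")
}

#' Numerical time derivative
#'
#' Central finite difference scaled by the sampling rate, with forward and
#' backward differences at the two ends.  Output units are input units per
#' second.
#'
#' @param x a [uniform_signal()] with at least 3 samples.
#' @return a [uniform_signal()] of the same length, rate and `t0`.
#' @export
derivative <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  v <- x$values
  n <- length(v)
  if (n < 3L)
    stop("derivative: need at least 3 samples", call. = FALSE)
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) * x$rate
  d[n] <- (v[n] - v[n - 1]) * x$rate
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * x$rate / 2
  uniform_signal(d, rate = x$rate, t0 = x$t0,
                 units = if (nzchar(x$units)) paste0(x$units, "/s") else "")
}

#' Anti-aliased down-sampling
#'
#' Converts a signal to a lower rate, as used to bring the 1000 Hz force
#' platform channel onto the 60 Hz IMU clock.  The signal is first low-pass
#' filtered with a zero-phase 6th-order Butterworth at 90% of the target
#' Nyquist frequency (anti-aliasing without phase distortion), then evaluated
#' at the target sample times `t0 + k / target_rate` by interpolation between
#' the densely sampled filtered values.  `t0` is preserved and the output
#' covers the same time span.
#'
#' @param x a [uniform_signal()].
#' @param target_rate desired output rate in Hz; must not exceed `x$rate`.
#' @return a [uniform_signal()] at `target_rate`.
#' @export
downsample_to <- function(x, target_rate) {
  stopifnot(inherits(x, "uniform_signal"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    stop("downsample_to: 'target_rate' must be a single positive number",
         call. = FALSE)
  if (target_rate > x$rate + 1e-9)
    stop(sprintf("downsample_to: target rate %g Hz exceeds input rate %g Hz",
                 target_rate, x$rate), call. = FALSE)
  if (abs(target_rate - x$rate) < 1e-9) return(x)
  filt <- lowpass(x, filter_spec(cutoff_hz = 0.45 * target_rate, order = 6,
                                 zero_phase = TRUE))
  span <- signal_duration(x)
  k <- 0:floor(span * target_rate + 1e-9)
  tt <- x$t0 + k / target_rate
  y <- stats::approx(signal_times(x), filt$values, xout = tt)$y
  uniform_signal(y, rate = target_rate, t0 = x$t0, units = x$units)
}

#' Map a time to the nearest sample index
#'
#' Returns the 0-based index of the sample nearest to time `t` on the
#' signal's clock, rounding half-sample midpoints up (towards the later
#' sample).  Used to re-express force-plate event times on the IMU clock.
#'
#' @param t time in seconds; must lie within the signal's time span.
#' @param signal a [uniform_signal()].
#' @return integer 0-based sample index.
#' @export
map_time_to_index <- function(t, signal) {
  stopifnot(inherits(signal, "uniform_signal"))
  t_end <- signal$t0 + signal_duration(signal)
  if (t < signal$t0 - 1e-9 || t > t_end + 1e-9)
    stop(sprintf("map_time_to_index: t = %g s outside span [%g, %g] s",
                 t, signal$t0, t_end), call. = FALSE)
  as.integer(floor((t - signal$t0) * signal$rate + 0.5))
}
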