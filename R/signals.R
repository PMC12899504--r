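#' Uniformly sampled signal
#'
#' The basic container for one sensor channel: a numeric vector sampled at a
#' constant rate on a shared trial clock.  Sample `k` (0-based) is taken at
#' time `t0 + k / rate` seconds.
#'
#' @param values numeric vector of samples (channel units); must be finite.
#' @param rate sampling rate in Hz; must be positive.
#' @param t0 time of sample 0 on the trial clock, in seconds.
#' @param units optional unit label (informational only).
#' @return an object of class `uniform_signal` with fields `values`, `rate`,
#'   `t0` and `units`.
#' @examples
#' s <- uniform_signal(sin(2 * pi * 2 * (0:59) / 60), rate = 60)
#' signal_times(s)[1:5]
#' @export
uniform_signal <- function(values, rate, t0 = 0, units = "") {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("uniform_signal: 'values' must have length >= 1", call. = FALSE)
  if (!all(is.finite(values)))
    stop("uniform_signal: all values must be finite", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("uniform_signal: 'rate' must be a single positive number", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("uniform_signal: 't0' must be a single finite number", call. = FALSE)
  structure(
    list(values = values, rate = as.numeric(rate), t0 = as.numeric(t0),
         units = as.character(units)),
    class = "uniform_signal"
  )
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %d samples @ %g Hz, t0 = %g s%s\n",
              length(x$values), x$rate, x$t0,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' @export
length.uniform_signal <- function(x) length(x$values)

#' Sample times of a uniform signal
#'
#' @param signal a [uniform_signal()].
#' @return numeric vector of times (s), one per sample.
#' @export
signal_times <- function(signal) {
  stopifnot(inherits(signal, "uniform_signal"))
  signal$t0 + (seq_along(signal$values) - 1) / signal$rate
}

#' Duration spanned by a uniform signal
#'
#' @param signal a [uniform_signal()].
#' @return time between the first and last sample, in seconds.
#' @export
signal_duration <- function(signal) {
  stopifnot(inherits(signal, "uniform_signal"))
  (length(signal$values) - 1) / signal$rate
}

#' Three-axis signal
#'
#' Bundles the x/y/z channels of a triaxial sensor.  The three channels must
#' be sampled on the same clock (identical rate, `t0` and length).
#'
#' @param x,y,z [uniform_signal()] objects, one per axis.
#' @return an object of class `triaxial_signal`.
#' @export
triaxial_signal <- function(x, y, z) {
  chans <- list(x = x, y = y, z = z)
  for (nm in names(chans))
    if (!inherits(chans[[nm]], "uniform_signal"))
      stop(sprintf("triaxial_signal: '%s' must be a uniform_signal", nm),
           call. = FALSE)
  if (length(unique(vapply(chans, function(s) length(s$values), 1L))) != 1L)
    stop("triaxial_signal: channels differ in length", call. = FALSE)
  if (max(abs(c(x$rate - y$rate, x$rate - z$rate))) > 1e-9)
    stop("triaxial_signal: channels differ in rate", call. = FALSE)
  if (max(abs(c(x$t0 - y$t0, x$t0 - z$t0))) > 1e-9)
    stop("triaxial_signal: channels differ in t0", call. = FALSE)
  structure(list(x = x, y = y, z = z, rate = x$rate, t0 = x$t0),
            class = "triaxial_signal")
}

#' @export
print.triaxial_signal <- function(x, ...) {
  cat(sprintf("<triaxial_signal> %d samples @ %g Hz, t0 = %g s\n",
              length(x$x$values), x$rate, x$t0))
  invisible(x)
}

#' Trial metadata
#'
#' Identifies one movement repetition: the participant, the task (90-degree
#' change of direction, `"COD"`, or sprint with deceleration, `"DEC"`), the
#' participant's sex, and which leg contacted the platform.
#'
#' @param trial_id,participant_id character identifiers.
#' @param task `"COD"` or `"DEC"`.
#' @param sex `"male"` or `"female"`.
#' @param leg `"dominant"` or `"nondominant"`.
#' @return an object of class `trial_meta`.
#' @export
trial_meta <- function(trial_id, participant_id, task, sex, leg) {
  task <- match.arg(task, c("COD", "DEC"))
  sex <- match.arg(sex, c("male", "female"))
  leg <- match.arg(leg, c("dominant", "nondominant"))
  structure(
    list(trial_id = as.character(trial_id),
         participant_id = as.character(participant_id),
         task = task, sex = sex, leg = leg),
    class = "trial_meta"
  )
}

#' @export
print.trial_meta <- function(x, ...) {
  cat(sprintf("<trial_meta> %s (participant %s, %s, %s, %s leg)\n",
              x$trial_id, x$participant_id, x$task, x$sex, x$leg))
  invisible(x)
}

#' One synchronized movement trial
#'
#' The bundle of synchronized signals for one repetition: the force-platform
#' vertical ground reaction force (vGRF, nominally 1000 Hz; optional), the
#' pelvis vertical velocity (nominally 60 Hz) and the triaxial foot linear
#' acceleration (same clock as the pelvis channel).  All channels share the
#' trial clock: equal `t0` means the hardware-triggered recordings are
#' aligned in time.
#'
#' @param meta a [trial_meta()].
#' @param pelvis_vz pelvis vertical velocity, a [uniform_signal()] in m/s.
#' @param foot_acc foot linear acceleration, a [triaxial_signal()] in m/s^2.
#' @param vgrf vertical ground reaction force in newtons, a
#'   [uniform_signal()], or `NULL` when no force-plate channel exists.
#' @return an object of class `fc_trial`.
#' @export
fc_trial <- function(meta, pelvis_vz, foot_acc, vgrf = NULL) {
  stopifnot(inherits(meta, "trial_meta"),
            inherits(pelvis_vz, "uniform_signal"),
            inherits(foot_acc, "triaxial_signal"))
  if (abs(pelvis_vz$rate - foot_acc$rate) > 1e-9)
    stop("fc_trial: pelvis_vz and foot_acc must share the IMU rate",
         call. = FALSE)
  if (abs(pelvis_vz$t0 - foot_acc$t0) > 1e-9)
    stop("fc_trial: pelvis_vz and foot_acc must share t0", call. = FALSE)
  if (!is.null(vgrf)) {
    stopifnot(inherits(vgrf, "uniform_signal"))
    if (abs(vgrf$t0 - pelvis_vz$t0) > 1e-9)
      stop("fc_trial: vgrf must share t0 with the IMU channels (synchronized clock)",
           call. = FALSE)
  }
  structure(list(meta = meta, vgrf = vgrf, pelvis_vz = pelvis_vz,
                 foot_acc = foot_acc),
            class = "fc_trial")
}

#' @export
print.fc_trial <- function(x, ...) {
  cat(sprintf("<fc_trial> %s: IMU %d samples @ %g Hz%s\n",
              x$meta$trial_id, length(x$pelvis_vz$values), x$pelvis_vz$rate,
              if (is.null(x$vgrf)) ", no vGRF"
              else sprintf(", vGRF %d samples @ %g Hz",
                           length(x$vgrf$values), x$vgrf$rate)))
  invisible(x)
}

#' Foot-contact event
#'
#' An (initial contact, toe-off) pair.  Indices are 0-based samples on the
#' clock of the signal the event was detected on; times are seconds on the
#' shared trial clock.  `duration` is `to_time - ic_time`.
#'
#' Events produced directly on a signal satisfy
#' `time == t0 + index / rate` to within 1e-9 s.  Events re-expressed on a
#' different clock (see [grf_event_on_imu_clock()]) keep their original exact
#' times, so the index/time agreement is only guaranteed to half a sample on
#' the new clock; the validator allows that much.
#'
#' @param ic_index,to_index 0-based sample indices; `to_index > ic_index`.
#' @param rate sampling rate (Hz) of the owning clock.
#' @param t0 time of sample 0 (s).
#' @param ic_time,to_time optional explicit event times (s); default to the
#'   index-derived times.
#' @return an object of class `contact_event` with fields `ic_index`,
#'   `to_index`, `ic_time`, `to_time`, `duration`, `rate`, `t0`.
#' @export
contact_event <- function(ic_index, to_index, rate, t0 = 0,
                          ic_time = NULL, to_time = NULL) {
  stopifnot(is.numeric(ic_index), is.numeric(to_index),
            is.numeric(rate), rate > 0)
  ic_index <- as.integer(round(ic_index))
  to_index <- as.integer(round(to_index))
  if (ic_index < 0L || to_index < 0L)
    stop("contact_event: indices are 0-based and must be >= 0", call. = FALSE)
  if (is.null(ic_time)) ic_time <- t0 + ic_index / rate
  if (is.null(to_time)) to_time <- t0 + to_index / rate
  if (to_time <= ic_time)
    stop("contact_event: to_time must be strictly after ic_time", call. = FALSE)
  half <- 0.5 / rate + 1e-9
  if (abs(ic_time - (t0 + ic_index / rate)) > half ||
      abs(to_time - (t0 + to_index / rate)) > half)
    stop("contact_event: times inconsistent with indices on the stated clock",
         call. = FALSE)
  structure(
    list(ic_index = ic_index, to_index = to_index,
         ic_time = as.numeric(ic_time), to_time = as.numeric(to_time),
         duration = as.numeric(to_time - ic_time),
         rate = as.numeric(rate), t0 = as.numeric(t0)),
    class = "contact_event"
  )
}

#' @export
print.contact_event <- function(x, ...) {
  cat(sprintf("<contact_event> IC %.4f s (sample %d) -> TO %.4f s (sample %d), %.1f ms\n",
              x$ic_time, x$ic_index, x$to_time, x$to_index, 1000 * x$duration))
  invisible(x)
}
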