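#' Force-plate reference parameters
#'
#' The reference foot-contact window is read off the vertical ground
#' reaction force: initial contact is the first frame in which the vGRF
#' exceeds 50 N, toe-off the first subsequent frame in which it drops below
#' the same threshold.  `min_contact_s` is a debounce: supra-threshold
#' windows shorter than this are treated as plate ringing near the threshold
#' and skipped.  Set it to 0 for the literal first-crossing rule.
#'
#' @param threshold_n force threshold in newtons (> 0).
#' @param min_contact_s minimum accepted contact duration in seconds (>= 0).
#' @return an object of class `grf_params`.
#' @export
grf_params <- function(threshold_n = 50, min_contact_s = 0.05) {
  if (!is.numeric(threshold_n) || length(threshold_n) != 1L || threshold_n <= 0)
    stop("grf_params: 'threshold_n' must be a single positive number", call. = FALSE)
  if (!is.numeric(min_contact_s) || length(min_contact_s) != 1L || min_contact_s < 0)
    stop("grf_params: 'min_contact_s' must be >= 0", call. = FALSE)
  structure(list(threshold_n = as.numeric(threshold_n),
                 min_contact_s = as.numeric(min_contact_s)),
            class = "grf_params")
}

#' Reference contact window from the force platform
#'
#' Scans the vGRF for supra-threshold windows.  Within a window, initial
#' contact is the first sample strictly above `threshold_n` and toe-off the
#' first subsequent sample strictly below it ("exceeded" / "dropped below"
#' read literally: samples exactly at the threshold trigger neither).
#' Windows shorter than the debounce are skipped and the scan continues.
#' When several windows survive, the longest is returned (ties broken by the
#' earlier initial contact), mirroring the detectors' longest-contact rule.
#'
#' A window still open at the last sample is ignored when at least one
#' complete window exists; if the only supra-threshold activity runs into
#' the end of the recording a truncated-contact error is raised.
#'
#' @param vgrf the vertical ground reaction force, a [uniform_signal()] in N.
#' @param params a [grf_params()].
#' @return a [contact_event()] on the vGRF clock.
#' @export
detect_grf_contact <- function(vgrf, params = grf_params()) {
  stopifnot(inherits(vgrf, "uniform_signal"), inherits(params, "grf_params"))
  v <- vgrf$values
  n <- length(v)
  thr <- params$threshold_n
  wins <- list()
  truncated <- FALSE
  i <- 1L
  while (i <= n) {
    if (v[i] > thr) {
      j <- i + 1L
      while (j <= n && !(v[j] < thr)) j <- j + 1L
      if (j > n) {
        truncated <- TRUE
        break
      }
      dur <- (j - i) / vgrf$rate
      if (dur >= params$min_contact_s)
        wins[[length(wins) + 1L]] <- c(ic = i, to = j)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (length(wins) == 0L) {
    if (truncated)
      stop("detect_grf_contact: contact unended at signal end (truncated contact)",
           call. = FALSE)
    stop(sprintf("detect_grf_contact: no sample exceeds %g N (no contact)", thr),
         call. = FALSE)
  }
  durs <- vapply(wins, function(w) (w["to"] - w["ic"]) / vgrf$rate, 1.0)
  ics <- vapply(wins, function(w) w[["ic"]], 1.0)
  best <- order(-durs, ics)[1L]
  contact_event(ic_index = wins[[best]][["ic"]] - 1L,
                to_index = wins[[best]][["to"]] - 1L,
                rate = vgrf$rate, t0 = vgrf$t0)
}

#' Re-express a force-plate event on the IMU clock
#'
#' Keeps the event's exact times (force-plate precision) and recomputes the
#' sample indices as the nearest samples of an IMU-rate clock sharing the
#' same time origin, with half-sample midpoints rounded up.  The round trip
#' index -> time -> index on the new clock is the identity.
#'
#' @param event a [contact_event()] from the vGRF clock.
#' @param imu_rate target clock rate in Hz (nominally 60).
#' @param t0 time origin of the IMU clock (defaults to the event's own).
#' @return a [contact_event()] carrying the original times with indices on
#'   the IMU clock.
#' @export
grf_event_on_imu_clock <- function(event, imu_rate, t0 = event$t0) {
  stopifnot(inherits(event, "contact_event"),
            is.numeric(imu_rate), imu_rate > 0)
  idx <- function(t) as.integer(floor((t - t0) * imu_rate + 0.5))
  contact_event(ic_index = idx(event$ic_time), to_index = idx(event$to_time),
                rate = imu_rate, t0 = t0,
                ic_time = event$ic_time, to_time = event$to_time)
}
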