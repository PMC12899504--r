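#' Read a trial from CSV
#'
#' The interchange layout is one CSV per trial with header
#' `t,pelvis_vz,foot_ax,foot_ay,foot_az` (IMU channels, nominally 60 Hz)
#' and optionally a `vgrf` column when the force channel shares the IMU
#' rate.  Because the force platform is normally sampled at 1000 Hz, the
#' vGRF may instead live in a companion CSV with header `t,vgrf`
#' (`grf_path`).  `t` is in seconds, strictly increasing and uniform to
#' within 1e-6 s; all samples must be finite.
#'
#' @param path path to the IMU CSV.
#' @param meta a [trial_meta()] for the trial.
#' @param grf_path optional path to the 1000 Hz `t,vgrf` CSV.
#' @return an [fc_trial()]; `vgrf` is `NULL` when no force channel is found.
#' @export
read_trial <- function(path, meta, grf_path = NULL) {
  stopifnot(inherits(meta, "trial_meta"))
  imu <- read_uniform_csv(path, c("t", "pelvis_vz", "foot_ax", "foot_ay",
                                  "foot_az"))
  rate <- imu$rate
  t0 <- imu$t0
  vgrf <- NULL
  if (!is.null(grf_path)) {
    g <- read_uniform_csv(grf_path, c("t", "vgrf"))
    vgrf <- uniform_signal(g$data$vgrf, rate = g$rate, t0 = g$t0, units = "N")
  } else if ("vgrf" %in% names(imu$data)) {
    vgrf <- uniform_signal(imu$data$vgrf, rate = rate, t0 = t0, units = "N")
  }
  fc_trial(
    meta = meta,
    pelvis_vz = uniform_signal(imu$data$pelvis_vz, rate = rate, t0 = t0,
                               units = "m/s"),
    foot_acc = triaxial_signal(
      uniform_signal(imu$data$foot_ax, rate = rate, t0 = t0, units = "m/s^2"),
      uniform_signal(imu$data$foot_ay, rate = rate, t0 = t0, units = "m/s^2"),
      uniform_signal(imu$data$foot_az, rate = rate, t0 = t0, units = "m/s^2")),
    vgrf = vgrf
  )
}

read_uniform_csv <- function(path, required) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  dat <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(required, names(dat))
  if (length(miss))
    stop(sprintf("%s: malformed header, missing column(s): %s",
                 basename(path), paste(miss, collapse = ", ")), call. = FALSE)
  for (col in names(dat)) {
    bad <- which(!is.finite(dat[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-finite value at row %d, column '%s'",
                   basename(path), bad[1L], col), call. = FALSE)
  }
  tt <- dat$t
  if (length(tt) < 2L)
    stop(sprintf("%s: need at least 2 samples", basename(path)), call. = FALSE)
  dt <- diff(tt)
  if (any(dt <= 0))
    stop(sprintf("%s: time stamps not strictly increasing at row %d, column 't'",
                 basename(path), which(dt <= 0)[1L] + 1L), call. = FALSE)
  step <- stats::median(dt)
  off <- which(abs(dt - step) > 1e-6)
  if (length(off))
    stop(sprintf("%s: non-uniform time stamps at row %d, column 't' (gap %.3g s vs step %.3g s)",
                 basename(path), off[1L] + 1L, dt[off[1L]], step), call. = FALSE)
  list(data = dat, rate = 1 / step, t0 = tt[1L])
}

#' Write a trial to CSV
#'
#' Inverse of [read_trial()]: writes the IMU channels to `path` and, when a
#' vGRF channel is present, the force channel to `grf_path` (default:
#' `path` with a `_grf.csv` suffix).  Values are written with full double
#' precision so that a read/write round trip reproduces the trial to within
#' 1e-9.
#'
#' @param trial an [fc_trial()].
#' @param path output path for the IMU CSV.
#' @param grf_path output path for the vGRF CSV (used only when the trial
#'   has a force channel).
#' @return invisibly, the paths written.
#' @export
write_trial <- function(trial, path,
                        grf_path = sub("\\.csv$", "_grf.csv", path)) {
  stopifnot(inherits(trial, "fc_trial"))
  imu <- data.frame(
    t = signal_times(trial$pelvis_vz),
    pelvis_vz = trial$pelvis_vz$values,
    foot_ax = trial$foot_acc$x$values,
    foot_ay = trial$foot_acc$y$values,
    foot_az = trial$foot_acc$z$values
  )
  write_full_csv(imu, path)
  paths <- path
  if (!is.null(trial$vgrf)) {
    write_full_csv(data.frame(t = signal_times(trial$vgrf),
                              vgrf = trial$vgrf$values), grf_path)
    paths <- c(paths, grf_path)
  }
  invisible(paths)
}

write_full_csv <- function(df, path) {
  for (col in names(df))
    df[[col]] <- sprintf("%.12g", df[[col]])
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop(sprintf("cannot write %s", path), call. = FALSE)
}

#' Write detection events to JSON
#'
#' One record per trial x algorithm:
#' `{trial_id, participant_id, task, sex, leg, algorithm, failed,
#' ic_time_s, to_time_s, duration_ms}`, with `null` event fields for
#' failed detections.
#'
#' @param events list of records, each a list with elements `meta`
#'   (a [trial_meta()]), `algorithm` (character) and `result`
#'   (a `detection_result`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_events <- function(events, path) {
  recs <- lapply(events, function(e) {
    stopifnot(inherits(e$meta, "trial_meta"))
    r <- e$result
    list(trial_id = e$meta$trial_id,
         participant_id = e$meta$participant_id,
         task = e$meta$task, sex = e$meta$sex, leg = e$meta$leg,
         algorithm = e$algorithm,
         failed = isTRUE(r$failed),
         ic_time_s = if (isTRUE(r$failed)) NULL else r$contact$ic_time,
         to_time_s = if (isTRUE(r$failed)) NULL else r$contact$to_time,
         duration_ms = if (isTRUE(r$failed)) NULL
                       else 1000 * r$contact$duration)
  })
  ok <- tryCatch({
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write %s", path), call. = FALSE)
  invisible(path)
}

#' Read detection events from JSON
#'
#' @param path path written by [write_events()].
#' @return a data frame with one row per record (`ic_time_s`, `to_time_s`
#'   and `duration_ms` are `NA` for failed detections).
#' @export
read_events <- function(path) {
  recs <- jsonlite::read_json(path)
  as_row <- function(r) data.frame(
    trial_id = r$trial_id, participant_id = r$participant_id,
    task = r$task, sex = r$sex, leg = r$leg, algorithm = r$algorithm,
    failed = isTRUE(r$failed),
    ic_time_s = if (is.null(r$ic_time_s)) NA_real_ else r$ic_time_s,
    to_time_s = if (is.null(r$to_time_s)) NA_real_ else r$to_time_s,
    duration_ms = if (is.null(r$duration_ms)) NA_real_ else r$duration_ms
  )
  do.call(rbind, lapply(recs, as_row))
}
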