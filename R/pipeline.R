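#' Default run configuration
#'
#' One nested list holding every constant of the chain at its development
#' value: the 50 N force threshold, the 20 Hz / 3rd-order zero-phase
#' low-pass filter, the -0.1 m/s^2 pelvis descent threshold, the 30 m/s^2
#' toe-off peak threshold, the 60 m/s^2 hybrid gate, and the synthetic
#' cohort specification.  Serializable to/from JSON so runs are fully
#' auditable.
#'
#' @param seed integer seed recorded in (and used by) every run.
#' @return a list with components `cohort`, `detector`, `grf` and `seed`.
#' @export
default_config <- function(seed = 1L) {
  list(
    cohort = unclass(cohort_spec(seed = seed)),
    detector = list(
      cutoff_hz = 20, order = 3, zero_phase = TRUE,
      pvv_descent_threshold = -0.1,
      rfa_to_threshold = 30,
      hybrid_ic_gate = 60,
      min_prominence_frac = 0.05,
      u_shape_frac = 0.5
    ),
    grf = list(threshold_n = 50, min_contact_s = 0.05),
    seed = as.integer(seed)
  )
}

#' Read a JSON run configuration
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path JSON file, or `NULL` for the defaults.
#' @param seed seed overriding the file's (and the default's) seed.
#' @return a configuration list.
#' @export
read_config <- function(path = NULL, seed = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (sec in intersect(names(user), names(cfg))) {
      if (is.list(cfg[[sec]]))
        cfg[[sec]][names(user[[sec]])] <- user[[sec]]
      else cfg[[sec]] <- user[[sec]]
    }
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$cohort$seed <- cfg$seed
  cfg
}

config_detector_params <- function(cfg) {
  d <- cfg$detector
  detector_params(
    filter = filter_spec(d$cutoff_hz, d$order, d$zero_phase),
    pvv_descent_threshold = d$pvv_descent_threshold,
    rfa_to_threshold = d$rfa_to_threshold,
    hybrid_ic_gate = d$hybrid_ic_gate,
    min_prominence_frac = d$min_prominence_frac,
    u_shape_frac = d$u_shape_frac
  )
}

config_cohort_spec <- function(cfg) do.call(cohort_spec, cfg$cohort)

config_grf_params <- function(cfg)
  grf_params(cfg$grf$threshold_n, cfg$grf$min_contact_s)

#' Simulate a cohort to disk
#'
#' Writes one IMU CSV and one vGRF CSV per trial, a `truth.json` with the
#' planted events, and a `manifest.json` recording the cohort
#' specification, seed and package version.
#'
#' @param config a configuration list (see [default_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
run_simulate <- function(config = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("run_simulate: cannot create %s", out_dir), call. = FALSE)
  spec <- config_cohort_spec(config)
  cohort <- generate_cohort(spec)
  truth <- list()
  trial_ids <- character(length(cohort))
  for (i in seq_along(cohort)) {
    tr <- cohort[[i]]$trial
    id <- tr$meta$trial_id
    trial_ids[i] <- id
    write_trial(tr, file.path(out_dir, paste0(id, ".csv")))
    truth[[id]] <- c(cohort[[i]]$truth,
                     list(meta = unclass(tr$meta)))
  }
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(package = "fcdetect",
                   version = as.character(utils::packageVersion("fcdetect")),
                   seed = spec$seed,
                   n_trials = length(cohort),
                   trial_ids = trial_ids,
                   cohort = unclass(spec))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the detectors over a simulated cohort on disk
#'
#' Reads every trial listed in the manifest, runs the selected algorithms,
#' and writes one events JSON (see [write_events()]).  Per-trial problems
#' (e.g. missing channel files) are recorded as failed records and the run
#' continues.
#'
#' @param trials_dir directory written by [run_simulate()].
#' @param out_file path of the events JSON to write.
#' @param config a configuration list.
#' @param algorithms subset of `c("PVV", "RFA", "HYBRID")`.
#' @return invisibly, the events data frame (via [read_events()]).
#' @export
run_detect <- function(trials_dir, out_file, config = default_config(),
                       algorithms = c("PVV", "RFA", "HYBRID")) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  manifest <- jsonlite::read_json(file.path(trials_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  truth <- jsonlite::read_json(file.path(trials_dir, "truth.json"))
  params <- config_detector_params(config)
  events <- list()
  for (id in manifest$trial_ids) {
    m <- truth[[id]]$meta
    meta <- trial_meta(m$trial_id, m$participant_id, m$task, m$sex, m$leg)
    res_list <- tryCatch({
      tr <- read_trial(file.path(trials_dir, paste0(id, ".csv")), meta,
                       grf_path = file.path(trials_dir, paste0(id, "_grf.csv")))
      lapply(algorithms, function(a) switch(
        a,
        PVV = detect_pvv(tr$pelvis_vz, params),
        RFA = detect_rfa(tr$foot_acc, params),
        HYBRID = detect_hybrid(tr$pelvis_vz, tr$foot_acc, params)))
    }, error = function(e) {
      warning(sprintf("trial %s: %s", id, conditionMessage(e)), call. = FALSE)
      lapply(algorithms, function(a)
        detection_result(a, contact = NULL, candidates = list()))
    })
    for (j in seq_along(algorithms))
      events[[length(events) + 1L]] <-
        list(meta = meta, algorithm = algorithms[j], result = res_list[[j]])
  }
  write_events(events, out_file)
  invisible(read_events(out_file))
}

#' Validate detector events against the force-plate reference
#'
#' Recomputes the reference contact from each trial's vGRF, joins it with
#' the detected events, and writes the concurrent-validity artifacts: an
#' agreement table CSV (median/IQR/quartiles/mean/limits of agreement per
#' algorithm x event), a mixed-model CSV (per-factor betas and p-values),
#' per-cell Bland-Altman plots (PNG), and a failure-count CSV.
#'
#' @param trials_dir directory written by [run_simulate()].
#' @param events_file events JSON written by [run_detect()].
#' @param out_dir output directory for the validation artifacts.
#' @param config a configuration list.
#' @return invisibly, a list with `offsets`, `agreement`, `failures` and
#'   `lme` (the mixed-model table, `NULL` when a factor is constant).
#' @export
run_validate <- function(trials_dir, events_file, out_dir,
                         config = default_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  events <- read_events(events_file)
  manifest <- jsonlite::read_json(file.path(trials_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  truth <- jsonlite::read_json(file.path(trials_dir, "truth.json"))
  gp <- config_grf_params(config)
  refs <- lapply(manifest$trial_ids, function(id) {
    m <- truth[[id]]$meta
    meta <- trial_meta(m$trial_id, m$participant_id, m$task, m$sex, m$leg)
    tr <- read_trial(file.path(trials_dir, paste0(id, ".csv")), meta,
                     grf_path = file.path(trials_dir, paste0(id, "_grf.csv")))
    detect_grf_contact(tr$vgrf, gp)
  })
  names(refs) <- manifest$trial_ids
  events <- events[events$trial_id %in% names(refs), , drop = FALSE]
  if (nrow(events) == 0L)
    stop("run_validate: no events overlap the simulated trials", call. = FALSE)
  ok <- events[!events$failed, , drop = FALSE]
  offsets <- do.call(rbind, lapply(c("IC", "TO"), function(ev) {
    ref_t <- vapply(ok$trial_id, function(id)
      if (ev == "IC") refs[[id]]$ic_time else refs[[id]]$to_time, 1.0)
    det_t <- if (ev == "IC") ok$ic_time_s else ok$to_time_s
    data.frame(ok[, c("trial_id", "participant_id", "task", "sex", "leg",
                      "algorithm")],
               event = ev, reference_s = ref_t, detected_s = det_t,
               offset_ms = 1000 * (ref_t - det_t), row.names = NULL)
  }))
  agreement <- agreement_table(offsets)
  utils::write.csv(agreement, file.path(out_dir, "agreement.csv"),
                   row.names = FALSE)
  failures <- stats::aggregate(failed ~ algorithm, data = events, FUN = sum)
  failures$n_trials <- as.vector(table(events$algorithm)[failures$algorithm])
  utils::write.csv(failures, file.path(out_dir, "failures.csv"),
                   row.names = FALSE)
  lme_rows <- NULL
  for (alg in unique(offsets$algorithm)) for (ev in c("IC", "TO")) {
    sub <- offsets[offsets$algorithm == alg & offsets$event == ev, ]
    fit <- tryCatch(fit_error_model(sub), error = function(e) NULL)
    if (!is.null(fit))
      lme_rows <- rbind(lme_rows,
                        cbind(algorithm = alg, event = ev, fit$betas,
                              r2_adj = fit$r2_adj, model_p = fit$model_p))
    p <- bland_altman_plot(sub$reference_s, sub$detected_s,
                           title = sprintf("%s, %s", alg, ev))
    ggplot2::ggsave(file.path(out_dir, sprintf("bland_altman_%s_%s.png",
                                               tolower(alg), tolower(ev))),
                    p, width = 5, height = 4, dpi = 120)
  }
  if (!is.null(lme_rows))
    utils::write.csv(lme_rows, file.path(out_dir, "error_model.csv"),
                     row.names = FALSE)
  invisible(list(offsets = offsets, agreement = agreement,
                 failures = failures, lme = lme_rows))
}
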