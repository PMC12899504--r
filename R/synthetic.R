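#' Synthetic cohort specification
#'
#' Parameters of the seeded trial generator.  The defaults mirror the study
#' conditions the detectors were developed under: 34 athletes, stance
#' (foot-contact) windows of 478.3 +/- 162.1 ms, foot acceleration at
#' initial contact of 94.6 +/- 36.8 m/s^2, and a 17.5% share of
#' "low-acceleration" trials whose IC peak falls below 57.8 m/s^2 (one SD
#' below the mean) -- the soft landings that degrade the foot-acceleration
#' detector and motivate the hybrid's 60 m/s^2 gate.
#'
#' @param n_participants number of participants.
#' @param trials_per_participant repetitions per participant.
#' @param task_mix fraction of trials that are changes of direction (COD);
#'   the rest are decelerations (DEC).
#' @param sex_mix fraction of participants that are male.
#' @param stance_mean_ms,stance_sd_ms stance-duration distribution (ms);
#'   draws are truncated to +/- 2 SD, keeping the mean unbiased.
#' @param rfa_ic_mean,rfa_ic_sd distribution of the foot-acceleration peak
#'   height at initial contact (m/s^2) on ordinary trials, truncated below
#'   at 5.
#' @param low_acc_fraction probability that a trial is a low-acceleration
#'   (soft-landing) trial, whose IC peak is drawn below 57.8 m/s^2 and is
#'   broad rather than spike-like.
#' @param noise_sd_pvv additive Gaussian noise SD on the pelvis vertical
#'   velocity (m/s).
#' @param noise_sd_rfa additive Gaussian noise SD per foot-acceleration
#'   axis (m/s^2).
#' @param noise_sd_grf additive Gaussian noise SD on the vGRF (N).
#' @param sync_jitter_ms SD of a per-trial clock offset between the IMU
#'   channels and the force platform (ms); 0 emulates a verified hardware
#'   trigger.
#' @param planted_task_beta_ms,planted_sex_beta_ms,planted_leg_beta_ms
#'   systematic timing effects (ms): IMU waveform landmarks are shifted
#'   earlier than the force-plate truth by the summed betas of the trial's
#'   COD / male / non-dominant indicators, so a positive beta surfaces as a
#'   positive (detector-early) offset for that level.
#' @param distractor_prob probability that an ordinary trial carries a
#'   preceding shorter running step (a distractor contact off the platform).
#' @param trial_duration_s length of each trial (s).
#' @param imu_rate_hz,grf_rate_hz channel sampling rates (Hz).
#' @param seed integer seed making the cohort reproducible.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 34,
                        trials_per_participant = 8,
                        task_mix = 0.5,
                        sex_mix = 18 / 34,
                        stance_mean_ms = 478.3,
                        stance_sd_ms = 162.1,
                        rfa_ic_mean = 94.6,
                        rfa_ic_sd = 36.8,
                        low_acc_fraction = 0.175,
                        noise_sd_pvv = 0.01,
                        noise_sd_rfa = 1.5,
                        noise_sd_grf = 1.0,
                        sync_jitter_ms = 0,
                        planted_task_beta_ms = 0,
                        planted_sex_beta_ms = 0,
                        planted_leg_beta_ms = 0,
                        distractor_prob = 0.35,
                        trial_duration_s = 2.5,
                        imu_rate_hz = 60,
                        grf_rate_hz = 1000,
                        seed = 1L) {
  spec <- list(n_participants = as.integer(n_participants),
               trials_per_participant = as.integer(trials_per_participant),
               task_mix = task_mix, sex_mix = sex_mix,
               stance_mean_ms = stance_mean_ms, stance_sd_ms = stance_sd_ms,
               rfa_ic_mean = rfa_ic_mean, rfa_ic_sd = rfa_ic_sd,
               low_acc_fraction = low_acc_fraction,
               noise_sd_pvv = noise_sd_pvv, noise_sd_rfa = noise_sd_rfa,
               noise_sd_grf = noise_sd_grf,
               sync_jitter_ms = sync_jitter_ms,
               planted_task_beta_ms = planted_task_beta_ms,
               planted_sex_beta_ms = planted_sex_beta_ms,
               planted_leg_beta_ms = planted_leg_beta_ms,
               distractor_prob = distractor_prob,
               trial_duration_s = trial_duration_s,
               imu_rate_hz = imu_rate_hz, grf_rate_hz = grf_rate_hz,
               seed = as.integer(seed))
  fracs <- c("task_mix", "sex_mix", "low_acc_fraction", "distractor_prob")
  for (f in fracs)
    if (spec[[f]] < 0 || spec[[f]] > 1)
      stop(sprintf("cohort_spec: '%s' must be in [0, 1]", f), call. = FALSE)
  for (f in c("stance_sd_ms", "noise_sd_pvv", "noise_sd_rfa", "noise_sd_grf",
              "sync_jitter_ms", "rfa_ic_sd"))
    if (spec[[f]] < 0)
      stop(sprintf("cohort_spec: '%s' must be >= 0", f), call. = FALSE)
  if (spec$stance_mean_ms <= 0)
    stop("cohort_spec: 'stance_mean_ms' must be positive", call. = FALSE)
  if (spec$n_participants < 1L || spec$trials_per_participant < 1L)
    stop("cohort_spec: cohort dimensions must be >= 1", call. = FALSE)
  if (spec$stance_mean_ms + 2 * spec$stance_sd_ms > 1000 * spec$trial_duration_s / 2)
    stop("cohort_spec: stance too long for the trial duration", call. = FALSE)
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d participants x %d trials; stance %.1f +/- %.1f ms;\n",
                     "  IC acceleration %.1f +/- %.1f m/s^2; low-acc fraction %.3f; seed %d\n"),
              x$n_participants, x$trials_per_participant,
              x$stance_mean_ms, x$stance_sd_ms,
              x$rfa_ic_mean, x$rfa_ic_sd, x$low_acc_fraction, x$seed))
  invisible(x)
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

gauss_bump <- function(t, center, sigma) exp(-((t - center)^2) / (2 * sigma^2))

#' Generate one synthetic trial with planted events
#'
#' Builds the three channels of a trial from smooth parametric bumps around
#' analytically planted initial-contact and toe-off times, plus additive
#' Gaussian noise, so that every stage of the chain can be verified against
#' known truth:
#'
#' * vGRF (1000 Hz): a Gaussian stance bump whose 50 N crossings fall
#'   exactly at the planted IC and TO times.
#' * Pelvis vertical velocity (60 Hz): a landing trough with its minimum at
#'   IC, a push-off peak at TO, and a steep post-toe-off descent, over a
#'   faint baseline oscillation.
#' * Foot acceleration (60 Hz): a fixed random unit direction scaled by a
#'   resultant profile with an impact peak at IC and a push-off peak at TO
#'   over a low baseline, giving the twin-peak "U shape" stance pattern.
#'
#' Low-acceleration (soft-landing) trials draw the IC peak below
#' 57.8 m/s^2 and make it broad (flat-topped) instead of spike-like, and
#' likewise shallow and broaden the pelvis landing trough; with noise this
#' reproduces the unreliable IC detection such landings cause, while at
#' zero noise all detectors still recover the planted events.  Ordinary
#' trials may carry a shorter preceding running step (distractor) whose
#' contact and the flight gap to the main step are both strictly shorter
#' than the main stance.  Draws use the current RNG state; see
#' [generate_cohort()] for seeded cohorts.
#'
#' @param spec a [cohort_spec()].
#' @param meta a [trial_meta()].
#' @param low_acc force low-acceleration status (default: drawn from
#'   `spec$low_acc_fraction`).
#' @param distractor force a distractor step (default: drawn from
#'   `spec$distractor_prob` on eligible trials).
#' @return a list with the [fc_trial()] in `trial` and the planted truth in
#'   `truth` (fields `ic_time`, `to_time`, `duration`, `low_acc`,
#'   `rfa_ic_magnitude`, `distractor_contacts`, `landmark_shift_ms`).
#' @export
generate_trial <- function(spec, meta, low_acc = NULL, distractor = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(meta, "trial_meta"))
  dur <- spec$trial_duration_s
  stance <- rnorm_trunc(1, spec$stance_mean_ms, spec$stance_sd_ms,
                        spec$stance_mean_ms - 2 * spec$stance_sd_ms,
                        spec$stance_mean_ms + 2 * spec$stance_sd_ms) / 1000
  stance <- max(stance, 0.12)
  ic <- stats::runif(1, 0.80, 1.05)
  to <- ic + stance
  if (is.null(low_acc)) low_acc <- stats::runif(1) < spec$low_acc_fraction

  # landmark shift: planted fixed effects plus trigger jitter, applied to the
  # IMU waveforms only; positive beta => IMU landmarks earlier than vGRF truth
  shift <- (meta$task == "COD") * spec$planted_task_beta_ms +
    (meta$sex == "male") * spec$planted_sex_beta_ms +
    (meta$leg == "nondominant") * spec$planted_leg_beta_ms
  jitter <- if (spec$sync_jitter_ms > 0)
    stats::rnorm(1, 0, spec$sync_jitter_ms) else 0
  ic_l <- ic - (shift + jitter) / 1000
  to_l <- to - (shift + jitter) / 1000

  # --- vGRF: Gaussian bump crossing the 50 N threshold exactly at ic and to
  peak_n <- stats::runif(1, 1500, 2200)
  sigma_f <- (stance / 2) / sqrt(2 * log(peak_n / 50))
  tg <- (0:(round(dur * spec$grf_rate_hz) - 1)) / spec$grf_rate_hz
  vgrf_v <- peak_n * gauss_bump(tg, (ic + to) / 2, sigma_f)
  if (spec$noise_sd_grf > 0)
    vgrf_v <- vgrf_v + stats::rnorm(length(tg), 0, spec$noise_sd_grf)
  vgrf_v <- pmax(vgrf_v, 0)

  # --- IMU time base
  ti <- (0:(round(dur * spec$imu_rate_hz) - 1)) / spec$imu_rate_hz

  # --- foot acceleration resultant profile
  # soft landings lack the sharp impact spike: the smaller the IC peak, the
  # broader it is and the more it reflects the (slightly later) loading
  # phase rather than impact -- the mechanism behind the negative
  # correlation between acceleration magnitude and IC reliability
  h_ic <- if (low_acc) stats::runif(1, 35, 57.5)
          else rnorm_trunc(1, spec$rfa_ic_mean, spec$rfa_ic_sd, lower = 5)
  soft <- min(1, max(0, (75 - h_ic) / 40))
  sig_ic <- min(0.018 + 0.22 * soft, stance / 3)
  ic_peak_t <- ic_l + 0.006 * soft
  h_to <- rnorm_trunc(1, 90, 12, lower = 70)
  sig_to <- min(0.018, stance / 6)
  rfa_base <- 3 + 0.3 * sin(2 * pi * 0.8 * ti)
  rfa_prof <- rfa_base + h_ic * gauss_bump(ti, ic_peak_t, sig_ic) +
    h_to * gauss_bump(ti, to_l, sig_to)

  # --- pelvis vertical velocity profile
  if (low_acc) {
    depth <- stats::runif(1, 0.35, 0.55)
    sig_tr <- min(0.045, stance / 5)
  } else {
    depth <- stats::runif(1, 0.8, 1.3)
    sig_tr <- min(0.04, stance / 5)
  }
  push <- stats::runif(1, 0.5, 0.9)
  sig_push <- min(0.035, stance / 5)
  drop_amp <- stats::runif(1, 1.0, 1.5)
  # pelvis landmarks lag touchdown / lead push-off by half an IMU sample:
  # the velocity minimum follows impact and the maximum precedes toe-off,
  # keeping zero-noise recovery within one sample while reproducing the
  # later-IC tendency of the pelvis signal relative to the foot signal
  pvv_lag <- 0.008
  pvv_prof <- 0.01 * sin(2 * pi * 0.35 * ti + stats::runif(1, 0, 2 * pi)) -
    depth * gauss_bump(ti, ic_l + pvv_lag, sig_tr) +
    push * gauss_bump(ti, to_l, sig_push) -
    drop_amp * stats::plogis((ti - (to_l + 0.10)) / 0.03)

  # --- optional distractor step strictly shorter than the main contact
  distractors <- list()
  eligible <- !low_acc && soft <= 0
  if (is.null(distractor)) distractor <- eligible &&
      stats::runif(1) < spec$distractor_prob
  if (distractor && eligible) {
    stance_d <- stats::runif(1, 0.5, 0.8) * min(stance, 0.5)
    gap <- stats::runif(1, 0.10, min(0.14, 0.8 * stance))
    to_d <- ic_l - gap
    ic_d <- to_d - stance_d
    if (ic_d > 0.15) {
      h1 <- stats::runif(1, 40, 70)
      h2 <- stats::runif(1, 40, 70)
      rfa_prof <- rfa_prof + h1 * gauss_bump(ti, ic_d, 0.016) +
        h2 * gauss_bump(ti, to_d, 0.016)
      pvv_prof <- pvv_prof - 0.5 * gauss_bump(ti, ic_d, 0.03) +
        0.35 * gauss_bump(ti, to_d, 0.025)
      distractors <- list(list(ic_time = ic_d, to_time = to_d,
                               duration = stance_d))
    }
  }

  # --- noise and channel assembly
  if (spec$noise_sd_pvv > 0)
    pvv_prof <- pvv_prof + stats::rnorm(length(ti), 0, spec$noise_sd_pvv)
  u <- abs(stats::rnorm(3))
  u <- u / sqrt(sum(u^2))
  mk_axis <- function(k) {
    v <- rfa_prof * u[k]
    if (spec$noise_sd_rfa > 0)
      v <- v + stats::rnorm(length(ti), 0, spec$noise_sd_rfa / sqrt(3))
    uniform_signal(v, rate = spec$imu_rate_hz, t0 = 0, units = "m/s^2")
  }
  trial <- fc_trial(
    meta = meta,
    pelvis_vz = uniform_signal(pvv_prof, rate = spec$imu_rate_hz, t0 = 0,
                               units = "m/s"),
    foot_acc = triaxial_signal(mk_axis(1), mk_axis(2), mk_axis(3)),
    vgrf = uniform_signal(vgrf_v, rate = spec$grf_rate_hz, t0 = 0,
                          units = "N")
  )
  truth <- list(ic_time = ic, to_time = to, duration = stance,
                low_acc = low_acc, rfa_ic_magnitude = h_ic,
                distractor_contacts = distractors,
                landmark_shift_ms = shift + jitter)
  list(trial = trial, truth = truth)
}

#' Generate a seeded synthetic cohort
#'
#' Draws a balanced cohort: participant sex follows `sex_mix` (deterministic
#' counts), legs alternate within participant, and tasks follow `task_mix`
#' within each participant's trials (counts rounded to the nearest integer).
#' The whole cohort is reproducible from `spec$seed`; the caller's RNG state
#' is restored afterwards.
#'
#' @param spec a [cohort_spec()].
#' @return a list of per-trial lists, each with elements `trial` and
#'   `truth` as returned by [generate_trial()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  n_male <- round(spec$sex_mix * spec$n_participants)
  tpp <- spec$trials_per_participant
  out <- vector("list", spec$n_participants * tpp)
  k <- 0L
  for (p in seq_len(spec$n_participants)) {
    pid <- sprintf("P%02d", p)
    sex <- if (p <= n_male) "male" else "female"
    # cumulative rounding keeps the cohort-wide COD count within 1 of
    # task_mix * n_trials
    n_cod <- round(spec$task_mix * p * tpp) - round(spec$task_mix * (p - 1) * tpp)
    tasks <- c(rep("COD", n_cod), rep("DEC", tpp - n_cod))
    for (j in seq_len(spec$trials_per_participant)) {
      k <- k + 1L
      meta <- trial_meta(
        trial_id = sprintf("%s_T%02d", pid, j),
        participant_id = pid,
        task = tasks[j],
        sex = sex,
        leg = if (j %% 2L == 1L) "dominant" else "nondominant"
      )
      out[[k]] <- generate_trial(spec, meta)
    }
  }
  out
}

#' Simulate offset records for statistics calibration
#'
#' Draws detector-error records directly at the offset level (no waveforms):
#' `offset_ms = task_beta * COD + sex_beta * male + leg_beta * nondominant +
#' participant intercept + residual`, with balanced factors at the study's
#' scale.  Used to calibrate [fit_error_model()] -- planted-effect recovery,
#' type-I error under the null, and variance-component estimation.
#'
#' @param n_participants,trials_per_participant cohort dimensions.
#' @param task_beta_ms,sex_beta_ms,leg_beta_ms planted fixed effects (ms).
#' @param ranef_sd_ms SD of the per-participant random intercept (ms).
#' @param resid_sd_ms residual SD (ms).
#' @return a data frame of offset records (`offset_ms`, `participant_id`,
#'   `task`, `sex`, `leg`).
#' @export
generate_offset_records <- function(n_participants = 34,
                                    trials_per_participant = 8,
                                    task_beta_ms = 0,
                                    sex_beta_ms = 0,
                                    leg_beta_ms = 0,
                                    ranef_sd_ms = 2,
                                    resid_sd_ms = 5) {
  n_male <- round(n_participants / 2)
  n_cod <- round(trials_per_participant / 2)
  rows <- list()
  for (p in seq_len(n_participants)) {
    b0 <- stats::rnorm(1, 0, ranef_sd_ms)
    sex <- if (p <= n_male) "male" else "female"
    for (j in seq_len(trials_per_participant)) {
      task <- if (j <= n_cod) "COD" else "DEC"
      leg <- if (j %% 2L == 1L) "dominant" else "nondominant"
      off <- task_beta_ms * (task == "COD") + sex_beta_ms * (sex == "male") +
        leg_beta_ms * (leg == "nondominant") + b0 +
        stats::rnorm(1, 0, resid_sd_ms)
      rows[[length(rows) + 1L]] <- data.frame(
        offset_ms = off, participant_id = sprintf("P%02d", p),
        task = task, sex = sex, leg = leg)
    }
  }
  do.call(rbind, rows)
}
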