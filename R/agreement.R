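#' Timing offset between reference and detected event
#'
#' `offset_ms = 1000 * (reference time - detected time)` for the chosen
#' event type, so a positive offset means the detector fired earlier than
#' the force platform.
#'
#' @param reference the force-plate [contact_event()].
#' @param detected the detector's [contact_event()].
#' @param event `"IC"` or `"TO"`.
#' @return the offset in milliseconds.
#' @export
compute_offset <- function(reference, detected, event = c("IC", "TO")) {
  event <- match.arg(event)
  stopifnot(inherits(reference, "contact_event"),
            inherits(detected, "contact_event"))
  if (event == "IC") 1000 * (reference$ic_time - detected$ic_time)
  else 1000 * (reference$to_time - detected$to_time)
}

#' Agreement summary for one algorithm and event type
#'
#' Median, quartiles (linear interpolation between order statistics,
#' `stats::quantile` type 7), IQR, mean, SD (n - 1 denominator), Bland-Altman
#' limits of agreement `mean +/- 1.96 * SD`, and the number of offsets
#' falling outside the limits (the outlier count).
#'
#' @param offsets_ms numeric vector of offsets in milliseconds (n >= 3).
#' @return an object of class `agreement_summary`: a list with `n`,
#'   `median_ms`, `q1_ms`, `q3_ms`, `iqr_ms`, `mean_ms`, `sd_ms`,
#'   `loa_low_ms`, `loa_high_ms`, `n_outliers`.
#' @export
summarize_offsets <- function(offsets_ms) {
  offsets_ms <- as.numeric(offsets_ms)
  if (length(offsets_ms) < 3L)
    stop("summarize_offsets: need at least 3 offsets", call. = FALSE)
  if (!all(is.finite(offsets_ms)))
    stop("summarize_offsets: offsets must be finite", call. = FALSE)
  q <- stats::quantile(offsets_ms, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  m <- mean(offsets_ms)
  s <- stats::sd(offsets_ms)
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  structure(
    list(n = length(offsets_ms),
         median_ms = q[2], q1_ms = q[1], q3_ms = q[3], iqr_ms = q[3] - q[1],
         mean_ms = m, sd_ms = s, loa_low_ms = lo, loa_high_ms = hi,
         n_outliers = sum(offsets_ms < lo | offsets_ms > hi)),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(paste0("<agreement_summary> n = %d\n",
                     "  median %.1f ms, IQR %.1f ms [%.1f; %.1f]\n",
                     "  mean %.1f ms, LoA [%.1f; %.1f] ms, %d outlier(s)\n"),
              x$n, x$median_ms, x$iqr_ms, x$q1_ms, x$q3_ms,
              x$mean_ms, x$loa_low_ms, x$loa_high_ms, x$n_outliers))
  invisible(x)
}

check_offset_frame <- function(offsets) {
  need <- c("offset_ms", "participant_id", "task", "sex", "leg")
  miss <- setdiff(need, names(offsets))
  if (length(miss))
    stop(sprintf("offset records lack column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  offsets
}

#' Mixed-effects model of detector error
#'
#' Fits `offset_ms ~ task + sex + leg + (1 | participant_id)` to ask whether
#' detector error is influenced by the task (change of direction vs
#' deceleration), sex, or the tested leg, with a per-participant random
#' intercept for the repeated measures.  Factors are coded with DEC, female
#' and dominant as reference levels, so the reported coefficients are the
#' COD, male and non-dominant effects.  Fixed-effect p-values use the
#' Satterthwaite approximation (lmerTest); the adjusted R-squared and the
#' overall model p-value are computed on the fixed-effects-only (marginal)
#' least-squares fit.
#'
#' @param offsets data frame of offset records with columns `offset_ms`,
#'   `participant_id`, `task` (`"COD"`/`"DEC"`), `sex` (`"male"`/`"female"`),
#'   `leg` (`"dominant"`/`"nondominant"`); at least 10 records from at
#'   least 2 participants.
#' @return an object of class `fc_lme`: a list with `betas` (a data frame of
#'   per-factor estimates, standard errors and p-values), `r2_adj`,
#'   `model_p`, `random_intercept_var`, `residual_var`, `n`,
#'   `n_participants` and the fitted `lmerMod` in `fit`.
#' @export
fit_error_model <- function(offsets) {
  offsets <- check_offset_frame(as.data.frame(offsets))
  if (nrow(offsets) < 10L)
    stop("fit_error_model: need at least 10 records", call. = FALSE)
  if (length(unique(offsets$participant_id)) < 2L)
    stop("fit_error_model: need at least 2 participants", call. = FALSE)
  if (!all(is.finite(offsets$offset_ms)))
    stop("fit_error_model: offsets must be finite", call. = FALSE)
  dat <- data.frame(
    offset_ms = offsets$offset_ms,
    task = factor(offsets$task, levels = c("DEC", "COD")),
    sex = factor(offsets$sex, levels = c("female", "male")),
    leg = factor(offsets$leg, levels = c("dominant", "nondominant")),
    participant_id = factor(offsets$participant_id)
  )
  for (f in c("task", "sex", "leg"))
    if (length(unique(dat[[f]])) < 2L)
      stop(sprintf("fit_error_model: factor '%s' is constant (singular design)", f),
           call. = FALSE)
  fit <- lmerTest::lmer(offset_ms ~ task + sex + leg + (1 | participant_id),
                        data = dat, REML = TRUE)
  coefs <- stats::coef(summary(fit))
  rows <- c("taskCOD", "sexmale", "legnondominant")
  betas <- data.frame(
    factor = c("task (COD)", "sex (male)", "leg (nondominant)"),
    beta = coefs[rows, "Estimate"],
    se = coefs[rows, "Std. Error"],
    p = coefs[rows, "Pr(>|t|)"],
    row.names = NULL
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_var <- vc$vcov[vc$grp == "participant_id"]
  res_var <- vc$vcov[vc$grp == "Residual"]
  marginal <- stats::lm(offset_ms ~ task + sex + leg, data = dat)
  sm <- summary(marginal)
  fstat <- sm$fstatistic
  model_p <- unname(stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  structure(
    list(betas = betas, r2_adj = sm$adj.r.squared, model_p = model_p,
         random_intercept_var = ri_var, residual_var = res_var,
         n = nrow(dat), n_participants = nlevels(dat$participant_id),
         fit = fit),
    class = "fc_lme"
  )
}

#' @export
print.fc_lme <- function(x, ...) {
  cat(sprintf("<fc_lme> n = %d (%d participants); adj. R^2 = %.3f, model p = %.3g\n",
              x$n, x$n_participants, x$r2_adj, x$model_p))
  cat(sprintf("  random intercept var %.2f ms^2, residual var %.2f ms^2\n",
              x$random_intercept_var, x$residual_var))
  print(x$betas, digits = 3)
  invisible(x)
}

#' Error-source correlation
#'
#' Pearson correlation between detector offsets and a per-trial covariate
#' (movement speed for the pelvis-velocity detector, acceleration magnitude
#' for the foot-acceleration detector), with the two-sided p-value.
#'
#' @param offsets_ms numeric vector of offsets (ms).
#' @param covariate numeric vector of the same length.
#' @return a list with `r`, `p` and `n`.
#' @export
correlate_error_source <- function(offsets_ms, covariate) {
  offsets_ms <- as.numeric(offsets_ms)
  covariate <- as.numeric(covariate)
  if (length(offsets_ms) != length(covariate))
    stop("correlate_error_source: vectors differ in length", call. = FALSE)
  if (length(offsets_ms) < 3L)
    stop("correlate_error_source: need at least 3 pairs", call. = FALSE)
  if (!all(is.finite(offsets_ms)) || !all(is.finite(covariate)))
    stop("correlate_error_source: inputs must be finite", call. = FALSE)
  if (stats::sd(offsets_ms) == 0 || stats::sd(covariate) == 0)
    stop("correlate_error_source: zero variance, correlation undefined",
         call. = FALSE)
  ct <- stats::cor.test(offsets_ms, covariate, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(offsets_ms))
}

#' Agreement table across algorithms and event types
#'
#' Applies [summarize_offsets()] to every algorithm x event cell of a set of
#' offset records, producing the layout of a concurrent-validity results
#' table (median, IQR, quartiles, mean, limits of agreement, outliers).
#'
#' @param offsets data frame with columns `algorithm`, `event`, `offset_ms`.
#' @return a data frame with one row per algorithm x event.
#' @export
agreement_table <- function(offsets) {
  offsets <- as.data.frame(offsets)
  stopifnot(all(c("algorithm", "event", "offset_ms") %in% names(offsets)))
  cells <- unique(offsets[, c("algorithm", "event")])
  cells <- cells[order(cells$event, cells$algorithm), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- offsets$algorithm == cells$algorithm[i] &
      offsets$event == cells$event[i]
    s <- summarize_offsets(offsets$offset_ms[sel])
    cbind(cells[i, , drop = FALSE],
          as.data.frame(unclass(s), optional = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman plot
#'
#' Mean-difference scatter for one algorithm and event type: each point is
#' one trial, the x-axis the mean of reference and detected event times, the
#' y-axis their difference (the offset, ms).  The mean offset and the
#' 1.96-SD limits of agreement are drawn as horizontal lines.
#'
#' @param reference_s numeric vector of reference event times (s).
#' @param detected_s numeric vector of detected event times (s).
#' @param title plot title.
#' @return a ggplot object.
#' @export
bland_altman_plot <- function(reference_s, detected_s, title = "Bland-Altman") {
  stopifnot(length(reference_s) == length(detected_s))
  diff_ms <- 1000 * (reference_s - detected_s)
  s <- summarize_offsets(diff_ms)
  dat <- data.frame(mean_s = (reference_s + detected_s) / 2, diff_ms = diff_ms)
  ggplot2::ggplot(dat, ggplot2::aes(x = mean_s, y = diff_ms)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = s$mean_ms, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(s$loa_low_ms, s$loa_high_ms),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(title = title, x = "Mean of event times (s)",
                  y = "Reference - detected (ms)") +
    ggplot2::theme_minimal()
}
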