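test_that("offsets follow the detector-early-positive sign convention", {
  ref <- contact_event(500, 1000, rate = 1000)
  det <- contact_event(29, 60, rate = 60)           # IC at 0.48333 s
  expect_equal(compute_offset(ref, det, "IC"), 1000 * (0.5 - 29 / 60))
  expect_gt(compute_offset(ref, det, "IC"), 0)      # earlier => positive
  expect_equal(compute_offset(ref, ref, "IC"), 0)
  late <- contact_event(520, 1020, rate = 1000)     # TO at 1.020 s
  expect_equal(compute_offset(ref, late, "TO"), -20)
})

test_that("summarize_offsets matches closed forms and the quantile oracle", {
  s <- summarize_offsets(c(-5, 10, 20))
  expect_equal(s$median_ms, 10)
  expect_equal(s$mean_ms, 25 / 3)
  expect_equal(s$iqr_ms, 12.5)
  expect_equal(s$q1_ms, 2.5)
  expect_equal(s$q3_ms, 15)

  eq <- summarize_offsets(rep(4.2, 10))
  expect_equal(eq$iqr_ms, 0)
  expect_equal(eq$loa_low_ms, 4.2)
  expect_equal(eq$loa_high_ms, 4.2)
  expect_equal(eq$n_outliers, 0)

  set.seed(71)
  for (rep in 1:40) {
    x <- stats::rnorm(sample(3:200, 1), sd = stats::runif(1, 0.5, 50))
    s <- summarize_offsets(x)
    expect_equal(s$median_ms, oracle_quantile(x, 0.5))
    expect_equal(s$q1_ms, oracle_quantile(x, 0.25))
    expect_equal(s$q3_ms, oracle_quantile(x, 0.75))
    # limits of agreement are symmetric about the mean
    expect_equal(s$loa_high_ms - s$mean_ms, s$mean_ms - s$loa_low_ms,
                 tolerance = 1e-12)
  }
  expect_error(summarize_offsets(c(1, 2)), "at least 3")
})

test_that("limits of agreement capture ~95% of Gaussian offsets", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- stats::rnorm(1000, mean = 5, sd = 20)
    s <- summarize_offsets(x)
    expect_gte(s$n_outliers, stats::qbinom(0.005, 1000, 0.05))
    expect_lte(s$n_outliers, stats::qbinom(0.995, 1000, 0.05))
  }
})

test_that("a detector firing one frame early yields median offset +16.67 ms", {
  refs <- lapply(seq(0.5, 2.0, by = 0.1), function(t0)
    contact_event(round(t0 * 1000), round(t0 * 1000) + 400, rate = 1000))
  offs <- vapply(refs, function(r) {
    det_idx <- map_time_to_index(r$ic_time,
                                 uniform_signal(rep(0, 300), 60)) - 1L
    compute_offset(r, contact_event(det_idx, det_idx + 30L, rate = 60), "IC")
  }, 1.0)
  expect_equal(stats::median(offs), 1000 / 60, tolerance = 0.5)
})

test_that("fit_error_model validates its design and recovers planted effects", {
  base <- generate_offset_records(4, 4)
  expect_error(fit_error_model(base[1:8, ]), "at least 10")
  one <- base; one$task <- "COD"
  expect_error(fit_error_model(one), "task")
  onep <- base; onep$participant_id <- "P01"
  expect_error(fit_error_model(onep), "participants")

  set.seed(81)
  est <- replicate(30, {
    d <- generate_offset_records(34, 8, task_beta_ms = -3.785,
                                 ranef_sd_ms = 2, resid_sd_ms = 4)
    fit <- suppressMessages(fit_error_model(d))
    fit$betas$beta[fit$betas$factor == "task (COD)"]
  })
  expect_gte(mean(abs(est - (-3.785)) <= 0.3 * 3.785), 0.9)
  expect_lt(abs(mean(est) - (-3.785)) / 3.785, 0.1)
})

test_that("a planted zero variance component is estimated near zero", {
  set.seed(82)
  frac <- replicate(30, {
    d <- generate_offset_records(20, 6, ranef_sd_ms = 0, resid_sd_ms = 5)
    fit <- suppressMessages(fit_error_model(d))
    fit$random_intercept_var / fit$residual_var
  })
  expect_gte(mean(frac < 0.10), 0.9)
})

test_that("Pearson error-source correlations behave as planted", {
  x <- 1:20
  perfect <- correlate_error_source(2 * x, x)
  expect_equal(perfect$r, 1)

  set.seed(83)
  big_r <- replicate(40, {
    abs(correlate_error_source(stats::rnorm(200), stats::rnorm(200))$r)
  })
  expect_gte(mean(big_r < 0.2), 0.95)

  r_pop <- -0.33
  for (seed in 1:3) {
    set.seed(seed)
    x <- stats::rnorm(257)
    y <- r_pop * x + sqrt(1 - r_pop^2) * stats::rnorm(257)
    got <- correlate_error_source(y, x)
    expect_lt(abs(got$r - r_pop), 0.15)
    expect_lt(got$p, 0.05)
  }
  expect_error(correlate_error_source(rep(1, 10), 1:10), "zero variance")
  expect_error(correlate_error_source(1:5, 1:4), "length")
})

test_that("agreement_table summarizes every algorithm x event cell", {
  set.seed(84)
  df <- expand.grid(algorithm = c("PVV", "RFA"), event = c("IC", "TO"),
                    i = 1:20, stringsAsFactors = FALSE)
  df$offset_ms <- stats::rnorm(nrow(df))
  tab <- agreement_table(df)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("median_ms", "iqr_ms", "loa_low_ms", "n_outliers")
                  %in% names(tab)))
  expect_equal(tab$n, rep(20, 4))
})

test_that("bland_altman_plot returns a ggplot with the LoA layers", {
  set.seed(85)
  ref <- stats::runif(30, 0.9, 1.1)
  det <- ref - stats::rnorm(30, 0.005, 0.01)
  p <- bland_altman_plot(ref, det, title = "demo")
  expect_s3_class(p, "ggplot")
  expect_gte(length(p$layers), 3)
})
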