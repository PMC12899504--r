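test_that("select_longest picks maximal duration with earliest-IC tie-break", {
  ev <- function(ic, dur) contact_event(ic, ic + dur, rate = 1000)
  picked <- select_longest(list(ev(100, 200), ev(400, 450), ev(900, 300)))
  expect_equal(picked$duration, 0.450)
  single <- ev(5, 100)
  expect_identical(select_longest(list(single)), single)
  tie <- select_longest(list(ev(600, 250), ev(200, 250)))
  expect_equal(tie$ic_time, 0.2)
  expect_error(select_longest(list()), "empty")
})

test_that("detect_pvv recovers a planted stance pattern", {
  sig <- pvv_template(ic_t = 1.0, to_t = 1.45)
  res <- detect_pvv(sig)
  expect_false(res$failed)
  expect_lte(abs(res$contact$ic_index - sample_index(1.0)), 1)
  expect_lte(abs(res$contact$to_index - sample_index(1.45)), 1)
  # verify against literal enumeration of (minimum, maximum) pairs
  filt <- lowpass(sig)
  expect_same_pairs(candidate_pairs(res),
                    oracle_pvv_pairs(filt$values, 60, detector_params()))
})

test_that("detect_pvv fails on a monotone signal and prefers longer stances", {
  mono <- uniform_signal(seq(-1, 1, length.out = 200), 60)
  expect_true(detect_pvv(mono)$failed)
  expect_null(detect_pvv(mono)$contact)

  two <- pvv_template(ic_t = 1.2, to_t = 1.65,
                      extra = function(t)
                        -0.5 * gaussian_at(t, 0.55, 0.03) +
                        0.4 * gaussian_at(t, 0.75, 0.025))
  res <- detect_pvv(two)
  expect_false(res$failed)
  expect_length(res$candidates, 2)
  expect_lte(abs(res$contact$ic_index - sample_index(1.2)), 1)
  durs <- vapply(res$candidates, function(e) e$duration, 1.0)
  expect_equal(res$contact$duration, max(durs))
})

test_that("detect_rfa recovers the twin-peak pattern and applies thresholds", {
  foot <- rfa_template(ic_t = 1.0, to_t = 1.45, h_ic = 95, h_to = 80)
  res <- detect_rfa(foot)
  expect_false(res$failed)
  expect_lte(abs(res$contact$ic_index - sample_index(1.0)), 1)
  expect_lte(abs(res$contact$to_index - sample_index(1.45)), 1)
  expect_gt(res$rfa_at_ic, 60)
  filt <- lowpass(resultant(foot))
  expect_same_pairs(candidate_pairs(res),
                    oracle_rfa_pairs(filt$values, detector_params()))

  # all peaks below the 30 m/s^2 toe-off threshold: failure, not an error
  low <- rfa_template(h_ic = 20, h_to = 25)
  expect_true(detect_rfa(low)$failed)

  # an extra shorter step: the longest pair is selected
  dist <- rfa_template(ic_t = 1.0, to_t = 1.45,
                       extra = function(t)
                         60 * gaussian_at(t, 0.55, 0.015) +
                         55 * gaussian_at(t, 0.78, 0.015))
  resd <- detect_rfa(dist)
  expect_lte(abs(resd$contact$ic_index - sample_index(1.0)), 1)
  durs <- vapply(resd$candidates, function(e) e$duration, 1.0)
  expect_equal(resd$contact$duration, max(durs))
})

test_that("candidate sets equal brute-force enumeration on random signals", {
  set.seed(41)
  params <- detector_params()
  for (rep in 1:25) {
    n <- sample(80:400, 1)
    s <- rand_smooth(n, scale = 2)
    got <- candidate_pairs(detect_pvv(s, params))
    expect_same_pairs(got, oracle_pvv_pairs(lowpass(s)$values, 60, params))
    tri <- rand_triaxial(n, scale = 70)
    got <- candidate_pairs(detect_rfa(tri, params))
    expect_same_pairs(got,
                      oracle_rfa_pairs(lowpass(resultant(tri))$values, params))
  }
})

test_that("every detected contact has toe-off strictly after initial contact", {
  set.seed(43)
  for (rep in 1:30) {
    s <- rand_smooth(sample(60:300, 1), scale = 2)
    res <- detect_pvv(s)
    for (e in res$candidates) expect_gt(e$to_time, e$ic_time)
    tri <- rand_triaxial(sample(60:300, 1), scale = 70)
    res <- detect_rfa(tri)
    for (e in res$candidates) expect_gt(e$to_time, e$ic_time)
  }
})

test_that("hybrid follows its gating logic on constructed fixtures", {
  p <- detector_params()

  fx <- hybrid_fixture("rfa_both")
  h <- detect_hybrid(fx$pelvis, fx$foot, p)
  r <- detect_rfa(fx$foot, p)
  expect_identical(h$provenance, "RFA_BOTH")
  expect_gte(h$rfa_at_ic, p$hybrid_ic_gate)
  expect_identical(h$contact$ic_index, r$contact$ic_index)
  expect_identical(h$contact$to_index, r$contact$to_index)

  fx <- hybrid_fixture("pvv_ic_rfa_to")
  h <- detect_hybrid(fx$pelvis, fx$foot, p)
  r <- detect_rfa(fx$foot, p)
  pv <- detect_pvv(fx$pelvis, p)
  expect_identical(h$provenance, "PVV_IC_RFA_TO")
  expect_lt(h$rfa_at_ic, p$hybrid_ic_gate)
  expect_identical(h$contact$ic_index, pv$contact$ic_index)
  expect_identical(h$contact$to_index, r$contact$to_index)

  fx <- hybrid_fixture("pvv_both")
  h <- detect_hybrid(fx$pelvis, fx$foot, p)
  pv <- detect_pvv(fx$pelvis, p)
  expect_true(detect_rfa(fx$foot, p)$failed)
  expect_identical(h$provenance, "PVV_BOTH")
  expect_identical(h$contact$ic_index, pv$contact$ic_index)
  expect_identical(h$contact$to_index, pv$contact$to_index)

  fx <- hybrid_fixture("double_failure")
  h <- detect_hybrid(fx$pelvis, fx$foot, p)
  expect_true(h$failed)
  expect_null(h$contact)
})

test_that("detection is deterministic and the gate is monotone", {
  spec <- cohort_spec(n_participants = 6, trials_per_participant = 4,
                      low_acc_fraction = 0.3, seed = 51)
  cohort <- generate_cohort(spec)
  n_subst <- vapply(c(20, 60, 100, 150), function(gate) {
    p <- detector_params(hybrid_ic_gate = gate)
    sum(vapply(cohort, function(x)
      identical(detect_hybrid(x$trial$pelvis_vz, x$trial$foot_acc, p)$provenance,
                "PVV_IC_RFA_TO"), TRUE))
  }, 1.0)
  expect_true(all(diff(n_subst) >= 0))

  x <- cohort[[1]]$trial
  r1 <- detect_hybrid(x$pelvis_vz, x$foot_acc)
  r2 <- detect_hybrid(x$pelvis_vz, x$foot_acc)
  expect_identical(r1, r2)
})
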