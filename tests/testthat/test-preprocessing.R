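test_that("lowpass has unit DC gain and the analytic Butterworth response", {
  const <- uniform_signal(rep(5, 200), 60)
  expect_equal(lowpass(const)$values, rep(5, 200), tolerance = 1e-9)

  fit_amplitude <- function(sig, f) {
    t <- signal_times(sig)
    keep <- seq(30, length(t) - 30)            # avoid edge transients
    co <- stats::coef(stats::lm(sig$values[keep] ~ sin(2 * pi * f * t[keep]) +
                                  cos(2 * pi * f * t[keep])))
    sqrt(co[2]^2 + co[3]^2)
  }
  t <- (0:599) / 60
  # passband: 1 Hz tone preserved within 1%
  s1 <- uniform_signal(sin(2 * pi * 1 * t), 60)
  expect_lt(abs(fit_amplitude(lowpass(s1), 1) - 1), 0.01)
  # stopband: 25 Hz tone attenuated at least to the analytic gain (applied
  # twice by forward-backward filtering) plus 5%
  s25 <- uniform_signal(sin(2 * pi * 25 * t), 60)
  gain <- 1 / (1 + (25 / 20)^(2 * 3))          # |H|^2 for order 3
  expect_lt(fit_amplitude(lowpass(s25), 25), gain + 0.05)
})

test_that("lowpass is linear and rejects bad inputs", {
  set.seed(11)
  x <- rand_smooth(120)
  y <- rand_smooth(120)
  lhs <- lowpass(uniform_signal(2 * x$values + 3 * y$values, 60))$values
  rhs <- 2 * lowpass(x)$values + 3 * lowpass(y)$values
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  expect_error(lowpass(uniform_signal(1:100, 60), filter_spec(30, 3)), "Nyquist")
  expect_error(lowpass(uniform_signal(1:8, 60), filter_spec(20, 3)), "short")
  expect_error(filter_spec(-1, 3), "cutoff")
  expect_error(filter_spec(20, 0), "order")
})

test_that("zero-phase filtering introduces no group delay on a symmetric pulse", {
  for (width in c(0.02, 0.05, 0.1)) {
    t <- (0:299) / 60
    pulse <- uniform_signal(exp(-((t - 2.5)^2) / (2 * width^2)), 60)
    raw_peak <- which.max(pulse$values)
    filt_peak <- which.max(lowpass(pulse)$values)
    expect_lte(abs(filt_peak - raw_peak), 1)
  }
})

test_that("resultant equals the per-sample Euclidean norm", {
  tri <- triaxial_signal(uniform_signal(3, 60), uniform_signal(4, 60),
                         uniform_signal(0, 60))
  expect_equal(resultant(tri)$values, 5)
  zero <- uniform_signal(0, 60)
  expect_equal(resultant(triaxial_signal(zero, zero, zero))$values, 0)
  set.seed(5)
  x <- stats::rnorm(100); y <- stats::rnorm(100); z <- stats::rnorm(100)
  tri <- triaxial_signal(uniform_signal(x, 60), uniform_signal(y, 60),
                         uniform_signal(z, 60))
  brute <- vapply(seq_len(100),
                  function(i) sqrt(x[i]^2 + y[i]^2 + z[i]^2), 1.0)
  expect_lt(max(abs(resultant(tri)$values - brute)), 1e-12)
})

test_that("derivative is a central difference in SI units", {
  ramp <- uniform_signal(2 * (0:99) / 60, 60)
  d <- derivative(ramp)$values
  expect_equal(d, rep(2, 100), tolerance = 1e-9)
  expect_equal(derivative(uniform_signal(rep(7, 50), 60))$values, rep(0, 50))
  t <- (0:299) / 60
  sine <- uniform_signal(sin(2 * pi * t), 60)
  d <- derivative(sine)$values
  interior <- 2:299
  # central difference error is O(h^2): bound (2*pi)^3 h^2 / 6
  bound <- (2 * pi)^3 * (1 / 60)^2 / 6
  expect_lt(max(abs(d[interior] - 2 * pi * cos(2 * pi * t[interior]))),
            bound * 1.01)
  expect_error(derivative(uniform_signal(1:2, 60)), "3 samples")
})

test_that("downsample_to preserves DC, low-frequency amplitude and duration", {
  const <- uniform_signal(rep(700, 1000), 1000, units = "N")
  down <- downsample_to(const, 60)
  expect_equal(down$rate, 60)
  expect_equal(down$t0, const$t0)
  expect_equal(length(down$values), 60)
  interior <- 10:50
  expect_lt(max(abs(down$values[interior] - 700)), 1e-6)

  t <- (0:999) / 1000
  s5 <- uniform_signal(sin(2 * pi * 5 * t), 1000)
  d5 <- downsample_to(s5, 60)
  td <- signal_times(d5)[10:50]
  expect_lt(max(abs(d5$values[10:50] - sin(2 * pi * 5 * td))), 0.02)
  expect_error(downsample_to(uniform_signal(1:100, 60), 1000), "exceeds")
})

test_that("map_time_to_index rounds to the nearest sample, half up", {
  s <- uniform_signal(rep(0, 120), 60)
  expect_identical(map_time_to_index(0.5, s), 30L)
  expect_identical(map_time_to_index(s$t0, s), 0L)
  expect_identical(map_time_to_index(1.5 / 60, s), 2L)   # exact midpoint: up
  expect_error(map_time_to_index(3.0, s), "outside")
  expect_error(map_time_to_index(-0.1, s), "outside")
})

test_that("down-sampling commutes with event-time mapping", {
  set.seed(21)
  for (rep in 1:20) {
    t_event <- stats::runif(1, 0.2, 0.8)
    s <- uniform_signal(stats::rnorm(1000), 1000)
    down <- downsample_to(s, 60)
    idx <- map_time_to_index(t_event, down)
    expect_lte(abs(down$t0 + idx / 60 - t_event), 0.5 / 60 + 1e-9)
  }
})
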