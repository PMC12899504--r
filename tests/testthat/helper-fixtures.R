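# Constructed waveform fixtures with known event samples (all at 60 Hz).

gaussian_at <- function(t, center, sigma) exp(-((t - center)^2) / (2 * sigma^2))

# pelvis-velocity stance pattern: descent into a trough at `ic_t`, rise to a
# peak at `to_t`, steep drop afterwards
pvv_template <- function(ic_t = 1.0, to_t = 1.45, n = 150, rate = 60,
                         depth = 1.0, push = 0.7,
                         extra = function(t) 0) {
  t <- (0:(n - 1)) / rate
  v <- -depth * gaussian_at(t, ic_t, 0.05) + push * gaussian_at(t, to_t, 0.04) -
    1.2 * stats::plogis((t - (to_t + 0.10)) / 0.03) + extra(t)
  uniform_signal(v, rate = rate, units = "m/s")
}

# resultant-foot-acceleration twin-peak pattern
rfa_template <- function(ic_t = 1.0, to_t = 1.45, n = 150, rate = 60,
                         h_ic = 95, h_to = 80, baseline = 3,
                         extra = function(t) 0) {
  t <- (0:(n - 1)) / rate
  v <- baseline + h_ic * gaussian_at(t, ic_t, 0.02) +
    h_to * gaussian_at(t, to_t, 0.02) + extra(t)
  u <- c(0.6, 0.64, 0.48)
  u <- u / sqrt(sum(u^2))
  triaxial_signal(uniform_signal(v * u[1], rate),
                  uniform_signal(v * u[2], rate),
                  uniform_signal(v * u[3], rate))
}

# fixtures driving each hybrid provenance branch
hybrid_fixture <- function(branch) {
  switch(
    branch,
    rfa_both = list(pelvis = pvv_template(), foot = rfa_template(h_ic = 95)),
    pvv_ic_rfa_to = list(pelvis = pvv_template(), foot = rfa_template(h_ic = 40)),
    pvv_both = list(pelvis = pvv_template(),
                    # all peaks below the 30 m/s^2 toe-off threshold
                    foot = rfa_template(h_ic = 20, h_to = 25)),
    double_failure = list(
      pelvis = uniform_signal(seq(0, 1, length.out = 150), 60),
      foot = {
        flat <- uniform_signal(seq(1, 2, length.out = 150), 60)
        triaxial_signal(flat, flat, flat)
      })
  )
}

sample_index <- function(t, rate = 60) as.integer(round(t * rate))
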