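# Independent brute-force oracles.  These re-derive every quantity with
# straightforward (often O(n^2)) code kept deliberately separate from the
# package's implementations.

# strict local extrema with prominence, computed by whole-vector scans
oracle_extrema <- function(v, min_prom = 0) {
  n <- length(v)
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n], FALSE)
  prom_of <- function(i, v) {
    higher_left <- which(v[seq_len(i - 1)] > v[i])
    lo_l <- if (length(higher_left)) min(v[(max(higher_left) + 1):(i - 1)])
            else min(v[seq_len(i - 1)])
    higher_right <- which(v[(i + 1):n] > v[i]) + i
    lo_r <- if (length(higher_right)) min(v[(i + 1):(min(higher_right) - 1)])
            else min(v[(i + 1):n])
    v[i] - max(lo_l, lo_r)
  }
  maxima <- which(is_max)
  maxima <- maxima[vapply(maxima, prom_of, 1.0, v = v) >= min_prom]
  w <- -v
  is_min <- c(FALSE, w[2:(n - 1)] > w[1:(n - 2)] & w[2:(n - 1)] > w[3:n], FALSE)
  minima <- which(is_min)
  minima <- minima[vapply(minima, prom_of, 1.0, v = w) >= min_prom]
  list(maxima = maxima, minima = minima)
}

# central-difference derivative, re-derived sample by sample
oracle_derivative <- function(v, rate) {
  n <- length(v)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- if (i == 1) (v[2] - v[1]) * rate
            else if (i == n) (v[n] - v[n - 1]) * rate
            else (v[i + 1] - v[i - 1]) * rate / 2
  }
  d
}

# pelvis-velocity pattern search by literal enumeration of (minimum, maximum)
# pairs under the three stance-pattern conditions; v must already be the
# filtered signal
oracle_pvv_pairs <- function(v, rate, params) {
  ext <- oracle_extrema(v, params$min_prominence_frac * (max(v) - min(v)))
  d <- oracle_derivative(v, rate)
  n <- length(v)
  pairs <- list()
  for (ic in ext$minima) {
    for (to in ext$maxima) {
      if (to <= ic) next                       # condition 1: TO after IC
      after <- ext$maxima[ext$maxima > to]
      w_end <- if (length(after)) min(after) - 1L else n
      descent <- Filter(function(s) d[s] < params$pvv_descent_threshold,
                        seq_len(n)[seq_len(n) > to & seq_len(n) <= w_end])
      if (length(descent) == 0) next           # condition 2: descent after TO
      onset <- min(descent)
      between <- ext$maxima[ext$maxima > ic & ext$maxima <= onset]
      if (max(v[between]) > v[to]) next        # condition 3: TO is highest
      pairs[[length(pairs) + 1L]] <- c(ic = ic, to = to)
      break                                    # first acceptable TO per IC
    }
  }
  pairs
}

# foot-acceleration twin-peak search by literal enumeration; v is the
# filtered resultant
oracle_rfa_pairs <- function(v, params) {
  ext <- oracle_extrema(v, params$min_prominence_frac * (max(v) - min(v)))
  pairs <- list()
  for (ic in ext$maxima) {
    for (to in ext$maxima) {
      if (to <= ic) next
      if (v[to] < params$rfa_to_threshold) next
      valley <- min(v[seq(ic + 1L, to - 1L)])
      if (valley >= params$u_shape_frac * min(v[ic], v[to])) next
      pairs[[length(pairs) + 1L]] <- c(ic = ic, to = to)
      break
    }
  }
  pairs
}

# force-plate rule re-derived with a run-length scan
oracle_grf_windows <- function(v, rate, threshold, min_contact_s) {
  above <- v > threshold
  below <- v < threshold
  wins <- list()
  i <- 1L
  n <- length(v)
  while (i <= n) {
    if (above[i]) {
      ends <- which(below & seq_len(n) > i)
      if (length(ends) == 0) break             # truncated
      j <- min(ends)
      if ((j - i) / rate >= min_contact_s)
        wins[[length(wins) + 1L]] <- c(ic = i, to = j)
      i <- j
    } else i <- i + 1L
  }
  wins
}

# sort-based quantiles: linear interpolation between order statistics
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[pmin(lo + 2, length(s))] - s[lo + 1])
}

candidate_pairs <- function(result) {
  lapply(result$candidates,
         function(e) c(ic = e$ic_index + 1L, to = e$to_index + 1L))
}

expect_same_pairs <- function(got, want) {
  fmt <- function(p) paste(vapply(p, function(x) paste(x, collapse = "-"), ""),
                           collapse = ";")
  expect_identical(fmt(got), fmt(want))
}

# smooth random test signals with several extrema
rand_smooth <- function(n, rate = 60, scale = 1) {
  raw <- cumsum(stats::rnorm(n + 20))
  sm <- stats::filter(raw, rep(1 / 7, 7), sides = 2)
  sm <- sm[!is.na(sm)][seq_len(n)]
  uniform_signal(scale * (sm - mean(sm)) / max(abs(sm - mean(sm)) + 1e-12),
                 rate = rate)
}

rand_triaxial <- function(n, rate = 60, scale = 60) {
  base <- abs(rand_smooth(n, rate, scale)$values) + 2
  u <- abs(stats::rnorm(3)); u <- u / sqrt(sum(u^2))
  triaxial_signal(uniform_signal(base * u[1], rate),
                  uniform_signal(base * u[2], rate),
                  uniform_signal(base * u[3], rate))
}
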