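#' Detector parameters
#'
#' Every threshold of the detection chain in one record, at the values the
#' method was developed with: 20 Hz / 3rd-order zero-phase low-pass
#' smoothing; a pelvis-velocity descent threshold of -0.1 m/s^2 on the
#' derivative of the filtered signal; a 30 m/s^2 minimum height for an
#' eligible toe-off peak in the resultant foot acceleration; a 60 m/s^2 gate
#' on the foot acceleration at initial contact below which the hybrid
#' detector swaps in the pelvis-derived initial contact; and a prominence
#' floor (fraction of the filtered signal's range) separating genuine local
#' extrema from noise-born micro-peaks.
#'
#' @param filter a [filter_spec()] applied to both detector signals.
#' @param pvv_descent_threshold m/s^2; derivative level defining the
#'   post-toe-off descent of the pelvis vertical velocity (< 0).
#' @param rfa_to_threshold m/s^2; minimum resultant-foot-acceleration peak
#'   height for an eligible toe-off (> 0).
#' @param hybrid_ic_gate m/s^2; foot-acceleration-at-IC level below which
#'   the hybrid replaces the RFA initial contact with the PVV one (> 0).
#' @param min_prominence_frac candidate peaks must have topographic
#'   prominence of at least this fraction of the filtered signal's range
#'   (in `[0, 1)`).
#' @param u_shape_frac the inter-peak valley must drop below this fraction
#'   of the lower of the two peak heights for the pair to count as the
#'   "U shape" stance pattern of the foot-acceleration signal.
#' @return an object of class `detector_params`.
#' @export
detector_params <- function(filter = filter_spec(20, 3, TRUE),
                            pvv_descent_threshold = -0.1,
                            rfa_to_threshold = 30,
                            hybrid_ic_gate = 60,
                            min_prominence_frac = 0.05,
                            u_shape_frac = 0.5) {
  stopifnot(inherits(filter, "filter_spec"))
  if (pvv_descent_threshold >= 0)
    stop("detector_params: 'pvv_descent_threshold' must be negative", call. = FALSE)
  if (rfa_to_threshold <= 0)
    stop("detector_params: 'rfa_to_threshold' must be positive", call. = FALSE)
  if (hybrid_ic_gate <= 0)
    stop("detector_params: 'hybrid_ic_gate' must be positive", call. = FALSE)
  if (min_prominence_frac < 0 || min_prominence_frac >= 1)
    stop("detector_params: 'min_prominence_frac' must be in [0, 1)", call. = FALSE)
  if (u_shape_frac <= 0 || u_shape_frac >= 1)
    stop("detector_params: 'u_shape_frac' must be in (0, 1)", call. = FALSE)
  structure(list(filter = filter,
                 pvv_descent_threshold = as.numeric(pvv_descent_threshold),
                 rfa_to_threshold = as.numeric(rfa_to_threshold),
                 hybrid_ic_gate = as.numeric(hybrid_ic_gate),
                 min_prominence_frac = as.numeric(min_prominence_frac),
                 u_shape_frac = as.numeric(u_shape_frac)),
            class = "detector_params")
}

#' Local extrema with topographic prominence
#'
#' A local maximum is a sample strictly greater than both neighbours
#' (plateaus produce no extremum); minima are defined symmetrically.  The
#' prominence of a maximum is its height above the higher of the two lowest
#' points separating it from taller terrain on either side (signal ends act
#' as walls); extrema with prominence below `min_prominence` are dropped.
#'
#' @param values numeric vector.
#' @param min_prominence minimum prominence to keep an extremum (>= 0).
#' @return a list with integer vectors `maxima` and `minima` of 1-based
#'   sample positions, each with a `prominence` attribute.
#' @export
local_extrema <- function(values, min_prominence = 0) {
  v <- as.numeric(values)
  pick <- function(v) {
    n <- length(v)
    if (n < 3L) return(integer(0))
    idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
    if (length(idx) == 0L) return(idx)
    prom <- vapply(idx, function(i) {
      left <- v[i]
      j <- i - 1L
      lo <- v[i]
      while (j >= 1L && v[j] <= v[i]) { lo <- min(lo, v[j]); j <- j - 1L }
      left <- lo
      j <- i + 1L
      lo <- v[i]
      while (j <= n && v[j] <= v[i]) { lo <- min(lo, v[j]); j <- j + 1L }
      v[i] - max(left, lo)
    }, 1.0)
    keep <- prom >= min_prominence
    out <- idx[keep]
    attr(out, "prominence") <- prom[keep]
    out
  }
  maxima <- pick(v)
  minima <- pick(-v)
  if (length(minima)) attr(minima, "prominence") <- attr(minima, "prominence")
  list(maxima = maxima, minima = minima)
}

detection_result <- function(algorithm, contact, candidates,
                             rfa_at_ic = NA_real_, provenance = NA_character_) {
  structure(
    list(algorithm = algorithm,
         contact = contact,
         failed = is.null(contact),
         candidates = candidates,
         rfa_at_ic = rfa_at_ic,
         provenance = provenance),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s: %s", x$algorithm,
              if (x$failed) "no valid foot contact found\n"
              else sprintf("IC %.4f s -> TO %.4f s (%.1f ms), %d candidate(s)%s\n",
                           x$contact$ic_time, x$contact$to_time,
                           1000 * x$contact$duration, length(x$candidates),
                           if (is.na(x$provenance)) ""
                           else paste0(", provenance ", x$provenance))))
  invisible(x)
}

#' Longest-duration contact selection
#'
#' Among all foot contacts a detector finds in a trial, the one with the
#' longest duration is taken as the contact of interest (the planted
#' change-of-direction or deceleration step); ties go to the earlier
#' initial contact.
#'
#' @param candidates non-empty list of [contact_event()]s.
#' @return the selected [contact_event()].
#' @export
select_longest <- function(candidates) {
  if (length(candidates) == 0L)
    stop("select_longest: empty candidate list", call. = FALSE)
  durs <- vapply(candidates, function(e) e$duration, 1.0)
  ics <- vapply(candidates, function(e) e$ic_time, 1.0)
  candidates[[order(-durs, ics)[1L]]]
}

#' Pelvis-vertical-velocity detector
#'
#' Searches the low-pass-filtered pelvis vertical velocity for the stance
#' pattern: a local minimum (candidate initial contact) followed by a local
#' maximum (candidate toe-off).  For each candidate IC, candidate TOs after
#' it are examined in order and the first one accepted for which
#' (a) a descent follows -- the derivative of the filtered signal drops
#' below `pvv_descent_threshold` at some sample after the TO and before the
#' next candidate TO (or the signal end), and
#' (b) the TO is the highest candidate maximum between the IC and that
#' descent onset.
#' All accepted pairs become candidate contacts; the longest is returned.
#' Failure (no acceptable pair) is encoded in the result, not raised.
#'
#' @param pelvis_vz pelvis vertical velocity, a [uniform_signal()] in m/s.
#' @param params a [detector_params()].
#' @return a `detection_result` with `algorithm = "PVV"`.
#' @export
detect_pvv <- function(pelvis_vz, params = detector_params()) {
  stopifnot(inherits(pelvis_vz, "uniform_signal"),
            inherits(params, "detector_params"))
  filt <- lowpass(pelvis_vz, params$filter)
  v <- filt$values
  n <- length(v)
  d <- derivative(filt)$values
  ext <- local_extrema(v, params$min_prominence_frac * (max(v) - min(v)))
  ics <- ext$minima
  tos <- ext$maxima
  cands <- list()
  for (ic in ics) {
    for (to in tos[tos > ic]) {
      nxt <- tos[tos > to]
      w_end <- if (length(nxt)) nxt[1L] - 1L else n
      if (to + 1L > w_end) next
      win <- (to + 1L):w_end
      below <- which(d[win] < params$pvv_descent_threshold)
      if (length(below) == 0L) next
      onset <- to + below[1L]
      comp <- tos[tos > ic & tos <= onset]
      if (any(v[comp] > v[to])) next
      cands[[length(cands) + 1L]] <-
        contact_event(ic - 1L, to - 1L, rate = filt$rate, t0 = filt$t0)
      break
    }
  }
  detection_result("PVV",
                   contact = if (length(cands)) select_longest(cands) else NULL,
                   candidates = cands)
}

#' Resultant-foot-acceleration detector
#'
#' Searches the low-pass-filtered resultant foot acceleration for the
#' twin-peak stance pattern: a peak at initial contact and a later peak at
#' toe-off with a pronounced "U shape" between them.  Candidate peaks are
#' local maxima passing the prominence floor.  For each candidate IC peak,
#' later candidate peaks are scanned in order; peaks below `rfa_to_threshold`
#' are discarded, and the first remaining peak whose inter-peak valley drops
#' below `u_shape_frac` times the lower of the two peak heights is accepted
#' as the toe-off.  All accepted pairs become candidate contacts; the
#' longest is returned.  `rfa_at_ic` is the filtered signal value at the
#' selected contact's initial contact, used by the hybrid gate.
#'
#' @param foot_acc foot linear acceleration, a [triaxial_signal()] in m/s^2.
#' @param params a [detector_params()].
#' @return a `detection_result` with `algorithm = "RFA"`.
#' @export
detect_rfa <- function(foot_acc, params = detector_params()) {
  stopifnot(inherits(foot_acc, "triaxial_signal"),
            inherits(params, "detector_params"))
  filt <- lowpass(resultant(foot_acc), params$filter)
  v <- filt$values
  ext <- local_extrema(v, params$min_prominence_frac * (max(v) - min(v)))
  peaks <- ext$maxima
  cands <- list()
  for (k in seq_along(peaks)) {
    ic <- peaks[k]
    later <- peaks[peaks > ic]
    for (to in later) {
      if (v[to] < params$rfa_to_threshold) next
      valley <- min(v[(ic + 1L):(to - 1L)])
      if (valley >= params$u_shape_frac * min(v[ic], v[to])) next
      cands[[length(cands) + 1L]] <-
        contact_event(ic - 1L, to - 1L, rate = filt$rate, t0 = filt$t0)
      break
    }
  }
  contact <- if (length(cands)) select_longest(cands) else NULL
  detection_result("RFA", contact = contact, candidates = cands,
                   rfa_at_ic = if (is.null(contact)) NA_real_
                               else v[contact$ic_index + 1L])
}

#' Hybrid detector
#'
#' Combines the two single-signal detectors.  The resultant foot
#' acceleration is the primary source for both events; the pelvis vertical
#' velocity serves as fallback and as a substitute for initial contact when
#' the landing is too soft for a sharp foot-acceleration spike:
#'
#' * RFA succeeded and its acceleration at IC is at or above
#'   `hybrid_ic_gate`: return the RFA contact (`provenance = "RFA_BOTH"`).
#' * RFA succeeded but the acceleration at IC falls below the gate: if PVV
#'   also succeeded and its IC precedes the RFA toe-off, return the PVV
#'   initial contact with the RFA toe-off (`"PVV_IC_RFA_TO"`); if the
#'   substitution is impossible (PVV failed or would invert the window),
#'   keep the RFA contact.
#' * RFA failed: return the PVV result (`"PVV_BOTH"`).
#' * Both failed: a failed result.
#'
#' @param pelvis_vz pelvis vertical velocity, a [uniform_signal()] in m/s.
#' @param foot_acc foot linear acceleration, a [triaxial_signal()] in m/s^2.
#' @param params a [detector_params()].
#' @return a `detection_result` with `algorithm = "HYBRID"` and a
#'   `provenance` field naming which detector produced each event.
#' @export
detect_hybrid <- function(pelvis_vz, foot_acc, params = detector_params()) {
  rfa <- detect_rfa(foot_acc, params)
  if (rfa$failed) {
    pvv <- detect_pvv(pelvis_vz, params)
    if (pvv$failed)
      return(detection_result("HYBRID", contact = NULL, candidates = list()))
    return(detection_result("HYBRID", contact = pvv$contact,
                            candidates = pvv$candidates,
                            provenance = "PVV_BOTH"))
  }
  if (rfa$rfa_at_ic >= params$hybrid_ic_gate)
    return(detection_result("HYBRID", contact = rfa$contact,
                            candidates = rfa$candidates,
                            rfa_at_ic = rfa$rfa_at_ic,
                            provenance = "RFA_BOTH"))
  pvv <- detect_pvv(pelvis_vz, params)
  if (!pvv$failed && pvv$contact$ic_time < rfa$contact$to_time) {
    combined <- contact_event(pvv$contact$ic_index, rfa$contact$to_index,
                              rate = rfa$contact$rate, t0 = rfa$contact$t0)
    return(detection_result("HYBRID", contact = combined,
                            candidates = list(combined),
                            rfa_at_ic = rfa$rfa_at_ic,
                            provenance = "PVV_IC_RFA_TO"))
  }
  detection_result("HYBRID", contact = rfa$contact,
                   candidates = rfa$candidates,
                   rfa_at_ic = rfa$rfa_at_ic,
                   provenance = "RFA_BOTH")
}
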