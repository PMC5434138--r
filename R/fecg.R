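# Fetal ECG: R-peak detection (Pan-Tompkins style), Q-onset estimation,
# and the bSQI two-detector agreement score.

#' Detect fetal R peaks
#'
#' Pan-Tompkins style chain: 5--45 Hz band-pass, derivative, squaring,
#' moving-window integration, then adaptive thresholding with a 200 ms
#' refractory period.  Peak times are refined to the local maximum of the
#' band-passed signal's absolute value.
#'
#' @param fecg numeric vector, extracted fetal ECG.
#' @param fs sampling rate in Hz (>= 250).
#' @return tibble with columns `time` (s, strictly increasing) and `rr`
#'   (ms to the previous accepted peak; `NA` for the first).  RR intervals
#'   outside 250--1100 ms (FHR ~55--240 bpm) cause the offending peak to be
#'   dropped.  A flat signal yields zero rows.
#' @export
detect_r_peaks <- function(fecg, fs) {
  if (fs < 250) stop("fs must be >= 250 Hz", call. = FALSE)
  if (length(fecg) < 2 * fs) stop("signal shorter than 2 s", call. = FALSE)
  if (sd(fecg) == 0) {
    return(tibble::tibble(time = numeric(0), rr = numeric(0)))
  }
  bp <- bandpass_zero_phase(fecg, fs, 5, 45)
  integ_w <- max(3L, round(0.080 * fs))
  feat <- stats::filter(c(0, diff(bp))^2, rep(1 / integ_w, integ_w), sides = 2)
  feat[is.na(feat)] <- 0
  feat <- as.numeric(feat)

  refractory <- round(0.2 * fs)
  # adaptive threshold: running signal-level estimate, initialised from the
  # first 2 s
  thr <- 0.25 * max(feat[seq_len(2 * fs)])
  sig_level <- max(feat[seq_len(2 * fs)])
  cand <- find_peaks(feat, min_prominence = 0, min_separation = refractory)
  accepted <- integer(0)
  for (i in cand) {
    if (feat[i] >= thr) {
      if (length(accepted) && (i - accepted[length(accepted)]) < refractory) next
      accepted <- c(accepted, i)
      sig_level <- 0.875 * sig_level + 0.125 * feat[i]
      thr <- 0.25 * sig_level
    }
  }
  if (!length(accepted)) {
    return(tibble::tibble(time = numeric(0), rr = numeric(0)))
  }
  # refine to the |band-passed| local maximum within +-40 ms
  half <- round(0.040 * fs)
  refined <- vapply(accepted, function(i) {
    lo <- max(1L, i - half); hi <- min(length(bp), i + half)
    as.integer(lo + which.max(abs(bp[lo:hi])) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  times <- (refined - 1) / fs
  # physiological RR gating
  keep <- rep(TRUE, length(times))
  last <- 1L
  for (j in seq_along(times)[-1]) {
    rr <- (times[j] - times[last]) * 1000
    if (rr < 250) keep[j] <- FALSE else last <- j
  }
  times <- times[keep]
  tibble::tibble(time = times, rr = c(NA_real_, diff(times) * 1000))
}

#' Estimate per-beat Q-wave onsets
#'
#' Within a 60 ms window before each R peak, the deflection start is first
#' located as the last time the low-passed derivative magnitude stays below
#' 5% of the R upstroke slope, then refined by the tangent method: the
#' tangent to the initial Q ramp is extrapolated back to the local baseline,
#' which cancels the symmetric smear of the zero-phase filter.  When no
#' crossing is found the onset falls back to a fixed 20 ms before R and the
#' beat is flagged.
#'
#' @param fecg numeric vector.
#' @param r_peaks tibble from [detect_r_peaks()] (column `time`).
#' @param fs sampling rate in Hz.
#' @return tibble: `beat_index`, `r_time` (s), `q_time` (s, < `r_time`),
#'   `q_offset_ms` (R minus Q, positive), `fallback` (logical).
#' @export
estimate_q_onset <- function(fecg, r_peaks, fs) {
  if (!nrow(r_peaks)) stop("r_peaks is empty", call. = FALSE)
  smooth <- lowpass_zero_phase(fecg, fs, min(150, 0.45 * fs), order = 2)
  der <- c(0, diff(smooth))
  win <- round(0.060 * fs)
  sustain <- max(2L, round(0.003 * fs))
  out <- purrr::map_dfr(seq_len(nrow(r_peaks)), function(b) {
    ri <- round(r_peaks$time[b] * fs) + 1L
    lo <- max(1L, ri - win)
    seg <- der[lo:ri]
    upstroke <- max(seg, na.rm = TRUE)
    q_t <- NA_real_
    fallback <- FALSE
    if (is.finite(upstroke) && upstroke > 0) {
      thr <- 0.05 * upstroke
      active <- abs(seg) >= thr
      # first sample from which activity is sustained up to the R upstroke
      run <- rle(active)
      ends <- cumsum(run$lengths)
      starts <- ends - run$lengths + 1L
      cand <- starts[run$values & run$lengths >= sustain]
      if (length(cand)) {
        first_act <- min(cand)
        i_act <- lo + first_act - 1L           # absolute index of first activity
        # tangent refinement: extrapolate the early-ramp slope back to the
        # baseline level estimated from the quiet samples before the onset
        # (the 3 ms next to the crossing are excluded -- the zero-phase
        # filter smears the ramp backwards into them)
        base_lo <- max(1L, i_act - round(0.015 * fs))
        base_hi <- max(base_lo, i_act - 1L - round(0.003 * fs))
        baseline <- mean(smooth[base_lo:base_hi])
        i_tan <- min(ri - 1L, i_act + round(0.002 * fs))
        slope <- der[i_tan] * fs
        if (is.finite(slope) && abs(slope) > 0) {
          t_tan <- (i_tan - 1L) / fs
          q_t <- t_tan - (smooth[i_tan] - baseline) / slope
          # keep the refinement local: never move > 5 ms from the crossing
          if (!is.finite(q_t) || abs(q_t - (i_act - 1L) / fs) > 0.005) {
            q_t <- (i_act - 1L) / fs
          }
        } else {
          q_t <- (i_act - 1L) / fs
        }
      }
    }
    if (is.na(q_t) || q_t >= r_peaks$time[b]) {
      q_t <- r_peaks$time[b] - 0.020
      fallback <- TRUE
    }
    tibble::tibble(
      beat_index = b, r_time = r_peaks$time[b],
      q_time = q_t,
      q_offset_ms = (r_peaks$time[b] - q_t) * 1000,
      fallback = fallback
    )
  })
  out
}

#' bSQI: agreement of two QRS detectors
#'
#' Matches the two detection series greedily (nearest pairs first,
#' one-to-one) within `tol_ms` and scores
#' `N_match / (N_a + N_b - N_match)`, i.e. 0 for disjoint detections and 1
#' for perfect agreement.  Both series empty scores 0.
#'
#' @param det_a,det_b numeric vectors of detection times (s), or tibbles
#'   with a `time` column.
#' @param tol_ms matching tolerance in ms (default 50).
#' @return score in \[0, 1\].
#' @export
bsqi <- function(det_a, det_b, tol_ms = 50) {
  if (tol_ms <= 0) stop("tol_ms must be > 0", call. = FALSE)
  a <- if (is.data.frame(det_a)) det_a$time else as.numeric(det_a)
  b <- if (is.data.frame(det_b)) det_b$time else as.numeric(det_b)
  na <- length(a); nb <- length(b)
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) return(0)
  d <- abs(outer(a, b, "-")) * 1000
  n_m <- 0L
  repeat {
    m <- which.min(d)
    if (!length(m) || d[m] > tol_ms) break
    ij <- arrayInd(m, dim(d))
    n_m <- n_m + 1L
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
    if (!any(is.finite(d))) break
  }
  n_m / (na + nb - n_m)
}

#' Simple amplitude-threshold QRS detector
#'
#' Deliberately less noise-robust second detector used as bSQI's partner:
#' local maxima of the band-passed signal above half of its 99th-percentile
#' amplitude, with a 200 ms refractory separation.
#'
#' @inheritParams detect_r_peaks
#' @return tibble with column `time` (s).
#' @export
detect_r_peaks_simple <- function(fecg, fs) {
  if (sd(fecg) == 0) return(tibble::tibble(time = numeric(0)))
  bp <- bandpass_zero_phase(fecg, fs, 5, 45)
  thr <- 0.5 * quantile(abs(bp), 0.99)
  idx <- find_peaks(abs(bp), min_prominence = thr, min_separation = round(0.2 * fs))
  idx <- idx[abs(bp[idx]) >= thr]
  tibble::tibble(time = (idx - 1) / fs)
}

#' Combined fECG annotation + quality
#'
#' Runs both detectors, computes bSQI, and estimates Q onsets from the
#' primary detections.
#'
#' @param record [fetal_record()] with an fECG channel.
#' @param tol_ms bSQI matching tolerance.
#' @return list: `r_peaks` (tibble), `q_onsets` (tibble), `bsqi` (scalar).
#' @export
annotate_fecg <- function(record, tol_ms = 50) {
  if (is.null(record$fecg)) stop("record has no fECG channel", call. = FALSE)
  rp <- detect_r_peaks(record$fecg, record$fs)
  rp2 <- detect_r_peaks_simple(record$fecg, record$fs)
  score <- bsqi(rp, rp2, tol_ms = tol_ms)
  qs <- if (nrow(rp)) estimate_q_onset(record$fecg, rp, record$fs) else
    tibble::tibble(beat_index = integer(0), r_time = numeric(0),
                   q_time = numeric(0), q_offset_ms = numeric(0), fallback = logical(0))
  vg_log("fecg", record$record_id, n_peaks = nrow(rp), bsqi = round(score, 3))
  list(r_peaks = rp, q_onsets = qs, bsqi = score)
}
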