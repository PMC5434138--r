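# DUS preprocessing: wavelet extraction of the ~200 Hz valve-motion
# component, envelope, cardiac-cycle segmentation, z-normalisation.

# Second-order complex Gaussian wavelet psi(x) = C (4x^2 - 3 + 4ix) e^{-x^2 - ix}.
cgau2 <- function(x) {
  (4 * x^2 - 3 + 4i * x) * exp(-x^2 - 1i * x)
}

# Centre frequency (cycles per unit of x) of the wavelet, located once
# numerically from the FFT magnitude peak of a dense sampling.
cgau2_center_freq <- local({
  fc <- NULL
  function() {
    if (!is.null(fc)) return(fc)
    dx <- 0.01
    x <- seq(-8, 8, by = dx)
    w <- cgau2(x)
    spec <- Mod(fft(w))
    freqs <- (seq_along(x) - 1) / (length(x) * dx)
    fc <<- freqs[which.max(spec[seq_len(length(x) %/% 2)])]
    fc
  }
})

#' Extract the high-frequency valve-motion component
#'
#' Continuous wavelet transform of the DUS signal with a second-order
#' complex Gaussian mother wavelet, evaluated at the single scale whose
#' centre frequency is closest to `target_hz` (~200 Hz, the valve-leaflet
#' band), via FFT convolution.  Returns the coefficient magnitude sequence,
#' same length as the input.
#'
#' @param dus numeric vector.
#' @param fs sampling rate in Hz (>= 500).
#' @param target_hz centre frequency to extract (default 200).
#' @param analytic drop the wavelet's residual negative-frequency energy
#'   (about 8% at this short scale) before convolving.  The one-sided
#'   magnitude is a smooth demodulated envelope with burst peaks at the
#'   burst centres; the default two-sided magnitude ripples at twice the
#'   carrier rate, which is what the maxima-interpolation step of
#'   [compute_envelope()] expects.
#' @return numeric vector of nonnegative magnitudes.
#' @export
extract_hf_component <- function(dus, fs, target_hz = 200, analytic = FALSE) {
  if (fs < 500) stop("fs must be >= 500 Hz", call. = FALSE)
  fc <- cgau2_center_freq()
  a <- fc * fs / target_hz            # scale with centre frequency target_hz
  half <- ceiling(5 * a)
  x <- (-half:half) / a
  psi <- Conj(cgau2(x)) / sqrt(a)
  n <- length(dus)
  nfft <- nextn(n + length(psi) - 1, 2)
  S <- fft(c(dus, rep(0, nfft - n)))
  P <- fft(c(psi, rep(0+0i, nfft - length(psi))))
  if (analytic) P[(nfft %/% 2 + 2):nfft] <- 0
  conv <- fft(S * P, inverse = TRUE) / nfft
  Mod(conv[(half + 1):(half + n)])
}

#' Smoothed envelope of the valve-motion component
#'
#' Takes the absolute value, cubic-spline interpolates through its local
#' maxima back onto the original time grid, low-passes the result at
#' `cutoff_hz` (zero-phase), and clips at zero.  With fewer than 4 maxima
#' the envelope falls back to the low-passed absolute value (flagged via
#' `attr(., "fallback")`).
#'
#' @param hf numeric vector (e.g. from [extract_hf_component()]).
#' @param fs sampling rate in Hz.
#' @param cutoff_hz envelope smoothing cutoff (default 30 Hz).
#' @return numeric vector `>= 0`, same length as `hf`; class `envelope`
#'   with `fs` attribute.
#' @export
compute_envelope <- function(hf, fs, cutoff_hz = 30) {
  if (!length(hf)) stop("empty signal", call. = FALSE)
  a <- abs(hf)
  mx <- find_peaks(a)
  fallback <- length(mx) < 4
  if (fallback) {
    interp <- a
    env <- lowpass_zero_phase(a, fs, cutoff_hz)
  } else {
    interp <- spline(x = mx, y = a[mx], xout = seq_along(a), method = "natural")$y
    env <- lowpass_zero_phase(interp, fs, cutoff_hz)
  }
  env <- pmax(env, 0)
  structure(env, fs = fs, fallback = fallback, raw = pmax(interp, 0),
            class = "envelope")
}

#' Segment an envelope into z-normalised cardiac cycles
#'
#' One segment per complete RR interval, starting at each R peak and ending
#' one sample before the next.  Each segment is z-normalised (mean 0,
#' SD 1).  Beats whose RR falls outside 250--1100 ms, or whose envelope is
#' constant (SD 0), are dropped and logged.
#'
#' @param env envelope from [compute_envelope()] (or any numeric vector
#'   with sampling rate `fs`).
#' @param r_peaks tibble with R-peak `time`s (s), or numeric vector.
#' @param fs sampling rate; defaults to the envelope's `fs` attribute.
#' @param raw optional companion signal sliced identically (default: the
#'   envelope's un-smoothed `raw` attribute, used downstream for sub-sample
#'   peak refinement).
#' @return tibble with one row per kept beat: `beat_index` (index into the
#'   R-peak series), `onset_r_time` (s), `rr_ms`, `values` (list-column
#'   of z-normalised numeric vectors of length `round(rr_ms * fs / 1000)`),
#'   and `raw_values` (unnormalised slices of `raw`, or `NULL`s).
#' @export
segment_cycles <- function(env, r_peaks, fs = attr(env, "fs"), raw = attr(env, "raw")) {
  times <- if (is.data.frame(r_peaks)) r_peaks$time else as.numeric(r_peaks)
  if (length(times) < 2) stop("need at least 2 R peaks", call. = FALSE)
  if (is.null(fs)) stop("sampling rate unknown; pass `fs`", call. = FALSE)
  force(raw)
  env <- as.numeric(env)
  out <- vector("list", length(times) - 1)
  keep <- logical(length(times) - 1)
  for (b in seq_len(length(times) - 1)) {
    rr_ms <- (times[b + 1] - times[b]) * 1000
    if (rr_ms < 250 || rr_ms > 1100) next
    i0 <- round(times[b] * fs) + 1L
    len <- round(rr_ms * fs / 1000)
    if (i0 + len - 1L > length(env)) next
    seg <- env[i0:(i0 + len - 1L)]
    s <- sd(seg)
    if (!is.finite(s) || s == 0) next
    out[[b]] <- tibble::tibble(
      beat_index = b, onset_r_time = times[b], rr_ms = rr_ms,
      values = list((seg - mean(seg)) / s),
      raw_values = list(if (is.null(raw)) NULL else raw[i0:(i0 + len - 1L)])
    )
    keep[b] <- TRUE
  }
  dropped <- sum(!keep)
  if (dropped) vg_log("segment", NA_character_, dropped = dropped)
  if (!any(keep)) {
    return(tibble::tibble(beat_index = integer(0), onset_r_time = numeric(0),
                          rr_ms = numeric(0), values = list(), raw_values = list()))
  }
  dplyr::bind_rows(out[keep])
}

#' Full DUS preprocessing for one record
#'
#' Segment morphology comes from the published chain (two-sided magnitude,
#' maxima interpolation, 30 Hz low-pass); the analytic one-sided magnitude
#' rides along as the `raw_values` companion for sub-sample event-phase
#' refinement.
#'
#' @param record [fetal_record()].
#' @param r_peaks tibble of R-peak times (from [detect_r_peaks()]).
#' @return tibble of segments, as [segment_cycles()].
#' @export
preprocess_dus <- function(record, r_peaks) {
  hf <- extract_hf_component(record$dus, record$fs)
  env <- compute_envelope(hf, record$fs)
  refine_track <- extract_hf_component(record$dus, record$fs, analytic = TRUE)
  segs <- segment_cycles(env, r_peaks, fs = record$fs, raw = refine_track)
  vg_log("dus_prep", record$record_id, n_segments = nrow(segs))
  segs
}
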