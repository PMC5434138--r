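# Fetal heart rate variability: time-domain and band-power parameters.

#' Time-domain FHRV parameters
#'
#' @param rr numeric vector of RR intervals in ms (>= 2 values).
#' @return one-row tibble: `mRR` (arithmetic mean), `SDRR` (sample SD,
#'   n-1 denominator), `RMSSD` (root mean square of successive
#'   differences), all ms.
#' @export
fhrv_time_domain <- function(rr) {
  rr <- rr[!is.na(rr)]
  if (length(rr) < 2) stop("need >= 2 RR values", call. = FALSE)
  tibble::tibble(
    mRR = mean(rr),
    SDRR = sd(rr),
    RMSSD = sqrt(mean(diff(rr)^2))
  )
}

#' Frequency-domain FHRV parameters
#'
#' The RR tachogram is evenly resampled at `resample_hz` (linear
#' interpolation against the R-peak times), mean-removed, and a single
#' Hann-tapered periodogram is integrated over the fetal bands
#' LF 0.03--0.15 Hz (sympathetic activity), MF 0.15--0.5 Hz (fetal
#' movements, maternal breathing) and HF 0.5--1 Hz (fetal breathing).
#' `TP` is the integral over the union 0.03--1 Hz, so LF + MF + HF = TP up
#' to integration tolerance; `lf_ratio = LF / (MF + HF)` (`NA` when the
#' denominator is 0).  Invariant to shifting all R times by a constant.
#'
#' @param r_times R-peak times in s (>= 30 beats over >= 30 s).
#' @param rr RR series in ms aligned to `r_times` (RR to the previous
#'   peak; `rr[1]` may be `NA`).
#' @param resample_hz even resampling rate (default 4 Hz).
#' @return one-row tibble: `LF`, `MF`, `HF`, `TP` (ms^2), `lf_ratio`.
#' @export
fhrv_freq_domain <- function(r_times, rr, resample_hz = 4) {
  ok <- !is.na(rr)
  t <- r_times[ok]; y <- rr[ok]
  if (length(y) < 30) stop("need >= 30 beats", call. = FALSE)
  if (diff(range(t)) < 30) stop("record shorter than 30 s", call. = FALSE)
  tg <- seq(min(t), max(t), by = 1 / resample_hz)
  yi <- approx(t, y, xout = tg)$y
  yi <- yi - mean(yi)
  n <- length(yi)
  w <- hann_window(n)
  yw <- yi * w
  # one-sided PSD with window power compensation (units ms^2 / Hz)
  spec <- Mod(fft(yw))^2 / (sum(w^2) * resample_hz)
  nf <- n %/% 2
  freqs <- (seq_len(nf) - 1) * resample_hz / n
  psd <- 2 * spec[seq_len(nf)]
  psd[1] <- spec[1]
  df <- resample_hz / n
  band_power <- function(lo, hi) sum(psd[freqs >= lo & freqs < hi]) * df
  LF <- band_power(0.03, 0.15)
  MF <- band_power(0.15, 0.5)
  HF <- band_power(0.5, 1.0)
  TP <- band_power(0.03, 1.0)
  tibble::tibble(
    LF = LF, MF = MF, HF = HF, TP = TP,
    lf_ratio = if ((MF + HF) > 1e-9) LF / (MF + HF) else NA_real_
  )
}

#' All FHRV parameters of an R-peak series
#'
#' @param r_peaks tibble from [detect_r_peaks()] (`time`, `rr`).
#' @return one-row tibble: `mRR`, `SDRR`, `RMSSD`, `LF`, `MF`, `HF`, `TP`,
#'   `lf_ratio`.
#' @export
fhrv_params <- function(r_peaks) {
  dplyr::bind_cols(
    fhrv_time_domain(r_peaks$rr),
    fhrv_freq_domain(r_peaks$time, r_peaks$rr)
  )
}
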