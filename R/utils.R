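# Small shared numerics: peak finding, filtering, windows.

#' Locate local maxima with a prominence and separation requirement
#'
#' Returns indices of samples that are strict local maxima, have topographic
#' prominence of at least `min_prominence`, and are separated by at least
#' `min_separation` samples (higher peaks win ties).
#'
#' @param x numeric vector.
#' @param min_prominence minimum prominence, in the units of `x`.
#' @param min_separation minimum index distance between retained peaks.
#' @return integer vector of peak indices, increasing.
#' @export
find_peaks <- function(x, min_prominence = 0, min_separation = 1) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  if (min_prominence > 0) {
    prom <- vapply(idx, function(i) {
      # lowest saddle between this peak and the nearest higher ground each side
      left <- x[1:i]
      right <- x[i:n]
      higher_l <- which(left > x[i])
      higher_r <- which(right > x[i])
      base_l <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
      base_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
      x[i] - max(base_l, base_r)
    }, numeric(1))
    idx <- idx[prom >= min_prominence]
  }
  if (min_separation > 1 && length(idx) > 1) {
    keep <- logical(length(idx))
    ord <- order(x[idx], decreasing = TRUE)
    taken <- integer(0)
    for (j in ord) {
      if (!length(taken) || all(abs(idx[j] - taken) >= min_separation)) {
        keep[j] <- TRUE
        taken <- c(taken, idx[j])
      }
    }
    idx <- idx[keep]
  }
  sort(idx)
}

# Zero-phase Butterworth low-pass; falls back to the identity when the cutoff
# is at/above Nyquist.
lowpass_zero_phase <- function(x, fs, cutoff, order = 4) {
  w <- cutoff / (fs / 2)
  if (w >= 1) return(x)
  bf <- signal::butter(order, w, type = "low")
  signal::filtfilt(bf, x)
}

bandpass_zero_phase <- function(x, fs, low, high, order = 3) {
  w <- c(low, high) / (fs / 2)
  w[2] <- min(w[2], 0.99)
  bf <- signal::butter(order, w, type = "pass")
  signal::filtfilt(bf, x)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Structured one-line stage log, silenced unless option set.
vg_log <- function(stage, record_id = NA_character_, ...) {
  if (!isTRUE(getOption("valvegest.verbose", FALSE))) return(invisible(NULL))
  kv <- list(...)
  msg <- paste0(
    "[", stage, "] record=", record_id,
    if (length(kv)) paste0(" ", paste(names(kv), unlist(kv), sep = "=", collapse = " ")) else ""
  )
  message(msg)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
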