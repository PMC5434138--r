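# Cardiac intervals: per-beat conversion of valve events + Q onsets into
# EDT/ICT/VET/IRT/VFT (and the linearly dependent PEP/STI), and robust
# record-level aggregation.

#' Per-beat cardiac intervals from valve events
#'
#' With Q the per-beat Q onset (before R), valve phases in ms after R, and
#' times across beats made absolute via the R-peak times:
#' `EDT = Mc - Q`, `ICT = Ao - Mc`, `VET = Ac - Ao`, `IRT = Mo - Ac`,
#' `VFT = Mc(next beat, absolute) - Mo`, `PEP = EDT + ICT`,
#' `STI = EDT + ICT + VET`.  Any interval with a missing constituent is
#' `NA`; non-positive intervals are rejected (set `NA`, `flagged`).  The
#' last beat has no successor, so its VFT is `NA`.
#'
#' @param events tibble from [decode_record()] (valve phases per beat, ms
#'   after R, plus `beat_index`, `onset_r_time`, `rr_ms`).
#' @param q_onsets tibble from [estimate_q_onset()] (`beat_index`,
#'   `q_offset_ms`).
#' @return tibble: `beat_index`, `EDT`, `ICT`, `VET`, `IRT`, `VFT`, `PEP`,
#'   `STI` (ms), `flagged`.
#' @export
compute_beat_intervals <- function(events, q_onsets) {
  ev <- dplyr::left_join(events, q_onsets[c("beat_index", "q_offset_ms")], by = "beat_index")
  ev <- ev[order(ev$beat_index), ]
  n <- nrow(ev)
  # next beat's Mc in absolute ms, when the next beat is consecutive
  next_mc_abs <- rep(NA_real_, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (ev$beat_index[i + 1] == ev$beat_index[i] + 1L) {
        next_mc_abs[i] <- ev$onset_r_time[i + 1] * 1000 + ev$Mc_ms[i + 1]
      }
    }
  }
  EDT <- ev$Mc_ms + ev$q_offset_ms
  ICT <- ev$Ao_ms - ev$Mc_ms
  VET <- ev$Ac_ms - ev$Ao_ms
  IRT <- ev$Mo_ms - ev$Ac_ms
  VFT <- next_mc_abs - (ev$onset_r_time * 1000 + ev$Mo_ms)
  out <- tibble::tibble(
    beat_index = ev$beat_index,
    EDT = EDT, ICT = ICT, VET = VET, IRT = IRT, VFT = VFT
  )
  flagged <- rep(FALSE, n)
  for (col in c("EDT", "ICT", "VET", "IRT", "VFT")) {
    bad <- !is.na(out[[col]]) & out[[col]] <= 0
    flagged <- flagged | bad
    out[[col]][bad] <- NA_real_
  }
  out$PEP <- out$EDT + out$ICT
  out$STI <- out$EDT + out$ICT + out$VET
  out$flagged <- flagged
  out
}

#' Aggregate beat intervals to record level
#'
#' Record value per interval = median over accepted beats; dispersion =
#' median absolute deviation.  Beats failing the quality mask are
#' excluded.  Order-invariant.
#'
#' @param beats tibble from [compute_beat_intervals()].
#' @param quality_mask logical per-beat accept flags (default all
#'   accepted).
#' @return one-row tibble: `EDT`..`VFT` medians (ms), `EDT_mad`..`VFT_mad`,
#'   `n_beats_used` (beats contributing at least one interval), `usable`.
#' @export
aggregate_record <- function(beats, quality_mask = rep(TRUE, nrow(beats))) {
  stopifnot(length(quality_mask) == nrow(beats))
  acc <- beats[quality_mask, , drop = FALSE]
  cols <- c("EDT", "ICT", "VET", "IRT", "VFT")
  med <- vapply(cols, function(cl) median(acc[[cl]], na.rm = TRUE), numeric(1))
  disp <- vapply(cols, function(cl) mad(acc[[cl]], na.rm = TRUE), numeric(1))
  n_used <- sum(rowSums(!is.na(acc[cols])) > 0)
  out <- tibble::as_tibble(as.list(med))
  names(disp) <- paste0(cols, "_mad")
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.list(disp)))
  out$n_beats_used <- n_used
  out$usable <- n_used >= 1 && all(is.finite(med))
  out
}
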