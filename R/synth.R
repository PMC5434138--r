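# Synthetic paired DUS + fECG generator with known per-beat ground truth.
# The generator is first-class: it defines the study conditions every
# downstream stage is exercised against.

#' Simulator parameters
#'
#' Defaults emulate 1-minute, 1 kHz paired recordings over gestational ages
#' 16--41 weeks.  In `model_inverse` mode the per-record intervals are drawn
#' uniformly (EDT 20--45, ICT 25--45, VFT 120--250 ms) and GA is the shipped
#' valve-interval polynomial of (EDT, ICT, VFT) plus Gaussian noise; in
#' `uniform_ga` mode GA ~ U(16, 41) and the intervals are affine in GA plus
#' noise.  Mean heart rate follows a linear trend from `fhr_trend[1]` bpm at
#' 16 weeks to `fhr_trend[2]` bpm at 41 weeks; per-beat RR jitter is
#' Gaussian with SD 2.5% of the mean RR.
#'
#' @param n_records number of records.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param ga_mode `"model_inverse"` or `"uniform_ga"`.
#' @param snr_db DUS signal-to-noise ratio in dB (`Inf` = noiseless).
#' @param duration record length in seconds.
#' @param fs sampling rate in Hz.
#' @param interval_ranges named list of `c(low, high)` ms ranges for EDT,
#'   ICT, VFT.
#' @param transitional_burst_prob per-beat probability of one extra
#'   transitional burst.
#' @param fhr_trend mean FHR (bpm) at 16 and at 41 weeks.
#' @param noise_sd_weeks SD of the Gaussian GA noise in `model_inverse`
#'   mode (weeks).
#' @param clip_ga clip simulated GA to \[16, 41\] weeks (`model_inverse`
#'   mode).  Disable when the cohort feeds coefficient-recovery fits, where
#'   censoring the response would bias the estimates.
#' @param q_offset_ms Q-wave onset to R-peak offset (ms).
#' @param rr_jitter relative SD of per-beat RR around the record mean.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(n_records = 20, seed = 1,
                         ga_mode = c("model_inverse", "uniform_ga"),
                         snr_db = 20, duration = 60, fs = 1000,
                         interval_ranges = list(EDT = c(20, 45),
                                                ICT = c(25, 45),
                                                VFT = c(120, 250)),
                         transitional_burst_prob = 0.3,
                         fhr_trend = c(160, 140),
                         noise_sd_weeks = 4.01,
                         clip_ga = TRUE,
                         q_offset_ms = 12,
                         rr_jitter = 0.025) {
  ga_mode <- match.arg(ga_mode)
  for (rng in interval_ranges) {
    if (rng[1] >= rng[2]) stop("interval range must have low < high", call. = FALSE)
  }
  if (!is.finite(snr_db) && snr_db < 0) stop("snr_db must be finite or +Inf", call. = FALSE)
  if (transitional_burst_prob < 0 || transitional_burst_prob > 1) {
    stop("transitional_burst_prob must be in [0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_params")
}

fhr_at_ga <- function(ga, fhr_trend) {
  fhr_trend[1] + (fhr_trend[2] - fhr_trend[1]) * (ga - 16) / (41 - 16)
}

#' Draw a cohort of per-record ground truths
#'
#' Each ground truth fixes the record's GA, mean FHR, per-beat R-peak times
#' and the four valve-event phases (ms after R).  Event phases are constant
#' within a record (phase-locked beats), so ICT+VET+IRT+VFT equals each
#' beat's RR exactly by construction.
#'
#' @param params [synth_params()].
#' @param truths build the per-beat `truth` list-column (default `TRUE`);
#'   disable for large regression-scale cohorts where only the tabular
#'   intervals and GA are needed.
#' @return tibble with one row per record: `record_id`, `ga`, `fhr_bpm`,
#'   generating intervals `EDT`..`VFT` (ms), and (with `truths = TRUE`) a
#'   `truth` list-column of `ground_truth` objects.
#' @export
sample_cohort <- function(params, truths = TRUE) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  n <- params$n_records
  rng <- params$interval_ranges
  if (params$ga_mode == "model_inverse") {
    EDT <- runif(n, rng$EDT[1], rng$EDT[2])
    ICT <- runif(n, rng$ICT[1], rng$ICT[2])
    VFT <- runif(n, rng$VFT[1], rng$VFT[2])
    ga <- predict_ga(ga_model_valve(), data.frame(EDT = EDT, ICT = ICT, VFT = VFT)) +
      rnorm(n, 0, params$noise_sd_weeks)
    if (params$clip_ga) ga <- pmin(pmax(ga, 16), 41)
  } else {
    ga <- runif(n, 16, 41)
    EDT <- pmin(pmax(22 + 0.60 * (ga - 16) + rnorm(n, 0, 1.5), rng$EDT[1]), rng$EDT[2])
    ICT <- pmin(pmax(27 + 0.55 * (ga - 16) + rnorm(n, 0, 1.5), rng$ICT[1]), rng$ICT[2])
    VFT <- pmin(pmax(130 + 4.0 * (ga - 16) + rnorm(n, 0, 8.0), rng$VFT[1]), rng$VFT[2])
  }
  fhr <- fhr_at_ga(pmin(pmax(ga, 16), 41), params$fhr_trend)
  mean_rr <- 60000 / fhr
  rem <- mean_rr - ICT - VFT
  if (any(rem <= 0)) stop("infeasible ranges: negative VET/IRT remainder", call. = FALSE)
  VET <- 0.75 * rem
  IRT <- 0.25 * rem

  base <- tibble::tibble(
    record_id = sprintf("synth%03d", seq_len(n)),
    ga = ga, fhr_bpm = fhr,
    EDT = EDT, ICT = ICT, VET = VET, IRT = IRT, VFT = VFT
  )
  if (!truths) return(base)

  truth_list <- vector("list", n)
  for (i in seq_len(n)) {
    truth_list[[i]] <- make_ground_truth(
      record_id = sprintf("synth%03d", i),
      ga = ga[i], mean_rr = mean_rr[i],
      EDT = EDT[i], ICT = ICT[i], VET = VET[i], IRT = IRT[i], VFT = VFT[i],
      q_offset_ms = params$q_offset_ms,
      duration = params$duration,
      rr_jitter = params$rr_jitter,
      transitional_burst_prob = params$transitional_burst_prob
    )
  }
  base$truth <- truth_list
  base
}

make_ground_truth <- function(record_id, ga, mean_rr, EDT, ICT, VET, IRT, VFT,
                              q_offset_ms, duration, rr_jitter,
                              transitional_burst_prob) {
  # beat train: start 0.5 s in, stop one full cycle before the end
  max_beats <- ceiling(duration * 1000 / (mean_rr * (1 - 4 * rr_jitter))) + 2L
  rr_seq <- mean_rr * (1 + rnorm(max_beats, 0, rr_jitter)) / 1000
  r_all <- 0.5 + c(0, cumsum(rr_seq))
  r_times <- r_all[r_all < duration - 1.2 * mean_rr / 1000]
  n_beats <- length(r_times)
  Mc <- EDT - q_offset_ms
  if (Mc <= 0) stop("EDT must exceed q_offset_ms", call. = FALSE)
  phases <- c(Mc = Mc, Ao = Mc + ICT, Ac = Mc + ICT + VET, Mo = Mc + ICT + VET + IRT)
  events <- tibble::tibble(
    beat_index = seq_len(n_beats),
    Mc = rep(phases[["Mc"]], n_beats), Ao = rep(phases[["Ao"]], n_beats),
    Ac = rep(phases[["Ac"]], n_beats), Mo = rep(phases[["Mo"]], n_beats)
  )
  # optional transitional bursts in the Ac-Mo or Mo-next gaps
  has_tr <- runif(n_beats) < transitional_burst_prob
  tr_phase <- ifelse(
    runif(n_beats) < 0.5,
    phases[["Ac"]] + runif(n_beats, 0.25, 0.75) * (phases[["Mo"]] - phases[["Ac"]]),
    phases[["Mo"]] + runif(n_beats, 15, 40)
  )
  transitional <- tibble::tibble(
    beat_index = which(has_tr),
    phase_ms = tr_phase[has_tr]
  )
  structure(
    list(
      record_id = record_id, ga = ga, fhr_bpm = 60000 / mean_rr,
      mean_rr = mean_rr, q_offset_ms = q_offset_ms,
      r_times = r_times, events = events, transitional = transitional,
      intervals = c(EDT = EDT, ICT = ICT, VET = VET, IRT = IRT, VFT = VFT),
      suppressed = character(0), duration = duration
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth '%s'> GA %.1f wk, FHR %.0f bpm, %d beats, intervals [ms]: %s\n",
    x$record_id, x$ga, x$fhr_bpm, length(x$r_times),
    paste(names(x$intervals), round(x$intervals, 1), sep = "=", collapse = " ")
  ))
  invisible(x)
}

# per-beat event times in absolute seconds (and per-beat intervals, ms)
truth_event_times <- function(truth) {
  ev <- truth$events
  tibble::tibble(
    beat_index = ev$beat_index,
    r_time = truth$r_times[ev$beat_index],
    Mc = truth$r_times[ev$beat_index] + ev$Mc / 1000,
    Ao = truth$r_times[ev$beat_index] + ev$Ao / 1000,
    Ac = truth$r_times[ev$beat_index] + ev$Ac / 1000,
    Mo = truth$r_times[ev$beat_index] + ev$Mo / 1000
  )
}

# event-specific burst amplitudes (z of the raw carrier, pre-noise)
burst_amplitudes <- c(Mc = 1.0, Ao = 1.2, Ac = 1.1, Mo = 0.9, transitional = 0.4)

#' Render a ground truth into waveforms
#'
#' The fECG is a train of 30 ms biphasic QRS templates whose deflection
#' starts exactly at the Q onset (`q_offset_ms` before each R); the DUS is a
#' sum of Hann-windowed 200 Hz cosine bursts of 24 ms, centred exactly at
#' the ground-truth event times, with event-specific amplitudes (Mc 1.0,
#' Ao 1.2, Ac 1.1, Mo 0.9, transitional 0.4) plus white Gaussian noise
#' scaled to `snr_db`.
#'
#' @param truth a `ground_truth`.
#' @param fs sampling rate in Hz (>= 500).
#' @param duration seconds; default the truth's duration.
#' @param snr_db DUS SNR in dB (`Inf` = no noise).
#' @param seed integer seed for the noise.
#' @param fecg_snr_db optional fECG SNR in dB (default `Inf`, clean).
#' @return [fetal_record()] with `ga_crl` set to the truth GA.
#' @export
render_waveforms <- function(truth, fs = 1000, duration = NULL, snr_db = Inf,
                             seed = 1, fecg_snr_db = Inf) {
  if (fs < 500) stop("fs < 500 Hz cannot represent 200 Hz valve bursts", call. = FALSE)
  duration <- duration %||% truth$duration
  n <- round(duration * fs)
  dus <- numeric(n)
  fecg <- numeric(n)

  # fECG: piecewise-linear biphasic QRS, flat before the Q onset.  The
  # continuous template is evaluated at the sample times (no snapping to the
  # grid), so event timing is preserved to sub-sample accuracy.
  q <- truth$q_offset_ms
  knots_ms <- c(-q, -4, 0, 5, 10)
  knots_val <- c(0, -0.35, 1, -0.30, 0)
  for (r in truth$r_times) {
    ii <- max(1L, floor((r - q / 1000) * fs)):min(n, ceiling((r + 0.011) * fs) + 1L)
    t_rel_ms <- ((ii - 1) / fs - r) * 1000
    v <- approx(knots_ms, knots_val, xout = t_rel_ms)$y
    v[is.na(v)] <- 0
    fecg[ii] <- fecg[ii] + v
  }

  # DUS: 200 Hz Hann bursts centred exactly at the (continuous) event times
  burst_dur <- 0.024
  add_burst <- function(sig, center_s, amp) {
    ii <- max(1L, floor((center_s - burst_dur / 2) * fs)):
      min(n, ceiling((center_s + burst_dur / 2) * fs) + 1L)
    t_rel <- (ii - 1) / fs - center_s
    inside <- abs(t_rel) <= burst_dur / 2
    w <- ifelse(inside, 0.5 + 0.5 * cos(2 * pi * t_rel / burst_dur), 0)
    sig[ii] <- sig[ii] + amp * w * cos(2 * pi * 200 * t_rel)
    sig
  }
  ev_abs <- truth_event_times(truth)
  for (evname in c("Mc", "Ao", "Ac", "Mo")) {
    amp <- if (evname %in% truth$suppressed) 0 else burst_amplitudes[[evname]]
    if (amp == 0) next
    for (tc in ev_abs[[evname]]) dus <- add_burst(dus, tc, amp)
  }
  if (nrow(truth$transitional)) {
    tr_abs <- truth$r_times[truth$transitional$beat_index] + truth$transitional$phase_ms / 1000
    for (tc in tr_abs) dus <- add_burst(dus, tc, burst_amplitudes[["transitional"]])
  }

  set.seed(seed)
  if (is.finite(snr_db)) {
    p_sig <- mean(dus^2)
    if (p_sig > 0) dus <- dus + rnorm(n, 0, sqrt(p_sig / 10^(snr_db / 10)))
    else dus <- dus + rnorm(n, 0, 1)  # zero beats: flat noise record
  }
  if (is.finite(fecg_snr_db)) {
    p_sig <- mean(fecg^2)
    if (p_sig > 0) fecg <- fecg + rnorm(n, 0, sqrt(p_sig / 10^(fecg_snr_db / 10)))
  }
  fetal_record(dus, fecg, fs = fs, record_id = truth$record_id, ga_crl = truth$ga,
               meta = list(fhr_bpm = truth$fhr_bpm, seed = seed, snr_db = snr_db))
}

#' Inject an arrhythmia or valve anomaly into a ground truth
#'
#' * `tachycardia`: rescales the beat train so mean FHR is at least 185 bpm,
#'   recomputing VET/IRT/VFT so events still fit inside the shortened cycle.
#' * `bradycardia`: rescales to 65 bpm; event phases and nominal intervals
#'   are untouched, so the longer diastole appears in the waveform only.
#' * `av_block`: slows the ventricular rate to 65 bpm and decouples a random
#'   half of the beats by jittering their event phases by up to +-60 ms.
#' * `valve_suppress`: zeroes the burst amplitude of one named event.
#'
#' @param truth a `ground_truth`.
#' @param kind one of `"tachycardia"`, `"bradycardia"`, `"av_block"`,
#'   `"valve_suppress"`.
#' @param event event to silence for `valve_suppress` (default `"Ao"`).
#' @param seed seed for the av_block beat subset.
#' @return modified `ground_truth`.
#' @export
inject_anomaly <- function(truth, kind = c("tachycardia", "bradycardia",
                                           "av_block", "valve_suppress"),
                           event = "Ao", seed = 1) {
  kind <- match.arg(kind)
  rescale_rate <- function(tr, new_fhr) {
    f <- tr$fhr_bpm / new_fhr
    tr$r_times <- tr$r_times[1] + (tr$r_times - tr$r_times[1]) * f
    tr$r_times <- tr$r_times[tr$r_times < tr$duration - 1.2 * (60 / new_fhr)]
    nb <- length(tr$r_times)
    tr$events <- tr$events[seq_len(nb), , drop = FALSE]
    tr$transitional <- tr$transitional[tr$transitional$beat_index <= nb, , drop = FALSE]
    tr$mean_rr <- tr$mean_rr * f
    tr$fhr_bpm <- new_fhr
    tr
  }
  if (kind == "tachycardia") {
    new_fhr <- max(185, truth$fhr_bpm)
    truth <- rescale_rate(truth, new_fhr)
    iv <- truth$intervals
    rem_all <- truth$mean_rr - iv[["ICT"]]
    VFT <- 0.60 * rem_all
    VET <- 0.75 * 0.40 * rem_all
    IRT <- 0.25 * 0.40 * rem_all
    Mc <- iv[["EDT"]] - truth$q_offset_ms
    nb <- nrow(truth$events)
    truth$events$Ao <- rep(Mc + iv[["ICT"]], nb)
    truth$events$Ac <- rep(Mc + iv[["ICT"]] + VET, nb)
    truth$events$Mo <- rep(Mc + iv[["ICT"]] + VET + IRT, nb)
    truth$intervals[c("VET", "IRT", "VFT")] <- c(VET, IRT, VFT)
  } else if (kind == "bradycardia") {
    # event phases and nominal intervals untouched: only the beat train slows,
    # so the extra diastole shows up in the waveform but not in the intended
    # valve timings
    truth <- rescale_rate(truth, 65)
  } else if (kind == "av_block") {
    truth <- rescale_rate(truth, 65)
    set.seed(seed)
    nb <- nrow(truth$events)
    decoupled <- sort(sample(nb, floor(nb / 2)))
    for (col in c("Mc", "Ao", "Ac", "Mo")) {
      truth$events[[col]][decoupled] <-
        pmax(2, truth$events[[col]][decoupled] + runif(length(decoupled), -60, 60))
    }
    truth$meta_decoupled <- decoupled
  } else {
    if (!event %in% c("Mc", "Ao", "Ac", "Mo")) stop("unknown event: ", event, call. = FALSE)
    truth$suppressed <- union(truth$suppressed, event)
  }
  truth$anomaly <- kind
  truth
}

#' Simulate a full cohort of rendered records
#'
#' Convenience wrapper: [sample_cohort()] then [render_waveforms()] per
#' record, with per-record noise seeds derived from `params$seed`.
#'
#' @param params [synth_params()].
#' @return tibble from [sample_cohort()] with an added `record` list-column
#'   of [fetal_record()] objects.
#' @export
simulate_records <- function(params) {
  cohort <- sample_cohort(params)
  cohort$record <- purrr::imap(
    cohort$truth,
    ~ render_waveforms(.x, fs = params$fs, duration = params$duration,
                       snr_db = params$snr_db, seed = params$seed + 1000L + .y)
  )
  cohort
}
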