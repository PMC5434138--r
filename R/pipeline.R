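# End-to-end orchestration: annotate -> preprocess -> quality -> decode ->
# intervals -> FHRV -> GA estimates, one cohort table out.

#' Pipeline configuration
#'
#' @param fecg_threshold record-level bSQI gate (default 0.4).
#' @param dus_threshold record-level DUS quality gate (default 0.3).
#' @param beat_quality_threshold per-beat posterior below which a beat is
#'   excluded from interval aggregation (default 0.5).
#' @param bsqi_tol_ms bSQI matching tolerance.
#' @param seed integer seed used by training helpers.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fecg_threshold = 0.4, dus_threshold = 0.3,
                            beat_quality_threshold = 0.5,
                            bsqi_tol_ms = 50, seed = 1) {
  stopifnot(fecg_threshold >= 0, fecg_threshold <= 1,
            dus_threshold >= 0, dus_threshold <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML key-value file
#'
#' Keys mirror the [pipeline_config()] arguments; unknown keys are an
#' error, omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config must be a key-value mapping", call. = FALSE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Train the decoder and quality classifier on simulated data
#'
#' Trains the valve decoder on a clean simulated cohort, and the DUS
#' quality classifier on segments pooled from clean (labelled good) and
#' heavily corrupted (labelled bad) renders of the same ground truths.
#'
#' @param n_train records in the decoder training cohort.
#' @param seed master seed.
#' @param duration training record length in seconds.
#' @param snr_clean,snr_bad SNRs (dB) of the good/bad quality renders.
#' @return list of class `pipeline_models`: `decoder` (`valve_decoder`),
#'   `quality` (`nb_kde_model`).
#' @export
train_pipeline_models <- function(n_train = 8, seed = 1, duration = 30,
                                  snr_clean = 25, snr_bad = -8) {
  params <- synth_params(n_records = n_train, seed = seed, snr_db = snr_clean,
                         duration = duration)
  cohort <- simulate_records(params)
  decoder <- train_valve_decoder(cohort, seed = seed)

  sqi_rows <- list()
  labels <- character(0)
  for (i in seq_len(nrow(cohort))) {
    truth <- cohort$truth[[i]]
    rp <- tibble::tibble(time = truth$r_times)
    # good class spans clean-to-noiseless renders so that very clean records
    # do not fall outside the good-class density support
    renders <- list(
      good = cohort$record[[i]],
      good = render_waveforms(truth, fs = params$fs, duration = duration,
                              snr_db = Inf, seed = seed + 4000L + i),
      bad = render_waveforms(truth, fs = params$fs, duration = duration,
                             snr_db = snr_bad, seed = seed + 5000L + i)
    )
    for (k in seq_along(renders)) {
      lab <- names(renders)[k]
      rec <- renders[[k]]
      segs <- preprocess_dus(rec, rp)
      ok <- vapply(segs$values, function(v) length(v) >= 0.350 * rec$fs, logical(1))
      if (!any(ok)) next
      sq <- purrr::map_dfr(segs$values[ok], compute_sqi_vector, fs = rec$fs)
      sqi_rows[[length(sqi_rows) + 1]] <- sq
      labels <- c(labels, rep(lab, nrow(sq)))
    }
  }
  raw <- dplyr::bind_rows(sqi_rows)
  norm <- normalize_sqi(raw)
  quality <- train_quality_classifier(norm, labels)
  structure(list(decoder = decoder, quality = quality), class = "pipeline_models")
}

process_one_record <- function(record, models, config) {
  na_row <- function(reason) {
    tibble::tibble(
      record_id = record$record_id, ga_crl = record$ga_crl,
      n_beats = NA_integer_, n_beats_used = NA_integer_,
      EDT = NA_real_, ICT = NA_real_, VET = NA_real_, IRT = NA_real_, VFT = NA_real_,
      mRR = NA_real_, SDRR = NA_real_, RMSSD = NA_real_,
      LF = NA_real_, MF = NA_real_, HF = NA_real_, TP = NA_real_, lf_ratio = NA_real_,
      fecg_sqi = NA_real_, dus_sqi = NA_real_,
      ga_est_valve = NA_real_, ga_est_fhrv = NA_real_,
      status = reason
    )
  }
  ann <- tryCatch(annotate_fecg(record, tol_ms = config$bsqi_tol_ms),
                  error = function(e) NULL)
  if (is.null(ann) || nrow(ann$r_peaks) < 3) return(na_row("fecg_detection_failed"))
  segs <- tryCatch(preprocess_dus(record, ann$r_peaks), error = function(e) NULL)
  if (is.null(segs) || !nrow(segs)) return(na_row("no_segments"))
  qual <- dus_quality(segs, models$quality, record$fs)
  dec <- decode_record(segs, models$decoder, record$fs)
  beat_q <- qual$segments$quality_prob[match(dec$beat_index, qual$segments$beat_index)]
  beat_q[is.na(beat_q)] <- 0
  beats <- compute_beat_intervals(dec, ann$q_onsets)
  agg <- aggregate_record(beats, quality_mask = beat_q >= config$beat_quality_threshold &
                            (dec$complete | TRUE))
  fh <- tryCatch(fhrv_params(ann$r_peaks), error = function(e) NULL)
  row <- tibble::tibble(
    record_id = record$record_id, ga_crl = record$ga_crl,
    n_beats = nrow(dec), n_beats_used = agg$n_beats_used,
    EDT = agg$EDT, ICT = agg$ICT, VET = agg$VET, IRT = agg$IRT, VFT = agg$VFT
  )
  if (is.null(fh)) {
    row <- dplyr::bind_cols(row, tibble::tibble(
      mRR = NA_real_, SDRR = NA_real_, RMSSD = NA_real_, LF = NA_real_,
      MF = NA_real_, HF = NA_real_, TP = NA_real_, lf_ratio = NA_real_))
  } else {
    row <- dplyr::bind_cols(row, fh)
  }
  row$fecg_sqi <- ann$bsqi
  row$dus_sqi <- qual$record_score
  row$ga_est_valve <- if (agg$usable)
    predict_ga(ga_model_valve(), row[c("EDT", "ICT", "VFT")]) else NA_real_
  row$ga_est_fhrv <- if (!is.null(fh))
    predict_ga(ga_model_fhrv(), row[c("mRR", "SDRR")]) else NA_real_
  row$status <- "ok"
  row
}

#' Run the full pipeline over a set of records
#'
#' Each record is annotated (R peaks, Q onsets, bSQI), preprocessed
#' (wavelet + envelope + segmentation), quality-scored, decoded, converted
#' to intervals and FHRV parameters, and given valve-based and FHRV-based
#' GA estimates from the shipped models.  A record failing any stage is
#' carried through with `NA` outputs and a `status` reason, so every input
#' record appears exactly once in the output.
#'
#' @param records list of [fetal_record()] objects (or a cohort tibble
#'   from [simulate_records()], whose `record` column is used).
#' @param models [train_pipeline_models()] output (or compatible list).
#' @param config [pipeline_config()].
#' @return cohort tibble, one row per record: intervals (ms), FHRV
#'   parameters, quality scores, GA estimates (weeks), `error`
#'   (valve estimate minus `ga_crl` when both exist), `status`.
#' @export
run_pipeline <- function(records, models, config = pipeline_config()) {
  if (is.data.frame(records)) records <- records$record
  if (!length(records)) {
    return(tibble::tibble(record_id = character(0)))
  }
  out <- purrr::map_dfr(records, process_one_record, models = models, config = config)
  out$error <- out$ga_est_valve - out$ga_crl
  out
}
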