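# Simulator: reproducibility, interval bookkeeping, waveform fidelity,
# anomaly injection.

test_that("identical parameters and seed give identical cohorts", {
  p <- synth_params(n_records = 4, seed = 123, duration = 15)
  a <- sample_cohort(p)
  b <- sample_cohort(p)
  expect_identical(a$ga, b$ga)
  expect_identical(a$truth[[2]]$r_times, b$truth[[2]]$r_times)
  expect_identical(a$truth[[3]]$events, b$truth[[3]]$events)
  ra <- render_waveforms(a$truth[[1]], snr_db = 10, seed = 9)
  rb <- render_waveforms(b$truth[[1]], snr_db = 10, seed = 9)
  expect_identical(ra$dus, rb$dus)
})

test_that("noise-free model-inverse GA equals the valve polynomial", {
  # direct evaluation of the published polynomial as the oracle
  oracle <- function(E, I, V) {
    -276.810 + 5.496 * E + 7.897 * I + 0.682 * V - 0.140 * E * I - 0.017 * I * V
  }
  expect_equal(oracle(25, 30, 180), 23.46, tolerance = 1e-9)
  p <- synth_params(n_records = 50, seed = 7, noise_sd_weeks = 0, clip_ga = FALSE)
  co <- sample_cohort(p)
  expect_equal(co$ga, oracle(co$EDT, co$ICT, co$VFT), tolerance = 1e-9)
})

test_that("per-beat interval sum equals RR exactly by construction", {
  p <- synth_params(n_records = 2, seed = 5, duration = 20)
  co <- sample_cohort(p)
  for (tr in co$truth) {
    ev <- tr$events
    rr <- diff(tr$r_times) * 1000
    nb <- length(rr)
    # ICT+VET+IRT = Mo - Mc phases; VFT closes the cycle to the next Mc
    ict_vet_irt <- ev$Mo[1:nb] - ev$Mc[1:nb]
    vft <- rr + ev$Mc[2:(nb + 1)] - ev$Mo[1:nb]
    expect_equal(ict_vet_irt + vft, rr, tolerance = 1e-9)
  }
})

test_that("rendered envelope has a local maximum within 5 ms of every event", {
  fix <- vg_clean_record()
  rec <- fix$record; tr <- fix$truth
  env <- compute_envelope(extract_hf_component(rec$dus, rec$fs), rec$fs)
  peaks <- find_peaks(as.numeric(env), min_prominence = 0.01 * max(env))
  peak_t <- (peaks - 1) / rec$fs
  ev <- truth_event_times(tr)
  for (col in c("Mc", "Ao", "Ac", "Mo")) {
    gaps <- vapply(ev[[col]], function(t) min(abs(peak_t - t)) * 1000, numeric(1))
    expect_lt(max(gaps), 5)
  }
})

test_that("z-normalised segments are invariant to amplitude rescaling", {
  fix <- vg_clean_record()
  rec <- fix$record; tr <- fix$truth
  rp <- tibble::tibble(time = tr$r_times)
  segs1 <- preprocess_dus(rec, rp)
  rec2 <- rec
  rec2$dus <- rec$dus * 2
  segs2 <- preprocess_dus(rec2, rp)
  expect_equal(segs1$values[[5]], segs2$values[[5]], tolerance = 1e-8)
})

test_that("zero-beat truth renders as pure noise", {
  p <- synth_params(n_records = 1, seed = 5, duration = 5)
  tr <- sample_cohort(p)$truth[[1]]
  tr$r_times <- numeric(0)
  tr$events <- tr$events[0, ]
  tr$transitional <- tr$transitional[0, ]
  rec <- render_waveforms(tr, snr_db = 10, seed = 3)
  expect_equal(length(rec$dus), 5000)
  expect_gt(sd(rec$dus), 0)  # noise floor present
  expect_equal(sum(abs(rec$fecg)), 0)
})

test_that("anomaly injection changes rate and amplitudes as designed", {
  p <- synth_params(n_records = 1, seed = 8, duration = 20)
  tr <- sample_cohort(p)$truth[[1]]

  tach <- inject_anomaly(tr, "tachycardia")
  expect_gte(tach$fhr_bpm, 180)
  expect_gte(min(60 / diff(tach$r_times)), 170)  # rendered rate matches
  # events still fit inside the shortened cycle
  expect_lt(max(tach$events$Mo), 0.95 * tach$mean_rr)

  brad <- inject_anomaly(tr, "bradycardia")
  expect_lte(brad$fhr_bpm, 70)
  expect_equal(brad$events$Mc[1], tr$events$Mc[1])  # phases untouched
  expect_equal(brad$intervals, tr$intervals)  # valve timings untouched

  sup <- inject_anomaly(tr, "valve_suppress", event = "Ao")
  expect_true("Ao" %in% sup$suppressed)
  rec_sup <- render_waveforms(sup, snr_db = Inf, seed = 2)
  rec_all <- render_waveforms(tr, snr_db = Inf, seed = 2)
  ev <- truth_event_times(tr)
  i_ao <- round(ev$Ao[3] * 1000) + 1
  expect_lt(max(abs(rec_sup$dus[(i_ao - 5):(i_ao + 5)])),
            max(abs(rec_all$dus[(i_ao - 5):(i_ao + 5)])))

  expect_error(inject_anomaly(tr, "nonsense"))
})

test_that("bradycardia moves the FHRV-based GA estimate more than the valve-based one", {
  p <- synth_params(n_records = 1, seed = 8, duration = 20)
  tr <- sample_cohort(p)$truth[[1]]
  brad <- inject_anomaly(tr, "bradycardia")
  est_valve <- function(t) predict_ga(ga_model_valve(), data.frame(
    EDT = t$intervals[["EDT"]], ICT = t$intervals[["ICT"]], VFT = t$intervals[["VFT"]]))
  est_fhrv <- function(t) predict_ga(ga_model_fhrv(), data.frame(
    mRR = t$mean_rr, SDRR = 0.025 * t$mean_rr))
  d_valve <- abs(est_valve(brad) - est_valve(tr))
  d_fhrv <- abs(est_fhrv(brad) - est_fhrv(tr))
  expect_lt(d_valve, d_fhrv)
})
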