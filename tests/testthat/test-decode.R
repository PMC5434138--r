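# Peak candidates, clustering, constrained Viterbi, valve-time extraction.

test_that("peak candidates find separated bumps and skip monotone ramps", {
  fs <- 1000
  t <- 0:399
  seg <- exp(-(t - 30)^2 / 18) + 0.8 * exp(-(t - 70)^2 / 18)
  seg <- (seg - mean(seg)) / sd(seg)
  cand <- detect_peaks(seg, fs)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$phase_ms, c(30, 70), tolerance = 2)
  expect_true(all(diff(cand$phase_ms) > 0))
  ramp <- ((1:400) - mean(1:400)) / sd(1:400)
  expect_equal(nrow(detect_peaks(ramp, fs)), 0L)
})

test_that("K-means clustering honours its identities and determinism", {
  set.seed(7)
  mk_seg <- function(center) {
    t <- 0:399
    v <- exp(-(t - center)^2 / 50) + rnorm(400, 0, 0.01)
    (v - mean(v)) / sd(v)
  }
  segs <- tibble::tibble(
    beat_index = 1:30, onset_r_time = 0, rr_ms = 400,
    values = lapply(rep(c(50, 150, 250, 320, 200, 100), 5), mk_seg)
  )
  m1 <- fit_clusters(segs, k = 6, seed = 3)
  m2 <- fit_clusters(segs, k = 6, seed = 3)
  expect_identical(m1$centroids, m2$centroids)
  # k = 1: the centroid is the mean resampled segment
  m3 <- fit_clusters(segs, k = 1, seed = 1)
  X <- t(vapply(segs$values, valvegest:::resample_segment,
                numeric(512), len = 512))
  expect_equal(as.numeric(m3$centroids[1, ]), colMeans(X), tolerance = 1e-9)
  # six well-separated morphologies recover the true partition
  truth_part <- rep(1:6, 5)
  got <- vapply(segs$values, assign_cluster, numeric(1), model = m1)
  tab <- table(truth_part, got)
  expect_equal(sum(apply(tab, 1, max)), 30)  # perfect agreement up to relabel
  # a centroid maps to its own index; equidistant ties take the lowest index
  expect_equal(assign_cluster(m1$centroids[4, ], m1), 4)
  mtie <- m1
  mtie$centroids[2, ] <- mtie$centroids[5, ]
  expect_equal(assign_cluster(mtie$centroids[5, ], mtie), 2)
  expect_error(fit_clusters(segs[1:4, ], k = 6), "fewer segments")
})

test_that("Viterbi equals exhaustive search on random constrained problems", {
  set.seed(8)
  labs <- event_labels()
  for (i in 1:60) {
    n <- sample(1:6, 1)
    emis <- matrix(runif(n * 8), n, 8, dimnames = list(NULL, labs))
    emis <- emis / rowSums(emis)
    tr <- matrix(runif(64), 8, 8, dimnames = list(labs, labs))
    tr <- tr / rowSums(tr)
    init <- runif(8); init <- init / sum(init)
    expect_identical(viterbi_decode(emis, tr, init),
                     brute_force_decode(emis, tr, init))
  }
})

test_that("each valve label is used at most once per beat", {
  labs <- event_labels()
  n <- 6
  # emissions overwhelmingly favour Mc everywhere
  emis <- matrix(1e-4, n, 8, dimnames = list(NULL, labs))
  emis[, "Mc"] <- 1
  emis <- emis / rowSums(emis)
  tr <- matrix(1 / 8, 8, 8, dimnames = list(labs, labs))
  init <- setNames(rep(1 / 8, 8), labs)
  path <- viterbi_decode(emis, tr, init)
  for (v in c("Mc", "Ao", "Ac", "Mo")) expect_lte(sum(path == v), 1L)
  # a single candidate takes the argmax of initial x emission
  e1 <- matrix(runif(8), 1, 8, dimnames = list(NULL, labs))
  expect_equal(viterbi_decode(e1, tr, init),
               labs[which.max(log(init) + log(e1[1, ]))])
})

test_that("degenerate single-label training yields a single-label decoder", {
  labelled <- tibble::tibble(
    segment_id = rep(1:40, each = 2),
    cluster = 1,
    phase_ms = rep(c(30, 60), 40) + rnorm(80, 0, 1),
    phase_frac = rep(c(0.08, 0.15), 40),
    amplitude = rnorm(80, 2, 0.1),
    label = factor("T1", levels = event_labels())
  )
  hmm <- train_event_models(labelled, k = 1, min_sequences = 10)
  cand <- tibble::tibble(phase_ms = c(25, 61), amplitude = c(2, 2),
                         phase_frac = c(0.07, 0.16))
  dec <- decode_events(cand, hmm, 1)
  expect_equal(dec$label, c("T1", "T1"))
  # transition rows always sum to 1
  expect_equal(rowSums(hmm$clusters[[1]]$markov$trans), rep(1, 8),
               ignore_attr = TRUE)
})

test_that("valve-time extraction enforces presence and ordering", {
  full <- tibble::tibble(phase_ms = c(20, 55, 230, 290),
                         label = c("Mc", "Ao", "Ac", "Mo"))
  vt <- extract_valve_times(full)
  expect_true(vt$complete)
  expect_equal(vt$Ao_ms, 55)
  # missing Ao: beat incomplete, others still reported
  no_ao <- full[-2, ]
  vt2 <- extract_valve_times(no_ao)
  expect_false(vt2$complete)
  expect_true(is.na(vt2$Ao_ms))
  expect_equal(vt2$Mc_ms, 20)
  # out-of-order decode flags the beat
  swapped <- tibble::tibble(phase_ms = c(20, 230, 55, 290),
                            label = c("Mc", "Ao", "Ac", "Mo"))
  expect_false(extract_valve_times(swapped)$complete)
})

test_that("the trained decoder recovers events on a held-out noiseless record", {
  models <- vg_models()
  fix <- vg_clean_record()
  rec <- fix$record; tr <- fix$truth
  segs <- preprocess_dus(rec, tibble::tibble(time = tr$r_times))
  out <- decode_record(segs, models$decoder, rec$fs)
  expect_gte(mean(out$complete), 0.95)
  ev <- tr$events
  errs <- c()
  for (i in which(out$complete)) {
    b <- out$beat_index[i]
    for (e in c("Mc", "Ao", "Ac", "Mo")) {
      errs <- c(errs, abs(out[[paste0(e, "_ms")]][i] - ev[[e]][ev$beat_index == b]))
    }
  }
  expect_lt(max(errs), 10)
  # decoding is deterministic given the trained model
  out2 <- decode_record(segs, models$decoder, rec$fs)
  expect_identical(out, out2)
})

test_that("suppressing the aortic burst lowers Ao recovery below the clean rate", {
  models <- vg_models()
  fix <- vg_clean_record()
  tr <- fix$truth
  sup <- inject_anomaly(tr, "valve_suppress", event = "Ao")
  rec_sup <- render_waveforms(sup, snr_db = 25, seed = 77)
  rec_cln <- render_waveforms(tr, snr_db = 25, seed = 77)
  rp <- tibble::tibble(time = tr$r_times)
  rate_ao <- function(rec) {
    out <- decode_record(preprocess_dus(rec, rp), models$decoder, rec$fs)
    ev <- tr$events
    hit <- 0
    for (i in seq_len(nrow(out))) {
      b <- out$beat_index[i]
      tru <- ev$Ao[ev$beat_index == b]
      if (!is.na(out$Ao_ms[i]) && abs(out$Ao_ms[i] - tru) <= 15) hit <- hit + 1
    }
    hit / nrow(out)
  }
  expect_lt(rate_ao(rec_sup), rate_ao(rec_cln))
})
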