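# Beat-interval arithmetic and record-level aggregation.

mk_events <- function(n_beats = 3, rr_ms = 430, Mc = 30, Ao = 60, Ac = 230,
                      Mo = 290, q = 20) {
  list(
    events = tibble::tibble(
      beat_index = seq_len(n_beats),
      onset_r_time = (seq_len(n_beats) - 1) * rr_ms / 1000,
      rr_ms = rr_ms,
      Mc_ms = Mc, Ao_ms = Ao, Ac_ms = Ac, Mo_ms = Mo,
      complete = TRUE
    ),
    q_onsets = tibble::tibble(beat_index = seq_len(n_beats), q_offset_ms = q)
  )
}

test_that("interval arithmetic matches the hand-worked beat", {
  fx <- mk_events()
  bi <- compute_beat_intervals(fx$events, fx$q_onsets)
  b1 <- bi[1, ]
  expect_equal(b1$EDT, 50)   # Mc 30 + Q offset 20
  expect_equal(b1$ICT, 30)
  expect_equal(b1$VET, 170)
  expect_equal(b1$IRT, 60)
  expect_equal(b1$VFT, 170)  # next R (430) + next Mc (30) - (R 0 + Mo 290)
  expect_equal(b1$PEP, 80)
  expect_equal(b1$STI, 250)
  # conservation: ICT + VET + IRT + VFT = RR, exactly
  expect_identical(b1$ICT + b1$VET + b1$IRT + b1$VFT, 430)
  # linear identities exact whenever defined
  expect_identical(b1$PEP - (b1$EDT + b1$ICT), 0)
  expect_identical(b1$STI - (b1$EDT + b1$ICT + b1$VET), 0)
  # the last beat has no successor: VFT absent
  expect_true(is.na(bi$VFT[nrow(bi)]))
})

test_that("a missing aortic opening removes exactly the dependent intervals", {
  fx <- mk_events()
  fx$events$Ao_ms[2] <- NA
  bi <- compute_beat_intervals(fx$events, fx$q_onsets)
  b2 <- bi[2, ]
  expect_true(is.na(b2$ICT) && is.na(b2$VET) && is.na(b2$PEP) && is.na(b2$STI))
  expect_false(is.na(b2$EDT))
  expect_false(is.na(b2$IRT))
  expect_false(is.na(b2$VFT))
})

test_that("non-positive intervals are rejected and flagged", {
  fx <- mk_events()
  fx$events$Ao_ms[1] <- 25  # before Mc: ICT would be negative
  bi <- compute_beat_intervals(fx$events, fx$q_onsets)
  expect_true(is.na(bi$ICT[1]))
  expect_true(bi$flagged[1])
})

test_that("aggregation is a median, robust and order-invariant", {
  fx <- mk_events(n_beats = 21)
  bi <- compute_beat_intervals(fx$events, fx$q_onsets)
  agg <- aggregate_record(bi)
  expect_equal(agg$EDT, 50)
  expect_equal(agg$EDT_mad, 0)
  expect_equal(agg$n_beats_used, 21)
  # one outlier beat leaves the median untouched
  bi2 <- bi
  bi2$EDT[5] <- 500
  expect_equal(aggregate_record(bi2)$EDT, 50)
  # permutation invariance
  perm <- sample(nrow(bi2))
  expect_equal(aggregate_record(bi2[perm, ])$EDT, aggregate_record(bi2)$EDT)
  expect_equal(aggregate_record(bi2[perm, ])$VFT, aggregate_record(bi2)$VFT)
  # quality mask excludes beats; none accepted marks the record unusable
  agg0 <- aggregate_record(bi, quality_mask = rep(FALSE, nrow(bi)))
  expect_false(agg0$usable)
})

test_that("decoded intervals match the generating values on a clean record", {
  models <- vg_models()
  fix <- vg_clean_record()
  rec <- fix$record; tr <- fix$truth
  ann <- annotate_fecg(rec)
  segs <- preprocess_dus(rec, ann$r_peaks)
  dec <- decode_record(segs, models$decoder, rec$fs)
  bi <- compute_beat_intervals(dec, ann$q_onsets)
  agg <- aggregate_record(bi)
  expect_lt(abs(agg$EDT - tr$intervals[["EDT"]]), 5)
  expect_lt(abs(agg$ICT - tr$intervals[["ICT"]]), 5)
  expect_lt(abs(agg$VFT - tr$intervals[["VFT"]]), 5)
})
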