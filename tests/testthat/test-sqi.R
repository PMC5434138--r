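# DUS quality indices and the kernel-density Naive Bayes classifier.

# helper: z-normalise
zn <- function(x) (x - mean(x)) / sd(x)

test_that("power concentrated in the valve ranges drives sqi1 toward 1", {
  fs <- 1000
  n <- 400
  seg <- rnorm(n, 0, 1e-3)
  for (rg in valve_ranges()) {
    idx <- (rg[1]:rg[2]) + 1
    seg[idx] <- seg[idx] + sin(seq_along(idx))
  }
  sq <- compute_sqi_vector(zn(seg), fs)
  expect_gt(sq$sqi1, 0.95)
  # direct power-ratio oracle on the same construction
  t_ms <- 0:(n - 1)
  inside <- rep(FALSE, n)
  for (rg in valve_ranges()) inside <- inside | (t_ms >= rg[1] & t_ms <= rg[2])
  z <- zn(seg)
  r <- mean(z[inside]^2) / mean(z[!inside]^2)
  expect_equal(sq$sqi1, r / (1 + r), tolerance = 1e-9)
  expect_error(compute_sqi_vector(zn(rnorm(300)), fs), "350 ms")
})

test_that("sample entropy separates white noise from a periodic signal", {
  set.seed(2)
  noise <- rnorm(400)
  periodic <- sin(2 * pi * (1:400) / 40)
  for (p in list(c(1, 0.2), c(2, 0.2))) {
    expect_gt(sample_entropy(noise, p[1], p[2]),
              sample_entropy(periodic, p[1], p[2]))
  }
  sq_n <- compute_sqi_vector(zn(noise), 1000)
  sq_p <- compute_sqi_vector(zn(periodic), 1000)
  expect_true(all(c(sq_n$sqi8, sq_n$sqi9, sq_n$sqi10, sq_n$sqi11) >
                  c(sq_p$sqi8, sq_p$sqi9, sq_p$sqi10, sq_p$sqi11)))
})

test_that("an exactly periodic segment has sqi12 of zero", {
  seg <- zn(rep(sin(2 * pi * (1:20) / 20), 20))  # period 20 divides window 20
  sq <- compute_sqi_vector(seg, 1000)
  expect_lt(sq$sqi12, 1e-8)
})

test_that("min-max normalisation maps extremes, clips, and is idempotent", {
  set.seed(3)
  raw <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(24), 2)),
                                    paste0("sqi", 1:12)))
  nm <- normalize_sqi(raw)
  for (f in paste0("sqi", 1:12)) {
    expect_setequal(nm[[f]], c(0, 1))
  }
  # inference above the training max clips to 1
  b <- attr(nm, "bounds")
  probe <- raw[1, ]
  probe$sqi1 <- b$max[b$feature == "sqi1"] + 10
  expect_equal(normalize_sqi(probe, bounds = b)$sqi1, 1)
  # idempotent when re-normalised with [0,1] bounds
  b01 <- tibble::tibble(feature = paste0("sqi", 1:12), min = 0, max = 1)
  expect_equal(as.data.frame(normalize_sqi(nm, bounds = b01)),
               as.data.frame(nm), ignore_attr = TRUE)
  # constant feature column maps to 0.5
  raw2 <- raw
  raw2$sqi5 <- c(1, 1)
  expect_equal(normalize_sqi(raw2)$sqi5, c(0.5, 0.5))
})

test_that("the KDE Naive Bayes separates well-separated classes", {
  set.seed(4)
  n <- 120
  mk <- function(mu) tibble::as_tibble(setNames(
    as.data.frame(matrix(rnorm(n * 12, mu, 0.1), n)), paste0("sqi", 1:12)))
  raw <- dplyr::bind_rows(mk(0.25), mk(0.75))  # d' = 5 per feature
  labels <- rep(c("bad", "good"), each = n)
  idx_train <- c(1:80, n + 1:80)
  nm <- normalize_sqi(raw[idx_train, ])
  model <- train_quality_classifier(nm, labels[idx_train])
  held <- setdiff(seq_len(2 * n), idx_train)
  p <- classify_quality(raw[held, ], model)
  acc <- mean((p > 0.5) == (labels[held] == "good"))
  expect_gte(acc, 0.95)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("10-fold cross-validated accuracy exceeds 0.85 on the separable fixture", {
  set.seed(5)
  n <- 200
  mk <- function(mu) tibble::as_tibble(setNames(
    as.data.frame(matrix(rnorm(n * 12, mu, 0.15), n)), paste0("sqi", 1:12)))
  raw <- dplyr::bind_rows(mk(0.3), mk(0.7))
  labels <- rep(c("bad", "good"), each = n)
  folds <- sample(rep(1:10, length.out = 2 * n))
  accs <- vapply(1:10, function(k) {
    tr <- folds != k
    nm <- normalize_sqi(raw[tr, ])
    model <- train_quality_classifier(nm, labels[tr])
    p <- classify_quality(raw[!tr, ], model)
    mean((p > 0.5) == (labels[!tr] == "good"))
  }, numeric(1))
  expect_gte(mean(accs), 0.85)
})

test_that("uninformative likelihoods return the class prior", {
  # both classes drawn from the same distribution: posterior ~ prior
  set.seed(6)
  n <- 400
  raw <- tibble::as_tibble(setNames(
    as.data.frame(matrix(runif(2 * n * 12), 2 * n)), paste0("sqi", 1:12)))
  labels <- rep(c("bad", "good"), each = n)    # priors (0.5, 0.5)
  nm <- normalize_sqi(raw)
  model <- train_quality_classifier(nm, labels)
  p <- classify_quality(raw, model)
  expect_equal(mean(p), 0.5, tolerance = 0.05)
  expect_error(train_quality_classifier(nm, rep("good", 2 * n)), "both classes")
})

test_that("record score is the arithmetic mean of segment posteriors", {
  models <- vg_models()
  fix <- vg_clean_record()
  rp <- tibble::tibble(time = fix$truth$r_times)
  segs <- preprocess_dus(fix$record, rp)
  q <- dus_quality(segs, models$quality, fix$record$fs)
  expect_equal(q$record_score, mean(q$segments$quality_prob))
  expect_true(all(q$segments$quality_prob >= 0 & q$segments$quality_prob <= 1))
})
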