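# Shipped GA models, stepwise regression, LOO CV, agreement analytics.

test_that("the shipped polynomial models evaluate correctly", {
  # hand arithmetic oracles on the printed coefficients
  expect_equal(predict_ga(ga_model_valve(),
                          data.frame(EDT = 25, ICT = 30, VFT = 180)),
               23.46, tolerance = 1e-9)
  expect_equal(predict_ga(ga_model_fhrv(), data.frame(mRR = 400, SDRR = 20)),
               4.788 + 0.064 * 400 + 0.120 * 20, tolerance = 1e-9)
  expect_equal(predict_ga(ga_model_valve(),
                          data.frame(EDT = 0, ICT = 0, VFT = 0)),
               -276.810)
  expect_error(predict_ga(ga_model_valve(), data.frame(EDT = 25, ICT = 30)),
               "missing variable")
  expect_error(predict_ga(ga_model_valve(),
                          data.frame(EDT = NA, ICT = 30, VFT = 100)),
               "non-finite")
})

test_that("shipped coefficient tables are internally consistent", {
  chk <- published_model_self_check()
  # estimate/SE reproduces the printed t at printed precision for all rows
  expect_true(all(chk$consistent_printed))
  # and within 0.05 for all but the one row whose SE rounds too coarsely
  expect_gte(sum(chk$consistent), 8)
  row_edt <- chk[chk$term == "EDT" & chk$model == "valve", ]
  expect_equal(row_edt$t_ratio, 5.496 / 1.215, tolerance = 1e-12)
  expect_lt(abs(row_edt$t_ratio - 4.525), 0.05)
})

test_that("stepwise selection keeps the informative predictor only", {
  set.seed(11)
  n <- 200
  d <- data.frame(x1 = runif(n), x2 = runif(n))
  d$ga <- 2 * d$x1 + rnorm(n, 0, 0.1)
  fit <- stepwise_fit(d, response = "ga")
  expect_setequal(fit$model$terms, c("(Intercept)", "x1"))
})

test_that("a constant response yields the intercept-only model", {
  d <- data.frame(x1 = runif(50), ga = 7)
  fit <- suppressWarnings(stepwise_fit(d, response = "ga"))
  expect_equal(fit$model$terms, "(Intercept)")
  expect_equal(suppressWarnings(glance(fit))$r.squared, 0)
})

test_that("stepwise refit recovers the generating five-term specification", {
  p <- synth_params(n_records = 4000, seed = 77, clip_ga = FALSE)
  co <- sample_cohort(p, truths = FALSE)
  d <- as.data.frame(co[, c("ga", "EDT", "ICT", "VFT")])
  fit <- stepwise_fit(d, response = "ga")
  expect_true(all(c("EDT", "ICT", "VFT", "EDT:ICT", "ICT:VFT") %in%
                  fit$model$terms))
  # tidy/glance report matches the underlying least-squares fit
  td <- tidy(fit)
  expect_equal(td$statistic, td$estimate / td$std.error, tolerance = 1e-9)
  g <- glance(fit)
  expect_true(g$adj.r.squared <= g$r.squared)
  expect_gte(g$r.squared, 0)
})

test_that("noiseless data from a term subset is selected exactly and LOO is exact", {
  set.seed(12)
  n <- 80
  d <- data.frame(x1 = runif(n, 1, 2), x2 = runif(n, 1, 2))
  d$ga <- 3 + 1.5 * d$x1 - 2 * d$x2
  fit <- suppressWarnings(stepwise_fit(d, response = "ga"))
  expect_setequal(fit$model$terms, c("(Intercept)", "x1", "x2"))
  cv <- suppressWarnings(loo_cv(d, response = "ga"))
  expect_lt(cv$mae, 1e-6)
  # MAE is order-invariant
  cv2 <- suppressWarnings(loo_cv(d[rev(seq_len(n)), ], response = "ga"))
  expect_equal(cv2$mae, cv$mae, tolerance = 1e-9)
})

test_that("Bland-Altman agreement matches its definition", {
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3))$bias, 0)
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3))$loa_upper, 0)
  ba2 <- bland_altman(c(30, 32, 34) + 2, c(30, 32, 34))
  expect_equal(ba2$bias, 2)
  expect_equal(c(ba2$loa_lower, ba2$loa_upper), c(2, 2))
  # Monte-Carlo: N(0,1) differences give LoA near +-1.96
  set.seed(13)
  ref <- rnorm(10000, 30, 5)
  ba3 <- bland_altman(ref + rnorm(10000), ref)
  expect_equal(ba3$loa_lower, -1.96, tolerance = 0.05)
  expect_equal(ba3$loa_upper, 1.96, tolerance = 0.05)
})

test_that("partial correlation equals the residual-method oracle", {
  set.seed(14)
  n <- 60
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- z1 + 0.5 * z2 + rnorm(n)
  y <- -z1 + 0.3 * z2 + 0.4 * x + rnorm(n)
  res <- error_correlations(y, data.frame(x = x, z1 = z1, z2 = z2))
  # brute-force residual oracle for the x row
  rx <- residuals(lm(x ~ z1 + z2))
  ry <- residuals(lm(y ~ z1 + z2))
  expect_equal(res$partial_r[res$covariate == "x"], cor(rx, ry),
               tolerance = 1e-12)
  # precision-matrix formulation as an independent check
  S <- solve(cor(cbind(y, x, z1, z2)))
  expect_equal(res$partial_r[res$covariate == "x"],
               -S[1, 2] / sqrt(S[1, 1] * S[2, 2]), tolerance = 1e-9)
  # plain correlation column matches cor.test
  expect_equal(res$r[res$covariate == "x"], unname(cor(y, x)), tolerance = 1e-12)
  expect_equal(error_correlations(x, data.frame(v = x))$r, 1)
})

test_that("partial equals plain correlation under independent controls", {
  set.seed(15)
  n <- 10000
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  ctl <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
  res <- error_correlations(y, cbind(data.frame(x = x), ctl))
  row <- res[res$covariate == "x", ]
  expect_equal(row$partial_r, row$r, tolerance = 0.03)
})

test_that("abnormal-case screening flags impossible estimates", {
  d <- tibble::tibble(
    record_id = c("a", "b"),
    EDT = c(30, 44), ICT = c(35, 44), VFT = c(180, 130),
    mRR = c(420, 900), SDRR = c(12, 30),
    ga_crl = c(30, 28)
  )
  out <- evaluate_abnormal(d)
  expect_equal(out$valve_error, out$valve_est - d$ga_crl)
  expect_equal(out$valve_flagged, out$valve_est > 42)
  # a 46-week estimate is flagged, a 35-week one is not
  d2 <- tibble::tibble(EDT = 25, ICT = 30, VFT = 180, mRR = 400, SDRR = 20,
                       ga_crl = 30)
  out2 <- evaluate_abnormal(d2)
  expect_false(out2$valve_flagged)      # 23.5 weeks
  out3 <- evaluate_abnormal(dplyr::mutate(d2, mRR = 1000, SDRR = 50))
  expect_true(out3$fhrv_est > 42 && out3$fhrv_flagged)
})

test_that("the bundled abnormal reference cohort loads intact", {
  ab <- abnormal_cohort_reference()
  expect_equal(nrow(ab), 30)
  expect_true(all(c("crl_ga", "valve_est", "valve_error", "fhr_est",
                    "fhr_error", "fhr_bpm", "abnormality") %in% names(ab)))
  expect_true(all(ab$fhr_bpm >= 60 & ab$fhr_bpm <= 220))
})
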