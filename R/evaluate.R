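# Evaluation analytics: leave-one-out CV, quality-threshold sweep,
# Bland-Altman agreement, error correlations, abnormal-case screening.

#' Leave-one-out cross-validated GA estimation
#'
#' For each record, the full selection/fit is re-run on the remaining
#' `n - 1` records and the held-out record predicted, so the reported term
#' sets may differ fold to fold when the signal is weak.  Folds whose
#' design is degenerate are flagged and excluded from the MAE (count
#' reported).
#'
#' @param data data frame with the response and predictors (one row per
#'   record).
#' @param response response column name (GA weeks).
#' @param variables predictor names (default: all other numeric columns).
#' @param terms optional fixed term list (skips stepwise selection, see
#'   [stepwise_fit()]).
#' @param p_enter,p_remove stepwise thresholds.
#' @return list of class `loo_cv`: `records` tibble (`estimate`, `error`,
#'   `abs_error` per row), `mae`, `n_failed`.
#' @export
loo_cv <- function(data, response = "ga", variables = NULL, terms = NULL,
                   p_enter = 0.05, p_remove = 0.10) {
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n < 10) stop("need >= 10 records", call. = FALSE)
  est <- rep(NA_real_, n)
  failed <- logical(n)
  sel_terms <- vector("list", n)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      stepwise_fit(data[-i, , drop = FALSE], response = response,
                   variables = variables, terms = terms,
                   p_enter = p_enter, p_remove = p_remove),
      error = function(e) NULL
    )
    if (is.null(fit_i)) { failed[i] <- TRUE; next }
    est[i] <- tryCatch(predict(fit_i, data[i, , drop = FALSE]),
                       error = function(e) NA_real_)
    if (is.na(est[i])) failed[i] <- TRUE
    sel_terms[[i]] <- fit_i$model$terms
  }
  err <- est - data[[response]]
  structure(
    list(
      records = tibble::tibble(
        estimate = est, reference = data[[response]],
        error = err, abs_error = abs(err), failed = failed,
        terms = sel_terms
      ),
      mae = mean(abs(err)[!failed]),
      n_failed = sum(failed)
    ),
    class = "loo_cv"
  )
}

#' @export
print.loo_cv <- function(x, ...) {
  cat(sprintf("<loo_cv> n = %d, MAE = %.3f wk, failed folds = %d\n",
              nrow(x$records), x$mae, x$n_failed))
  invisible(x)
}

#' Quality-threshold sweep of the LOO error
#'
#' For every (fECG, DUS) threshold pair, records with `fecg_sqi > t_f` and
#' `dus_sqi > t_d` are retained and the leave-one-out MAE recomputed on
#' the retained subset.  Cells with fewer than `min_n` retained records
#' are marked unevaluable.
#'
#' @param data cohort with columns `fecg_sqi`, `dus_sqi` (scores in
#'   \[0, 1\]), the response and predictors.
#' @param thresholds_f,thresholds_d numeric threshold grids.
#' @param min_n minimum retained records per cell (default 10).
#' @inheritParams loo_cv
#' @return tibble of class `quality_sweep`: `t_fecg`, `t_dus`, `n_retained`,
#'   `n_excluded`, `mae`, `evaluable`.
#' @export
quality_threshold_sweep <- function(data, thresholds_f, thresholds_d,
                                    response = "ga", variables = NULL,
                                    terms = NULL, min_n = 10,
                                    p_enter = 0.05, p_remove = 0.10) {
  data <- as.data.frame(data)
  stopifnot(all(data$fecg_sqi >= 0 & data$fecg_sqi <= 1),
            all(data$dus_sqi >= 0 & data$dus_sqi <= 1))
  grid <- tidyr::expand_grid(t_fecg = thresholds_f, t_dus = thresholds_d)
  res <- purrr::pmap_dfr(grid, function(t_fecg, t_dus) {
    keep <- data$fecg_sqi > t_fecg & data$dus_sqi > t_dus
    n_ret <- sum(keep)
    if (n_ret < min_n) {
      return(tibble::tibble(t_fecg = t_fecg, t_dus = t_dus,
                            n_retained = n_ret, n_excluded = nrow(data) - n_ret,
                            mae = NA_real_, evaluable = FALSE))
    }
    cv <- loo_cv(data[keep, , drop = FALSE], response = response,
                 variables = variables, terms = terms,
                 p_enter = p_enter, p_remove = p_remove)
    tibble::tibble(t_fecg = t_fecg, t_dus = t_dus,
                   n_retained = n_ret, n_excluded = nrow(data) - n_ret,
                   mae = cv$mae, evaluable = TRUE)
  })
  class(res) <- c("quality_sweep", class(res))
  res
}

#' Bland-Altman agreement between estimated and reference GA
#'
#' @param estimates,references numeric vectors of equal length (>= 2),
#'   weeks.
#' @return one-row tibble of class `bland_altman`: `bias` (mean of
#'   estimate - reference), `sd`, `loa_lower`, `loa_upper`
#'   (bias -/+ 1.96 SD), `n`; the paired differences are kept in the
#'   `"differences"` attribute for plotting.
#' @export
bland_altman <- function(estimates, references) {
  stopifnot(length(estimates) == length(references), length(estimates) >= 2)
  d <- estimates - references
  s <- sd(d)
  out <- tibble::tibble(
    bias = mean(d), sd = s,
    loa_lower = mean(d) - 1.96 * s, loa_upper = mean(d) + 1.96 * s,
    n = length(d)
  )
  attr(out, "differences") <- tibble::tibble(
    mean_ga = (estimates + references) / 2, difference = d
  )
  class(out) <- c("bland_altman", class(out))
  out
}

# partial correlation by regressing out controls from both variables
partial_cor_test <- function(x, y, controls) {
  k <- ncol(controls)
  rx <- residuals(lm(x ~ ., data = controls))
  ry <- residuals(lm(y ~ ., data = controls))
  r <- cor(rx, ry)
  df <- length(x) - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df))
}

#' Correlation of GA-estimation errors with covariates
#'
#' For each covariate: plain Pearson correlation (two-sided p), and the
#' partial correlation controlling for all other covariates (residual
#' method: both the error and the covariate are regressed on the controls
#' and the residuals correlated; p from a t-test on n - 2 - k df).
#'
#' @param errors numeric vector (signed or absolute errors, weeks).
#' @param covariates data frame of covariates (e.g. GA, FHR, fECG score,
#'   DUS score), n rows.
#' @return tibble: `covariate`, `r`, `p`, `partial_r`, `partial_p`.
#' @export
error_correlations <- function(errors, covariates) {
  covariates <- as.data.frame(covariates)
  n <- length(errors)
  if (n < 10) stop("need >= 10 records", call. = FALSE)
  stopifnot(nrow(covariates) == n)
  purrr::map_dfr(names(covariates), function(v) {
    ct <- cor.test(errors, covariates[[v]])
    others <- covariates[setdiff(names(covariates), v)]
    if (ncol(others)) {
      pc <- partial_cor_test(errors, covariates[[v]], others)
    } else {
      pc <- list(r = NA_real_, p = NA_real_)
    }
    tibble::tibble(covariate = v, r = unname(ct$estimate), p = ct$p.value,
                   partial_r = pc$r, partial_p = pc$p)
  })
}

#' Screen a cohort of abnormal cases
#'
#' Applies the valve-interval and FHRV GA models to each record and flags
#' estimates above 42 weeks -- physiologically impossible values that mark
#' records where the abnormality corrupts the intervals or the heart rate,
#' so the regression fails by construction.
#'
#' @param data cohort tibble with interval columns (`EDT`, `ICT`, `VFT`,
#'   ms), FHRV columns (`mRR`, `SDRR`, ms), reference `ga_crl` (weeks) and
#'   optionally `record_id` / `abnormality`.
#' @param valve_model,fhrv_model `ga_model`s (default the shipped ones).
#' @param flag_above flag threshold in weeks (default 42).
#' @return tibble: per-record `valve_est`, `valve_error`, `valve_flagged`,
#'   `fhrv_est`, `fhrv_error`, `fhrv_flagged`; summary counts in attribute
#'   `"n_flagged"`.
#' @export
evaluate_abnormal <- function(data, valve_model = ga_model_valve(),
                              fhrv_model = ga_model_fhrv(), flag_above = 42) {
  data <- tibble::as_tibble(data)
  out <- data
  out$valve_est <- predict(valve_model, data)
  out$fhrv_est <- predict(fhrv_model, data)
  out$valve_error <- out$valve_est - data$ga_crl
  out$fhrv_error <- out$fhrv_est - data$ga_crl
  out$valve_flagged <- out$valve_est > flag_above
  out$fhrv_flagged <- out$fhrv_est > flag_above
  attr(out, "n_flagged") <- c(valve = sum(out$valve_flagged),
                              fhrv = sum(out$fhrv_flagged))
  out
}

#' Bundled reference cohort of 30 abnormal cases
#'
#' Per-case CRL-based GA, valve-interval and FHR-based GA estimates with
#' their errors, mean FHR, DUS/fECG quality scores, and abnormality type
#' (arrhythmias, structural anomalies, hydrops, placental conditions).
#' Estimates above 42 weeks indicate that the abnormality broke the
#' regression's assumptions.
#'
#' @return tibble with columns `id`, `crl_ga`, `valve_est`, `valve_error`,
#'   `fhr_est`, `fhr_error`, `fhr_bpm`, `dus_sqi`, `fecg_sqi`,
#'   `abnormality`.
#' @export
abnormal_cohort_reference <- function() {
  path <- system.file("extdata", "abnormal_cohort.csv", package = "valvegest",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
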