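# DUS signal quality: twelve per-segment indices and a kernel-density
# Naive Bayes quality classifier.

#' Plausible valve-motion ranges
#'
#' Per-beat windows (ms after the segment onset, i.e. the preceding R peak)
#' in which each valve event is expected: Mc 9--44, Ao 45--90, Ac 200--260,
#' Mo 265--326 ms.
#'
#' @return named list of `c(low, high)` ms pairs, ordered Mc < Ao < Ac < Mo.
#' @export
valve_ranges <- function() {
  list(Mc = c(9, 44), Ao = c(45, 90), Ac = c(200, 260), Mo = c(265, 326))
}

#' Sample entropy
#'
#' `-log(A/B)` where `B` counts template pairs of length `m` within
#' Chebyshev tolerance `r * sd(x)` and `A` the pairs still matching at
#' length `m + 1`.  Degenerate counts are guarded with a small epsilon, so
#' highly regular signals return a large finite value rather than `Inf`.
#'
#' @param x numeric vector.
#' @param m template length (1 or 2 supported).
#' @param r tolerance as a fraction of `sd(x)`.
#' @return nonnegative scalar.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2) {
  n <- length(x)
  if (n < m + 2) return(NA_real_)
  tol <- r * sd(x)
  if (!is.finite(tol) || tol == 0) return(NA_real_)
  D <- abs(outer(x, x)) <= tol
  diag(D) <- FALSE
  count_pairs <- function(M) sum(M)
  if (m == 1) {
    B <- count_pairs(D[1:(n - 1), 1:(n - 1), drop = FALSE])
    A <- count_pairs(D[1:(n - 1), 1:(n - 1), drop = FALSE] & D[2:n, 2:n, drop = FALSE])
  } else if (m == 2) {
    B2 <- D[1:(n - 2), 1:(n - 2), drop = FALSE] & D[2:(n - 1), 2:(n - 1), drop = FALSE]
    B <- count_pairs(B2)
    A <- count_pairs(B2 & D[3:n, 3:n, drop = FALSE])
  } else {
    stop("only m = 1 or 2 supported", call. = FALSE)
  }
  eps <- 1e-12
  max(0, -log((A + eps) / (B + eps)))
}

# Hjorth parameters of a sequence.
hjorth_params <- function(x) {
  v0 <- var(x)
  d1 <- diff(x); d2 <- diff(d1)
  mob <- sqrt(var(d1) / v0)
  cmp <- sqrt(var(d2) / var(d1)) / mob
  c(activity = v0, mobility = mob, complexity = cmp)
}

# outer(x,x,"-") is what we want; define abs difference matrix cheaply
abs_outer_diff <- function(x) abs(outer(x, x, "-"))

#' Twelve DUS segment quality indices (raw, pre-normalisation)
#'
#' Computed on one z-normalised envelope segment:
#' * `sqi1`--`sqi4`: ratio of the power, number of peaks, mean peak
#'   amplitude and variance inside the union of the four valve-motion
#'   ranges to the same statistic outside, mapped `r -> r / (1 + r)` so the
#'   unbounded ratio lands in \[0, 1\] (a zero outside-statistic gives 1,
#'   flagged).
#' * `sqi5`, `sqi6`: kurtosis and skewness of the whole segment.
#' * `sqi7`: Hjorth complexity (mobility available via
#'   [hjorth_diagnostics()]).
#' * `sqi8`--`sqi11`: sample entropy with (m, r) = (1, 0.1), (1, 0.2),
#'   (2, 0.1), (2, 0.2); `r` scales with the segment SD (1 after
#'   normalisation).
#' * `sqi12`: minimum over window sizes 10, 15, ..., 100 of the ratio of
#'   the 2nd to 1st singular value of the matrix whose rows are consecutive
#'   non-overlapping windows of that size (trailing partial window
#'   dropped); 0 for an exactly periodic segment when a window size divides
#'   the period.
#'
#' @param values numeric vector, z-normalised segment.
#' @param fs sampling rate in Hz.
#' @param ranges valve ranges, default [valve_ranges()].
#' @return one-row tibble `sqi1`..`sqi12` plus `flagged` (any degenerate
#'   denominator).
#' @export
compute_sqi_vector <- function(values, fs, ranges = valve_ranges()) {
  n <- length(values)
  if (n < 0.350 * fs) stop("segment shorter than 350 ms", call. = FALSE)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  inside <- rep(FALSE, n)
  for (rg in ranges) inside <- inside | (t_ms >= rg[1] & t_ms <= rg[2])
  flagged <- FALSE
  ratio_map <- function(num, den) {
    if (!is.finite(den) || den <= 0) { flagged <<- TRUE; return(1) }
    r <- num / den
    r / (1 + r)
  }
  x_in <- values[inside]; x_out <- values[!inside]
  sqi1 <- ratio_map(mean(x_in^2), mean(x_out^2))
  pk <- find_peaks(values, min_prominence = 0.1)
  pk_in <- pk[inside[pk]]; pk_out <- pk[!inside[pk]]
  sqi2 <- ratio_map(length(pk_in), length(pk_out))
  sqi3 <- ratio_map(
    if (length(pk_in)) mean(values[pk_in]) - min(values) else 0,
    if (length(pk_out)) mean(values[pk_out]) - min(values) else 0
  )
  sqi4 <- ratio_map(var(x_in), var(x_out))
  sqi5 <- e1071::kurtosis(values)
  sqi6 <- e1071::skewness(values)
  hj <- hjorth_params(values)
  sqi7 <- hj[["complexity"]]
  sampen_grid <- list(c(1, 0.1), c(1, 0.2), c(2, 0.1), c(2, 0.2))
  se <- vapply(sampen_grid, function(p) sample_entropy(values, p[1], p[2]), numeric(1))
  sqi12 <- min(vapply(seq(10, 100, by = 5), function(w) {
    k <- n %/% w
    if (k < 2) return(NA_real_)
    M <- matrix(values[seq_len(k * w)], nrow = k, byrow = TRUE)
    sv <- svd(M, nu = 0, nv = 0)$d
    sv[2] / sv[1]
  }, numeric(1)), na.rm = TRUE)
  tibble::tibble(
    sqi1 = sqi1, sqi2 = sqi2, sqi3 = sqi3, sqi4 = sqi4,
    sqi5 = sqi5, sqi6 = sqi6, sqi7 = sqi7,
    sqi8 = se[1], sqi9 = se[2], sqi10 = se[3], sqi11 = se[4],
    sqi12 = sqi12, flagged = flagged
  )
}

#' Hjorth mobility/complexity diagnostic for a segment
#' @param values numeric vector.
#' @return named numeric vector: activity, mobility, complexity.
#' @export
hjorth_diagnostics <- function(values) hjorth_params(values)

sqi_feature_names <- paste0("sqi", 1:12)

#' Min-max normalisation of SQI feature matrices
#'
#' In training (no `bounds`), per-feature min-max bounds are computed from
#' the data and stored in the `"bounds"` attribute; at inference the stored
#' bounds are applied and values clipped to \[0, 1\].  A constant feature
#' column maps to 0.5 and is flagged.
#'
#' @param x data frame / tibble with columns `sqi1`..`sqi12`.
#' @param bounds optional bounds tibble (`feature`, `min`, `max`) from a
#'   previous call or a trained model.
#' @return tibble of normalised features with attribute `bounds`.
#' @export
normalize_sqi <- function(x, bounds = NULL) {
  x <- tibble::as_tibble(x)[sqi_feature_names]
  if (is.null(bounds)) {
    if (nrow(x) < 2) stop("need >= 2 rows to derive bounds", call. = FALSE)
    bounds <- tibble::tibble(
      feature = sqi_feature_names,
      min = unname(vapply(x, min, numeric(1), na.rm = TRUE)),
      max = unname(vapply(x, max, numeric(1), na.rm = TRUE))
    )
  }
  out <- x
  for (i in seq_along(sqi_feature_names)) {
    f <- sqi_feature_names[i]
    lo <- bounds$min[bounds$feature == f]
    hi <- bounds$max[bounds$feature == f]
    if (hi - lo <= 0) {
      out[[f]] <- rep(0.5, nrow(x))
    } else {
      out[[f]] <- pmin(pmax((x[[f]] - lo) / (hi - lo), 0), 1)
    }
  }
  attr(out, "bounds") <- bounds
  out
}

#' Train the kernel-density Naive Bayes quality classifier
#'
#' Per class and feature, the class-conditional density is a univariate
#' Gaussian kernel density over the training values with Silverman's
#' bandwidth; class priors are the label frequencies.  Posterior
#' probabilities follow from Bayes' rule under feature independence.
#'
#' @param features normalised SQI tibble (from [normalize_sqi()]); the
#'   bounds attribute is stored with the model.
#' @param labels factor/character of `"good"`/`"bad"`, one per row; both
#'   classes with >= 20 rows required.
#' @return object of class `nb_kde_model`.
#' @export
train_quality_classifier <- function(features, labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("good", "bad"))) stop("labels must be 'good'/'bad'", call. = FALSE)
  tab <- table(labels)
  if (length(tab) < 2) stop("both classes must be present", call. = FALSE)
  if (any(tab < 20)) stop("need >= 20 samples per class", call. = FALSE)
  X <- as.data.frame(features)[sqi_feature_names]
  classes <- c("bad", "good")
  dens <- lapply(classes, function(cl) {
    lapply(X[labels == cl, , drop = FALSE], function(v) {
      v <- v[is.finite(v)]
      bw <- stats::bw.nrd0(v)
      if (!is.finite(bw) || bw <= 0) bw <- 0.01
      list(values = v, bw = bw)
    })
  })
  names(dens) <- classes
  structure(
    list(densities = dens,
         priors = as.numeric(tab[classes]) / sum(tab),
         classes = classes,
         bounds = attr(features, "bounds")),
    class = "nb_kde_model"
  )
}

kde_log_lik <- function(comp, x) {
  # log mean_k dnorm(x; v_k, bw): one value per x
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(0)  # missing feature: uninformative
    log(mean(dnorm(xi, comp$values, comp$bw)) + 1e-300)
  }, numeric(1))
}

#' Posterior quality probability of segments
#'
#' @param sqi tibble of raw or normalised SQI rows (raw values are
#'   normalised with the model's stored bounds).
#' @param model trained [train_quality_classifier()] model.
#' @param normalized set `TRUE` when `sqi` is already normalised.
#' @return numeric vector: posterior probability of the `"good"` class per
#'   row.
#' @export
classify_quality <- function(sqi, model, normalized = FALSE) {
  stopifnot(inherits(model, "nb_kde_model"))
  X <- if (normalized) tibble::as_tibble(sqi)[sqi_feature_names]
       else normalize_sqi(sqi, bounds = model$bounds)
  if (normalized && any(unlist(X) < -1e-6 | unlist(X) > 1 + 1e-6, na.rm = TRUE)) {
    stop("normalized input must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(X)
  loglik <- matrix(0, n, 2, dimnames = list(NULL, model$classes))
  for (ci in seq_along(model$classes)) {
    cl <- model$classes[ci]
    for (f in sqi_feature_names) {
      loglik[, ci] <- loglik[, ci] + kde_log_lik(model$densities[[cl]][[f]], X[[f]])
    }
    loglik[, ci] <- loglik[, ci] + log(model$priors[ci])
  }
  m <- apply(loglik, 1, max)
  p <- exp(loglik - m)
  p[, "good"] / rowSums(p)
}

#' Segment- and record-level DUS quality for one record
#'
#' Computes the twelve SQIs per segment, the per-segment posterior quality,
#' and the record-level score (mean of segment posteriors).
#'
#' @param segments tibble from [segment_cycles()].
#' @param model trained `nb_kde_model`.
#' @param fs sampling rate in Hz.
#' @param ranges valve ranges.
#' @return list: `segments` (tibble of SQIs + `quality_prob`),
#'   `record_score` (scalar).
#' @export
dus_quality <- function(segments, model, fs, ranges = valve_ranges()) {
  if (!nrow(segments)) return(list(segments = tibble::tibble(), record_score = NA_real_))
  ok <- vapply(segments$values, function(v) length(v) >= 0.350 * fs, logical(1))
  sq <- purrr::map_dfr(segments$values[ok], compute_sqi_vector, fs = fs, ranges = ranges)
  sq$beat_index <- segments$beat_index[ok]
  sq$quality_prob <- classify_quality(sq, model)
  list(segments = sq, record_score = mean(sq$quality_prob))
}
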