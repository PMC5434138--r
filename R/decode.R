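# Valve-event decoding: envelope-morphology clustering, per-cluster hybrid
# SVM-HMM emissions, and Viterbi search constrained so each valve label is
# used at most once per beat.

#' The eight per-beat event labels
#'
#' Four valve events (Mc, Ao, Ac, Mo) and four transitional peak labels
#' (T1--T4).  In cycle order starting at aortic opening the chain is
#' Ao, T1, Ac, T2, Mo, T3, Mc, T4.
#' @return character vector of length 8.
#' @export
event_labels <- function() c("Mc", "Ao", "Ac", "Mo", "T1", "T2", "T3", "T4")

valve_labels <- c("Mc", "Ao", "Ac", "Mo")

#' Peak candidates of a normalised segment
#'
#' Local maxima of the smoothed envelope with prominence >= 0.3 z-units and
#' separation >= 8 ms, ordered by phase.  When the un-smoothed analytic
#' companion track is supplied, its peaks are added as extra candidates
#' (where at least 6 ms from an existing one): the 30 Hz envelope smoothing
#' cannot resolve valve doublets closer than ~25 ms, which the analytic
#' magnitude still separates.  Amplitudes are always read from the smoothed
#' envelope so the emission feature space stays homogeneous.
#'
#' @param values z-normalised envelope segment.
#' @param fs sampling rate in Hz.
#' @param rr_ms segment RR (for the cycle-fraction feature).
#' @param raw_values optional un-normalised analytic magnitude slice.
#' @return tibble: `phase_ms`, `amplitude`, `phase_frac`; possibly empty.
#' @export
detect_peaks <- function(values, fs, rr_ms = length(values) / fs * 1000,
                         raw_values = NULL) {
  sep <- max(1L, round(0.008 * fs))
  idx <- find_peaks(values, min_prominence = 0.3, min_separation = sep)
  if (!is.null(raw_values) && length(raw_values) == length(values)) {
    s <- sd(raw_values)
    if (is.finite(s) && s > 0) {
      zr <- (raw_values - mean(raw_values)) / s
      extra <- find_peaks(zr, min_prominence = 0.3, min_separation = sep)
      if (length(idx)) {
        near <- vapply(extra, function(i) min(abs(i - idx)), numeric(1))
        extra <- extra[near >= round(0.006 * fs)]
      }
      idx <- sort(unique(c(idx, extra)))
    }
  }
  tibble::tibble(
    phase_ms = (idx - 1) / fs * 1000,
    amplitude = values[idx],
    phase_frac = (idx - 1) / fs * 1000 / rr_ms
  )
}

# --- morphology clustering --------------------------------------------------

resample_segment <- function(values, len) {
  approx(seq_along(values), values, xout = seq(1, length(values), length.out = len))$y
}

#' Cluster segments into k envelope morphologies
#'
#' Segments are linearly resampled to a common template length and
#' partitioned by K-means (Euclidean metric, `nstart` restarts, best
#' within-cluster sum of squares kept).  Deterministic given `seed`.
#'
#' @param segments tibble from [segment_cycles()] (list-column `values`).
#' @param k number of clusters (default 6).
#' @param seed integer seed.
#' @param template_len resampling length (default 512).
#' @param nstart K-means restarts (default 10).
#' @return object of class `cluster_model` with fields `centroids`
#'   (k x template_len matrix) and `template_len`.
#' @export
fit_clusters <- function(segments, k = 6, seed = 1, template_len = 512, nstart = 10) {
  if (nrow(segments) < k) stop("fewer segments than clusters", call. = FALSE)
  X <- t(vapply(segments$values, resample_segment, numeric(template_len), len = template_len))
  set.seed(seed)
  km <- kmeans(X, centers = k, nstart = nstart, iter.max = 50)
  structure(
    list(centroids = km$centers, template_len = template_len, k = k,
         withinss = sum(km$withinss)),
    class = "cluster_model"
  )
}

#' Nearest-centroid cluster assignment
#'
#' @param values one segment (numeric vector), resampled internally.
#' @param model [fit_clusters()] model.
#' @return cluster index (ties broken toward the lowest index).
#' @export
assign_cluster <- function(values, model) {
  v <- resample_segment(values, model$template_len)
  d2 <- rowSums((model$centroids - matrix(v, nrow = nrow(model$centroids),
                                          ncol = model$template_len, byrow = TRUE))^2)
  unname(which.min(d2))
}

# --- labelling synthetic candidates for training ---------------------------

#' Label peak candidates against ground-truth event phases
#'
#' Each candidate within `tol_ms` of a true Mc/Ao/Ac/Mo phase takes that
#' valve label (nearest event wins, one candidate per event); the rest are
#' transitional, named by the inter-event gap they fall in (T4 between Mc
#' and Ao, T1 between Ao and Ac, T2 between Ac and Mo, T3 after Mo or
#' before Mc).
#'
#' @param candidates tibble from [detect_peaks()].
#' @param true_phases named vector/list with `Mc`, `Ao`, `Ac`, `Mo` in ms.
#' @param tol_ms matching tolerance (default 15).
#' @return `candidates` with an added `label` column.
#' @export
label_candidates <- function(candidates, true_phases, tol_ms = 15) {
  n <- nrow(candidates)
  lab <- rep(NA_character_, n)
  used <- character(0)
  for (ev in valve_labels) {
    d <- abs(candidates$phase_ms - true_phases[[ev]])
    d[!is.na(lab)] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_ms) {
      lab[j] <- ev
      used <- c(used, ev)
    }
  }
  trans_label <- function(p) {
    if (p < true_phases[["Mc"]]) "T3"
    else if (p < true_phases[["Ao"]]) "T4"
    else if (p < true_phases[["Ac"]]) "T1"
    else if (p < true_phases[["Mo"]]) "T2"
    else "T3"
  }
  lab[is.na(lab)] <- vapply(candidates$phase_ms[is.na(lab)], trans_label, character(1))
  candidates$label <- factor(lab, levels = event_labels())
  candidates
}

# --- hybrid SVM-HMM ---------------------------------------------------------

emission_features <- c("phase_ms", "phase_frac", "amplitude")

fit_emission_svm <- function(train) {
  labs <- droplevels(train$label)
  if (nlevels(labs) < 2) {
    return(structure(list(constant = as.character(labs[1])), class = "const_emitter"))
  }
  e1071::svm(
    x = as.matrix(train[emission_features]), y = labs,
    kernel = "radial", probability = TRUE
  )
}

emission_probs <- function(emitter, candidates) {
  labs <- event_labels()
  n <- nrow(candidates)
  P <- matrix(1e-6, n, 8, dimnames = list(NULL, labs))
  if (inherits(emitter, "const_emitter")) {
    P[, emitter$constant] <- 1
  } else {
    pr <- attr(predict(emitter, as.matrix(candidates[emission_features]),
                       probability = TRUE), "probabilities")
    P[, colnames(pr)] <- pmax(pr, 1e-6)
  }
  P / rowSums(P)
}

fit_markov <- function(label_seqs) {
  labs <- event_labels()
  trans <- matrix(1, 8, 8, dimnames = list(labs, labs))  # add-one smoothing
  init <- setNames(rep(1, 8), labs)
  for (s in label_seqs) {
    s <- as.character(s)
    if (!length(s)) next
    init[s[1]] <- init[s[1]] + 1
    if (length(s) > 1) {
      for (t in 2:length(s)) trans[s[t - 1], s[t]] <- trans[s[t - 1], s[t]] + 1
    }
  }
  list(trans = trans / rowSums(trans), init = init / sum(init))
}

#' Train per-cluster SVM-HMM event models
#'
#' For each envelope cluster, fits a multiclass SVM with probability
#' calibration over (phase, cycle fraction, amplitude) as the emission
#' model, and an add-one-smoothed label-bigram transition matrix plus
#' smoothed initial-label distribution.  Clusters with fewer than
#' `min_sequences` labelled beats fall back to a pooled (all-cluster)
#' model, flagged in `$pooled_clusters`.
#'
#' @param labelled tibble of labelled candidates: columns `segment_id`,
#'   `cluster`, `phase_ms`, `phase_frac`, `amplitude`, `label`.
#' @param k number of clusters.
#' @param min_sequences minimum labelled beats per cluster (default 30).
#' @return object of class `svmhmm`: per-cluster `emitter`, `trans`,
#'   `init`.
#' @export
train_event_models <- function(labelled, k = 6, min_sequences = 30) {
  labelled$label <- factor(as.character(labelled$label), levels = event_labels())
  seqs_of <- function(df) {
    split(df$label[order(df$segment_id, df$phase_ms)], df$segment_id[order(df$segment_id, df$phase_ms)])
  }
  pooled <- list(
    emitter = fit_emission_svm(labelled),
    markov = fit_markov(seqs_of(labelled))
  )
  per_cluster <- vector("list", k)
  pooled_clusters <- integer(0)
  for (cl in seq_len(k)) {
    sub <- labelled[labelled$cluster == cl, , drop = FALSE]
    n_seq <- length(unique(sub$segment_id))
    if (n_seq < min_sequences) {
      per_cluster[[cl]] <- pooled
      pooled_clusters <- c(pooled_clusters, cl)
    } else {
      per_cluster[[cl]] <- list(
        emitter = fit_emission_svm(sub),
        markov = fit_markov(seqs_of(sub))
      )
    }
  }
  structure(
    list(clusters = per_cluster, pooled = pooled, k = k,
         pooled_clusters = pooled_clusters),
    class = "svmhmm"
  )
}

# --- constrained decoding ---------------------------------------------------

valve_bit <- setNames(c(1L, 2L, 4L, 8L), valve_labels)

label_bits <- function() {
  b <- setNames(integer(8), event_labels())
  b[valve_labels] <- valve_bit
  b
}

#' Constrained Viterbi decoding of one candidate sequence
#'
#' Maximum a-posteriori label path: the sum of log initial, log emission
#' and log transition scores is maximised by dynamic programming over the
#' joint state (label, set of valve labels already used), which enforces
#' that each of Mc/Ao/Ac/Mo is used at most once per beat.
#'
#' @param emis n x 8 emission probability matrix (columns
#'   [event_labels()]).
#' @param trans 8 x 8 transition matrix, `init` length-8 initial
#'   distribution.
#' @param init initial label distribution.
#' @return character vector of n decoded labels.
#' @export
viterbi_decode <- function(emis, trans, init) {
  n <- nrow(emis)
  if (n == 0) return(character(0))
  labs <- event_labels()
  bits <- label_bits()
  le <- log(emis); lt <- log(trans); li <- log(init)
  NEG <- -Inf
  # score[label, mask+1] at step t
  score <- matrix(NEG, 8, 16)
  back <- array(NA_integer_, c(n, 8, 16, 2))  # prev label, prev mask+1
  for (l in 1:8) {
    m <- bits[l]
    score[l, m + 1] <- li[l] + le[1, l]
  }
  if (n > 1) {
    for (t in 2:n) {
      new <- matrix(NEG, 8, 16)
      for (pm in 0:15) {
        for (pl in 1:8) {
          s <- score[pl, pm + 1]
          if (s == NEG) next
          for (l in 1:8) {
            b <- bits[l]
            if (b != 0L && bitwAnd(pm, b) != 0L) next
            nm <- bitwOr(pm, b)
            v <- s + lt[pl, l] + le[t, l]
            if (v > new[l, nm + 1]) {
              new[l, nm + 1] <- v
              back[t, l, nm + 1, ] <- c(pl, pm + 1L)
            }
          }
        }
      }
      score <- new
    }
  }
  best <- which(score == max(score), arr.ind = TRUE)[1, ]
  path <- integer(n)
  l <- best[1]; m <- best[2]
  path[n] <- l
  if (n > 1) {
    for (t in n:2) {
      prev <- back[t, l, m, ]
      path[t - 1] <- prev[1]
      l <- prev[1]; m <- prev[2]
    }
  }
  labs[path]
}

#' Brute-force constrained path search (reference implementation)
#'
#' Exhaustively scores all `8^n` label paths (valve labels at most once)
#' and returns the best.  Exponential; intended as an independent oracle
#' for [viterbi_decode()] on short sequences.
#'
#' @inheritParams viterbi_decode
#' @param max_n refuse sequences longer than this (default 7).
#' @return character vector of n labels.
#' @export
brute_force_decode <- function(emis, trans, init, max_n = 7) {
  n <- nrow(emis)
  if (n == 0) return(character(0))
  if (n > max_n) stop("sequence too long for brute force", call. = FALSE)
  labs <- event_labels()
  paths <- as.matrix(expand.grid(rep(list(1:8), n)))
  # constraint: each valve label at most once
  ok <- rep(TRUE, nrow(paths))
  for (v in 1:4) ok <- ok & (rowSums(paths == v) <= 1L)
  paths <- paths[ok, , drop = FALSE]
  le <- log(emis); lt <- log(trans); li <- log(init)
  sc <- li[paths[, 1]] + le[cbind(1, paths[, 1])]
  if (n > 1) {
    for (t in 2:n) {
      sc <- sc + lt[cbind(paths[, t - 1], paths[, t])] + le[cbind(t, paths[, t])]
    }
  }
  labs[paths[which.max(sc), ]]
}

#' Decode the events of one segment
#'
#' @param candidates tibble from [detect_peaks()].
#' @param model `svmhmm` from [train_event_models()].
#' @param cluster cluster index of the segment.
#' @return `candidates` with a `label` column of decoded labels (empty
#'   tibble in, empty out).
#' @export
decode_events <- function(candidates, model, cluster) {
  if (!nrow(candidates)) {
    candidates$label <- character(0)
    return(candidates)
  }
  cm <- model$clusters[[cluster]]
  emis <- emission_probs(cm$emitter, candidates)
  candidates$label <- viterbi_decode(emis, cm$markov$trans, cm$markov$init)
  candidates
}

#' Extract valve-event phases from a decoded sequence
#'
#' A beat is complete when all four valve labels are present and ordered
#' Mc < Ao < Ac < Mo; otherwise it is marked incomplete (intervals needing
#' a missing event stay unavailable, the others remain computable).
#'
#' @param decoded tibble from [decode_events()] (columns `phase_ms`,
#'   `label`).
#' @return one-row tibble: `Mc_ms`, `Ao_ms`, `Ac_ms`, `Mo_ms` (NA when
#'   missing), `complete` (all four present and ordered).
#' @export
extract_valve_times <- function(decoded) {
  get1 <- function(ev) {
    p <- decoded$phase_ms[decoded$label == ev]
    if (length(p) == 1) p else NA_real_
  }
  ph <- vapply(valve_labels, get1, numeric(1))
  ordered <- all(!is.na(ph)) && all(diff(ph[c("Mc", "Ao", "Ac", "Mo")]) > 0)
  tibble::tibble(
    Mc_ms = ph[["Mc"]], Ao_ms = ph[["Ao"]], Ac_ms = ph[["Ac"]], Mo_ms = ph[["Mo"]],
    complete = ordered
  )
}

# --- end-to-end helpers -----------------------------------------------------

#' Build a labelled training corpus from simulated records
#'
#' Preprocesses each record, detects peak candidates per segment, labels
#' them against the ground truth, and assigns envelope clusters.
#'
#' @param cohort tibble from [simulate_records()] (columns `record`,
#'   `truth`).
#' @param cluster_model optional pre-fit [fit_clusters()] model; fitted on
#'   the pooled segments when `NULL`.
#' @param seed seed for cluster fitting.
#' @param k number of clusters.
#' @return list: `labelled` tibble (training rows), `cluster_model`.
#' @export
build_training_corpus <- function(cohort, cluster_model = NULL, seed = 1, k = 6) {
  all_segments <- list()
  rows <- list()
  seg_offset <- 0L
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort$record[[i]]
    truth <- cohort$truth[[i]]
    rp <- tibble::tibble(time = truth$r_times)   # training uses truth R peaks
    segs <- preprocess_dus(rec, rp)
    if (!nrow(segs)) next
    all_segments[[length(all_segments) + 1]] <- segs
    ev <- truth$events
    for (j in seq_len(nrow(segs))) {
      b <- segs$beat_index[j]
      cand <- detect_peaks(segs$values[[j]], rec$fs, segs$rr_ms[j],
                           raw_values = segs$raw_values[[j]])
      if (!nrow(cand)) next
      truep <- as.list(ev[ev$beat_index == b, c("Mc", "Ao", "Ac", "Mo")])
      cand <- label_candidates(cand, truep)
      cand$segment_id <- seg_offset + j
      cand$record_id <- rec$record_id
      cand$seg_values <- list(NULL)
      rows[[length(rows) + 1]] <- cand
      rows[[length(rows)]]$seg_values <- rep(list(segs$values[[j]]), nrow(cand))
    }
    seg_offset <- seg_offset + nrow(segs)
  }
  segments <- dplyr::bind_rows(all_segments)
  labelled <- dplyr::bind_rows(rows)
  if (is.null(cluster_model)) cluster_model <- fit_clusters(segments, k = k, seed = seed)
  seg_cluster <- vapply(
    split(labelled$seg_values, labelled$segment_id),
    function(v) assign_cluster(v[[1]], cluster_model), numeric(1)
  )
  labelled$cluster <- seg_cluster[as.character(labelled$segment_id)]
  labelled$seg_values <- NULL
  list(labelled = labelled, cluster_model = cluster_model)
}

#' Train the full valve decoder on a simulated cohort
#'
#' @param cohort tibble from [simulate_records()].
#' @param seed seed for clustering.
#' @param k number of envelope clusters (default 6).
#' @return object of class `valve_decoder`: `cluster_model` + `svmhmm`.
#' @export
train_valve_decoder <- function(cohort, seed = 1, k = 6) {
  corpus <- build_training_corpus(cohort, seed = seed, k = k)
  hmm <- train_event_models(corpus$labelled, k = k)
  structure(list(cluster_model = corpus$cluster_model, svmhmm = hmm, k = k),
            class = "valve_decoder")
}

# Sub-sample phase refinement: local maximum of the un-smoothed envelope
# near the decoded phase, with parabolic interpolation.  The 30 Hz envelope
# smoothing makes cluster/emission features stable but drags the peaks of
# closely spaced bursts toward each other; the raw interpolated-maxima
# envelope keeps them put.
refine_phase <- function(phase_ms, raw, fs, halfwin_ms = 6) {
  if (is.na(phase_ms) || is.null(raw)) return(phase_ms)
  i <- round(phase_ms * fs / 1000) + 1L
  w <- round(halfwin_ms * fs / 1000)
  lo <- max(2L, i - w); hi <- min(length(raw) - 1L, i + w)
  if (hi <= lo) return(phase_ms)
  j <- lo + which.max(raw[lo:hi]) - 1L
  y0 <- raw[j - 1L]; y1 <- raw[j]; y2 <- raw[j + 1L]
  den <- y0 - 2 * y1 + y2
  delta <- if (is.finite(den) && den < 0) 0.5 * (y0 - y2) / den else 0
  (j - 1L + max(-0.5, min(0.5, delta))) / fs * 1000
}

#' Decode all beats of a record
#'
#' @param segments tibble from [segment_cycles()]/[preprocess_dus()].
#' @param decoder `valve_decoder` from [train_valve_decoder()].
#' @param fs sampling rate in Hz.
#' @return tibble with one row per segment: `beat_index`, `onset_r_time`,
#'   `rr_ms`, `cluster`, valve phases `Mc_ms`..`Mo_ms`, `complete`.
#' @export
decode_record <- function(segments, decoder, fs) {
  purrr::map_dfr(seq_len(nrow(segments)), function(j) {
    cl <- assign_cluster(segments$values[[j]], decoder$cluster_model)
    raw <- if ("raw_values" %in% names(segments)) segments$raw_values[[j]] else NULL
    cand <- detect_peaks(segments$values[[j]], fs, segments$rr_ms[j],
                         raw_values = raw)
    dec <- decode_events(cand, decoder$svmhmm, cl)
    vt <- extract_valve_times(dec)
    for (col in c("Mc_ms", "Ao_ms", "Ac_ms", "Mo_ms")) {
      vt[[col]] <- refine_phase(vt[[col]], raw, fs)
    }
    dplyr::bind_cols(
      tibble::tibble(beat_index = segments$beat_index[j],
                     onset_r_time = segments$onset_r_time[j],
                     rr_ms = segments$rr_ms[j], cluster = cl),
      vt
    )
  })
}
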