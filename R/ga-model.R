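# Gestational-age regression: shipped published models, polynomial
# prediction, stepwise refit, broom-style accessors.

#' Gestational-age regression models
#'
#' A `ga_model` is a polynomial regression over named predictors: an
#' intercept plus linear, squared (`x:x`) and pairwise-product (`x:y`)
#' terms.  Two published models ship with the package:
#'
#' * `ga_model_valve()` -- valve-interval model,
#'   `GA = a0 + a1 EDT + a2 ICT + a3 VFT + a4 EDT*ICT + a5 ICT*VFT`
#'   (intervals in ms, GA in weeks), with coefficients
#'   (-276.810, 5.496, 7.897, 0.682, -0.140, -0.017), residual SD 4.01 wk.
#' * `ga_model_fhrv()` -- heart-rate model, `GA = b0 + b1 mRR + b2 SDRR`
#'   (ms), with coefficients (4.788, 0.064, 0.120), residual SD 5.55 wk.
#'
#' Coefficients are shipped at their printed (rounded) precision, so
#' predictions inherit that rounding.
#'
#' @param terms character vector of term names: `"(Intercept)"`, a predictor
#'   name, or two predictor names joined by `":"` for a product (a squared
#'   term is `"x:x"`).
#' @param coefficients numeric vector, one per term.
#' @param variables character vector of predictor names the model needs.
#' @param se optional standard errors per term.
#' @param sigma optional residual standard deviation (weeks).
#' @return object of class `ga_model`.
#' @export
ga_model <- function(terms, coefficients, variables = NULL, se = NULL, sigma = NA_real_) {
  stopifnot(length(terms) == length(coefficients), !anyDuplicated(terms))
  if (!"(Intercept)" %in% terms) stop("intercept term is required", call. = FALSE)
  vars <- variables %||% unique(unlist(strsplit(setdiff(terms, "(Intercept)"), ":", fixed = TRUE)))
  structure(
    list(terms = terms, coefficients = setNames(as.numeric(coefficients), terms),
         variables = vars, se = if (is.null(se)) NULL else setNames(as.numeric(se), terms),
         sigma = sigma),
    class = "ga_model"
  )
}

#' @rdname ga_model
#' @export
ga_model_valve <- function() {
  ga_model(
    terms = c("(Intercept)", "EDT", "ICT", "VFT", "EDT:ICT", "ICT:VFT"),
    coefficients = c(-276.810, 5.496, 7.897, 0.682, -0.140, -0.017),
    se = c(61.772, 1.215, 1.743, 0.267, 0.034, 0.007),
    sigma = 4.01
  )
}

#' @rdname ga_model
#' @export
ga_model_fhrv <- function() {
  ga_model(
    terms = c("(Intercept)", "mRR", "SDRR"),
    coefficients = c(4.788, 0.064, 0.120),
    se = c(10.866, 0.026, 0.058),
    sigma = 5.55
  )
}

#' @export
print.ga_model <- function(x, ...) {
  cat("<ga_model> GA [weeks] =\n")
  for (i in seq_along(x$terms)) {
    cat(sprintf("  %+.4g * %s\n", x$coefficients[i], x$terms[i]))
  }
  invisible(x)
}

# Evaluate one term column on a data frame of predictors.
eval_term <- function(term, data) {
  if (term == "(Intercept)") return(rep(1, nrow(data)))
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  missing <- setdiff(parts, names(data))
  if (length(missing)) stop("missing variable(s): ", paste(missing, collapse = ", "), call. = FALSE)
  Reduce(`*`, lapply(parts, function(p) data[[p]]))
}

#' Predict gestational age from a model
#'
#' Evaluates the model polynomial on each row of `newdata`.  Intervals must
#' be in milliseconds; the result is weeks, unclipped.
#'
#' @param object a `ga_model`.
#' @param newdata data frame with one column per model variable.
#' @param ... unused.
#' @return numeric vector of GA estimates (weeks).
#' @export
predict.ga_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  X <- vapply(object$terms, eval_term, numeric(nrow(newdata)), data = newdata)
  X <- matrix(X, nrow = nrow(newdata))
  if (any(!is.finite(X))) stop("non-finite predictor value", call. = FALSE)
  drop(X %*% object$coefficients)
}

#' @rdname predict.ga_model
#' @param model a `ga_model`.
#' @param inputs data frame (or named list) of predictor values.
#' @export
predict_ga <- function(model, inputs) {
  predict(model, tibble::as_tibble(as.data.frame(inputs)))
}

#' Internal-consistency check of shipped coefficient tables
#'
#' For every term of both published models, verifies that the printed
#' estimate divided by the printed standard error reproduces the printed
#' t-statistic.  `consistent` applies the fixed tolerance `tol`;
#' `rounding_bound` is the worst-case deviation attributable to the
#' three-decimal rounding of the printed estimate, SE and t (half-ulp
#' propagation through the ratio), and `consistent_printed` checks against
#' the larger of the two.  Ratios reconstructed from rounded tables can
#' deviate beyond a fixed tolerance when the SE itself is small (its
#' half-ulp is a large relative error), which `rounding_bound` captures.
#'
#' @param tol fixed absolute tolerance on estimate/SE minus printed t.
#' @return tibble with columns `model`, `term`, `estimate`, `se`,
#'   `t_printed`, `t_ratio`, `consistent`, `rounding_bound`,
#'   `consistent_printed`.
#' @export
published_model_self_check <- function(tol = 0.05) {
  printed <- tibble::tibble(
    model = c(rep("valve", 6), rep("fhrv", 3)),
    term = c("(Intercept)", "EDT", "ICT", "VFT", "EDT:ICT", "ICT:VFT",
             "(Intercept)", "mRR", "SDRR"),
    t_printed = c(-4.481, 4.525, 4.530, 2.551, -4.142, -2.273,
                  0.441, 2.432, 2.044)
  )
  models <- list(valve = ga_model_valve(), fhrv = ga_model_fhrv())
  printed |>
    dplyr::mutate(
      estimate = purrr::map2_dbl(.data$model, .data$term, ~ models[[.x]]$coefficients[[.y]]),
      se = purrr::map2_dbl(.data$model, .data$term, ~ models[[.x]]$se[[.y]]),
      t_ratio = .data$estimate / .data$se,
      consistent = abs(.data$t_ratio - .data$t_printed) < tol,
      rounding_bound = 0.0005 / .data$se +
        0.0005 * abs(.data$estimate) / .data$se^2 + 0.0005,
      consistent_printed = abs(.data$t_ratio - .data$t_printed) <
        pmax(tol, .data$rounding_bound)
    ) |>
    dplyr::relocate("t_printed", .after = "se")
}

# --- stepwise fitting -------------------------------------------------------

# All candidate terms over `vars`: linear, squared, pairwise products.
candidate_terms <- function(vars) {
  sq <- paste0("I(", vars, "^2)")
  prods <- if (length(vars) > 1) utils::combn(vars, 2, FUN = paste, collapse = ":") else character(0)
  c(vars, sq, prods)
}

#' Stepwise polynomial regression of gestational age
#'
#' Forward-backward selection over a candidate pool containing the forced
#' intercept plus all linear, squared and pairwise-product terms of the
#' supplied predictors.  A term enters when its partial F-test p-value is
#' below `p_enter` and is removed when its p-value rises above `p_remove`.
#' Selection stops when no move is possible; a term is never re-entered in
#' the step immediately after its removal, so the procedure terminates.
#'
#' @param data data frame of predictors plus the response column.
#' @param response name of the response column (GA in weeks).
#' @param variables predictor names; default all other numeric columns.
#' @param p_enter entry threshold for the partial F-test (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @param terms optional fixed term list: skips selection and fits exactly
#'   these terms by ordinary least squares (use the `ga_model` term syntax,
#'   e.g. `c("EDT", "ICT", "EDT:ICT")`).
#' @return object of class `ga_fit`: the selected `ga_model`, the underlying
#'   `lm` fit, and fit statistics.  Use [tidy()]/[glance()] for the report.
#' @export
stepwise_fit <- function(data, response = "ga", variables = NULL,
                         p_enter = 0.05, p_remove = 0.10, terms = NULL) {
  data <- as.data.frame(data)
  if (!response %in% names(data)) stop("response column '", response, "' not found", call. = FALSE)
  if (!is.null(terms)) {
    variables <- unique(unlist(strsplit(setdiff(terms, "(Intercept)"), ":", fixed = TRUE)))
  }
  variables <- variables %||% setdiff(names(data)[vapply(data, is.numeric, logical(1))], response)
  if (!length(variables)) stop("no predictor variables", call. = FALSE)
  data <- data[complete.cases(data[c(response, variables)]), , drop = FALSE]
  const <- variables[vapply(variables, function(v) var(data[[v]]) == 0, logical(1))]
  if (length(const)) stop("constant predictor(s): ", paste(const, collapse = ", "), call. = FALSE)

  if (!is.null(terms)) {
    fml <- fixed_terms_formula(response, terms)
    fit <- lm(fml, data = data)
    return(new_ga_fit(fit, data, response))
  }

  pool <- candidate_terms(variables)
  fml0 <- as.formula(paste(response, "~ 1"))
  fit <- lm(fml0, data = data)
  just_removed <- character(0)
  repeat {
    moved <- FALSE
    # backward: drop the worst term above p_remove
    in_terms <- attr(stats::terms(fit), "term.labels")
    if (length(in_terms)) {
      dr <- drop1(fit, test = "F")
      pv <- dr[["Pr(>F)"]][-1]
      names(pv) <- rownames(dr)[-1]
      pv <- pv[is.finite(pv)]
      if (length(pv) && max(pv) > p_remove) {
        worst <- names(pv)[which.max(pv)]
        fit <- stats::update(fit, as.formula(paste(". ~ . -", worst)))
        just_removed <- worst
        moved <- TRUE
      }
    }
    # forward: add the best candidate below p_enter
    in_terms <- attr(stats::terms(fit), "term.labels")
    cand <- setdiff(pool, c(in_terms, just_removed))
    # guard rank: need enough rows for one more parameter
    if (length(cand) && nrow(data) > length(in_terms) + 2) {
      scope <- as.formula(paste("~ . +", paste(cand, collapse = " + ")))
      ad <- tryCatch(add1(fit, scope = scope, test = "F"), error = function(e) NULL)
      if (!is.null(ad)) {
        pv <- ad[["Pr(>F)"]][-1]
        names(pv) <- rownames(ad)[-1]
        pv <- pv[is.finite(pv)]
        if (length(pv) && min(pv) < p_enter) {
          best <- names(pv)[which.min(pv)]
          fit <- stats::update(fit, as.formula(paste(". ~ . +", best)))
          just_removed <- character(0)
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  new_ga_fit(fit, data, response)
}

fixed_terms_formula <- function(response, terms) {
  terms <- setdiff(terms, "(Intercept)")
  rhs <- vapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2 && parts[1] == parts[2]) paste0("I(", parts[1], "^2)") else tm
  }, character(1))
  as.formula(paste(response, "~", if (length(rhs)) paste(rhs, collapse = " + ") else "1"))
}

new_ga_fit <- function(fit, data, response) {
  # translate lm term labels back to ga_model syntax
  labs <- names(coef(fit))
  to_gm <- function(lab) {
    if (lab == "(Intercept)") return(lab)
    m <- regmatches(lab, regexec("^I\\((.+)\\^2\\)$", lab))[[1]]
    if (length(m) == 2) return(paste0(m[2], ":", m[2]))
    # canonical product order (lm labels interactions by formula entry order)
    if (grepl(":", lab, fixed = TRUE)) {
      return(paste(sort(strsplit(lab, ":", fixed = TRUE)[[1]]), collapse = ":"))
    }
    lab
  }
  gm_terms <- vapply(labs, to_gm, character(1), USE.NAMES = FALSE)
  sm <- summary(fit)
  model <- ga_model(
    terms = gm_terms, coefficients = coef(fit),
    se = sm$coefficients[, "Std. Error"], sigma = sm$sigma
  )
  structure(
    list(model = model, fit = fit, data = data, response = response),
    class = "ga_fit"
  )
}

#' @export
print.ga_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<ga_fit> %d terms, n = %d, sigma = %.3f wk, R^2 = %.3f (adj %.3f)\n",
    length(x$model$terms), nrow(x$data), g$sigma, g$r.squared, g$adj.r.squared
  ))
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted gestational-age regression
#'
#' @param x a `ga_fit` from [stepwise_fit()].
#' @param ... unused.
#' @return tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic` (t), `p.value`.
#' @export
tidy.ga_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = x$model$terms,
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' Fit statistics of a gestational-age regression
#'
#' @param x a `ga_fit`.
#' @param ... unused.
#' @return one-row tibble: `r.squared`, `adj.r.squared`, `sigma` (residual
#'   SD, weeks), `statistic` (F vs. the constant model), `p.value`, `df`,
#'   `nobs`.
#' @export
glance.ga_fit <- function(x, ...) {
  sm <- summary(x$fit)
  fstat <- sm$fstatistic
  if (is.null(fstat)) {
    f <- NA_real_; pf_ <- NA_real_
  } else {
    f <- unname(fstat[1])
    pf_ <- pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  }
  tibble::tibble(
    r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma, statistic = f, p.value = unname(pf_),
    df = length(coef(x$fit)) - 1L, nobs = nrow(x$data)
  )
}

#' @export
predict.ga_fit <- function(object, newdata, ...) {
  predict(object$model, newdata)
}
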