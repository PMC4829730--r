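# Model families fitted per participant and target: intercept-only mean
# model, lag-2 history model, and forward stepwise regression with either an
# AIC criterion or a PRESS-based leave-one-out cross-validated MSE criterion.
#
# All families share one least-squares core that also returns the hat-matrix
# diagonal, so the leave-one-out error of any fit comes from a single model
# run via the PRESS identity e_i / (1 - h_ii).

# Solve least squares for design A (with intercept column) against y.
# Fast path: Cholesky of the Gram matrix. A rank-deficient design either
# fails (default) or falls back to the minimum-norm SVD solution.
ols_core <- function(A, y, allow_deficient = FALSE) {
  G <- crossprod(A)
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (!is.null(R)) {
    Ginv <- chol2inv(R)
    beta <- drop(Ginv %*% crossprod(A, y))
  } else {
    if (!allow_deficient) return(NULL)
    s <- svd(A)
    pos <- s$d > max(dim(A)) * .Machine$double.eps * s$d[1]
    beta <- drop(s$v[, pos, drop = FALSE] %*%
                   ((crossprod(s$u[, pos, drop = FALSE], y)) / s$d[pos]))
    Ginv <- s$v[, pos, drop = FALSE] %*%
      (t(s$v[, pos, drop = FALSE]) / s$d[pos]^2)
  }
  fitted <- drop(A %*% beta)
  h <- rowSums((A %*% Ginv) * A)
  list(coef = beta, residuals = y - fitted, leverages = h,
       rank_deficient = is.null(R))
}

new_mood_model <- function(family, intercept, coefficients, n_train,
                           residuals = NULL, leverages = NULL,
                           trace = NULL, criterion = NA_character_,
                           baseline = NA_real_) {
  structure(list(family = family,
                 intercept = intercept,
                 coefficients = coefficients,
                 n_train = n_train,
                 residuals = residuals,
                 leverages = leverages,
                 trace = trace,
                 criterion = criterion,
                 baseline = baseline),
            class = "mood_model")
}

#' Ordinary least squares with leverage diagnostics
#'
#' Fits an intercept + selected-predictor linear model by least squares and
#' returns, alongside the coefficients, the fit residuals and the hat-matrix
#' diagonal (leverages) needed for the single-run leave-one-out error of
#' [press_cv_mse()].
#'
#' @param data Data frame of training rows.
#' @param target Name of the response column.
#' @param predictors Character vector of predictor column names (may be
#'   empty for an intercept-only fit).
#' @return A `mood_model` with residuals and leverages attached.
#' @export
#' @examples
#' d <- data.frame(x = 1:6, y = 2 * (1:6) + 1)
#' m <- fit_ols(d, "y", "x")
#' c(m$intercept, m$coefficients)
fit_ols <- function(data, target, predictors = character(0)) {
  y <- data[[target]]
  n <- length(y)
  if (n <= length(predictors))
    rlang::abort("fit_ols() needs more rows than predictors")
  A <- cbind(`(Intercept)` = rep(1, n),
             as.matrix(data[, predictors, drop = FALSE]))
  fit <- ols_core(A, y)
  if (is.null(fit)) {
    # name the first column that is linearly dependent on its predecessors
    qa <- qr(A)
    bad <- colnames(A)[qa$pivot[seq_len(ncol(A)) > qa$rank]]
    rlang::abort(sprintf("degenerate fit: rank-deficient design (column %s)",
                         paste(bad, collapse = ", ")),
                 class = "moodstep_degenerate_fit")
  }
  new_mood_model("ols", fit$coef[1],
                 stats::setNames(fit$coef[-1], predictors), n,
                 residuals = fit$residuals, leverages = fit$leverages)
}

#' PRESS-based leave-one-out cross-validated MSE
#'
#' Computes the leave-one-out cross-validated mean squared error of a fitted
#' least-squares model from a single model run, using the predicted residual
#' sum of squares identity: the held-out residual of observation i equals
#' `e_i / (1 - h_ii)` where `e_i` is the fit residual and `h_ii` the
#' leverage. Returns `PRESS / n`.
#'
#' @param model A `mood_model` from [fit_ols()] (residuals and leverages
#'   attached).
#' @param epsilon Leverages at or above `1 - epsilon` are degenerate: the
#'   observation fully determines its own fitted value, so its held-out
#'   residual is unbounded.
#' @return The cross-validated MSE (a scalar).
#' @export
#' @examples
#' d <- data.frame(y = c(1, 2, 3))
#' press_cv_mse(fit_ols(d, "y"))  # 1.5
press_cv_mse <- function(model, epsilon = 1e-8) {
  stopifnot(inherits(model, "mood_model"))
  if (is.null(model$residuals) || is.null(model$leverages))
    rlang::abort("model carries no residuals/leverages; refit with fit_ols()")
  h <- model$leverages
  if (any(h >= 1 - epsilon))
    rlang::abort("degenerate leverage (h >= 1 - epsilon); LOO residual unbounded",
                 class = "moodstep_degenerate_leverage")
  mean((model$residuals / (1 - h))^2)
}

# PRESS mean for a column subset of a precomputed Gram system; NA when the
# subset is numerically singular or has a degenerate leverage. Used inside
# forward selection so each candidate costs O(n p^2) with no re-crossprod.
press_from_gram <- function(A, y, G, b, idx) {
  R <- tryCatch(chol(G[idx, idx, drop = FALSE]), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  Ginv <- chol2inv(R)
  Ai <- A[, idx, drop = FALSE]
  beta <- drop(Ginv %*% b[idx])
  e <- y - drop(Ai %*% beta)
  h <- rowSums((Ai %*% Ginv) * Ai)
  if (any(h >= 1 - 1e-8)) return(NA_real_)
  mean((e / (1 - h))^2)
}

sse_from_gram <- function(A, y, G, b, idx) {
  R <- tryCatch(chol(G[idx, idx, drop = FALSE]), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  beta <- drop(chol2inv(R) %*% b[idx])
  sum((y - drop(A[, idx, drop = FALSE] %*% beta))^2)
}

#' Complexity cap for stepwise models
#'
#' The maximum number of predictor variables allowed in a personalized
#' model: the number of training points divided by `divisor`, floored. With
#' 42 training days and the default divisor of 5 the cap is 8 variables.
#' Fewer than `divisor` training points force an intercept-only model.
#'
#' @param n_train Number of training observations.
#' @param divisor Training points required per admitted variable.
#' @return Integer cap (possibly 0).
#' @export
#' @examples
#' cap_variables(42)  # 8
cap_variables <- function(n_train, divisor = 5) {
  stopifnot(is.numeric(n_train), length(n_train) == 1, n_train >= 0)
  as.integer(floor(n_train / divisor))
}

# Shared greedy driver for both stepwise criteria. `crit_fun(idx)` scores a
# design-column subset; lower is better; NA marks a degenerate candidate.
# Candidates are scanned in schema (column) order and a challenger must beat
# the incumbent by more than 1e-12, which breaks exact ties deterministically
# in favour of the earlier column.
forward_select_core <- function(X, y, cap, crit_fun, baseline) {
  p <- ncol(X)
  selected <- integer(0)
  current <- baseline
  steps_var <- character(0)
  steps_val <- numeric(0)
  repeat {
    if (length(selected) >= cap) break
    remaining <- setdiff(seq_len(p), selected)
    if (!length(remaining)) break
    best_j <- NA_integer_
    best_val <- Inf
    for (j in remaining) {
      val <- crit_fun(c(1L, selected + 1L, j + 1L))
      if (!is.na(val) && val < best_val - 1e-12) {
        best_val <- val
        best_j <- j
      }
    }
    if (is.na(best_j) || !(best_val < current)) break
    selected <- c(selected, best_j)
    current <- best_val
    steps_var <- c(steps_var, colnames(X)[best_j])
    steps_val <- c(steps_val, best_val)
  }
  list(selected = selected,
       trace = tibble::tibble(step = seq_along(steps_var),
                              variable = steps_var,
                              criterion = steps_val))
}

finish_step_model <- function(data, target, X, y, sel, family,
                              criterion, baseline) {
  vars <- colnames(X)[sel$selected]
  fit <- fit_ols(data, target, vars)
  new_mood_model(family, fit$intercept, fit$coefficients, length(y),
                 residuals = fit$residuals, leverages = fit$leverages,
                 trace = sel$trace, criterion = criterion, baseline = baseline)
}

step_design <- function(data, target, predictors) {
  if (is.null(predictors))
    predictors <- intersect(feature_variables(), names(data))
  X <- as.matrix(data[, predictors, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = data[[target]])
}

#' Forward stepwise regression under cross-validated error
#'
#' Greedy forward selection of predictors for one participant's standardized
#' mood target, scored by the PRESS-based leave-one-out cross-validated MSE.
#' Starting from the intercept-only model, each step adds the candidate
#' whose admission gives the lowest cross-validated MSE, provided that MSE
#' is strictly below the current model's; selection stops when no candidate
#' improves (the point where the cross-validated error would start to rise)
#' or when the complexity cap is reached. Degenerate candidates (collinear,
#' or producing a leverage of 1) are skipped, not fatal.
#'
#' @param data Data frame of modelable training rows (>= 3).
#' @param target Name of the standardized target column.
#' @param cap Maximum number of variables; defaults to
#'   [cap_variables()] of the row count.
#' @param predictors Candidate columns; defaults to every schema variable
#'   present in `data`, scanned in schema order (the deterministic
#'   tie-break).
#' @return A `mood_model` (family `"stepCV"`) whose `trace` records each
#'   accepted variable and the strictly decreasing cross-validated MSE;
#'   `baseline` holds the intercept-only cross-validated MSE.
#' @export
forward_select_cv <- function(data, target, cap = cap_variables(nrow(data)),
                              predictors = NULL) {
  if (nrow(data) < 3)
    rlang::abort("forward_select_cv() needs at least 3 modelable rows")
  d <- step_design(data, target, predictors)
  n <- length(d$y)
  A <- cbind(1, d$X)
  G <- crossprod(A)
  b <- drop(crossprod(A, d$y))
  baseline <- press_from_gram(A, d$y, G, b, 1L)
  sel <- forward_select_core(d$X, d$y, cap,
                             function(idx) press_from_gram(A, d$y, G, b, idx),
                             baseline)
  finish_step_model(data, target, d$X, d$y, sel, "stepCV", "cv_mse", baseline)
}

#' Forward stepwise regression under AIC
#'
#' Forward-only selection minimizing the Gaussian AIC,
#' `n * log(SSE / n) + 2 * (k + 2)` for `k` predictors (intercept and the
#' profiled-out error variance counted as parameters; the additive
#' `n * (log(2 * pi) + 1)` constant is dropped since it cannot affect
#' selection). Stops when no addition lowers the AIC or the complexity cap
#' is reached.
#'
#' @inheritParams forward_select_cv
#' @return A `mood_model` (family `"stepAIC"`) with the AIC trace;
#'   `baseline` holds the intercept-only AIC.
#' @export
forward_select_aic <- function(data, target, cap = cap_variables(nrow(data)),
                               predictors = NULL) {
  if (nrow(data) < 3)
    rlang::abort("forward_select_aic() needs at least 3 modelable rows")
  d <- step_design(data, target, predictors)
  n <- length(d$y)
  A <- cbind(1, d$X)
  G <- crossprod(A)
  b <- drop(crossprod(A, d$y))
  aic_of <- function(idx) {
    sse <- sse_from_gram(A, d$y, G, b, idx)
    if (is.na(sse)) return(NA_real_)
    k <- length(idx) - 1L
    n * log(sse / n) + 2 * (k + 2)
  }
  baseline <- aic_of(1L)
  sel <- forward_select_core(d$X, d$y, cap, aic_of, baseline)
  finish_step_model(data, target, d$X, d$y, sel, "stepAIC", "aic", baseline)
}

#' Naive benchmark: the mean model
#'
#' Intercept-only model predicting every day's mood as the training-set
#' average. Its leave-one-out prediction for row i is the mean of the other
#' rows, available in closed form.
#'
#' @inheritParams forward_select_cv
#' @return A `mood_model` (family `"mean"`), no coefficients.
#' @export
#' @examples
#' fit_mean_model(data.frame(y = c(1, 2, 3)), "y")$intercept  # 2
fit_mean_model <- function(data, target) {
  if (nrow(data) < 2)
    rlang::abort("fit_mean_model() needs at least 2 rows")
  fit <- fit_ols(data, target)
  fit$family <- "mean"
  fit
}

#' Naive benchmark: the lag-2 history model
#'
#' Linear regression of the mood target on an intercept and the
#' standardized mood of the previous two days (`mood_lag1`, `mood_lag2`).
#' Exactly collinear lags fall back to the minimum-norm least-squares
#' solution rather than failing.
#'
#' @inheritParams forward_select_cv
#' @return A `mood_model` (family `"history"`) with exactly the two lag
#'   coefficients.
#' @export
fit_history_model <- function(data, target) {
  if (nrow(data) < 4)
    rlang::abort("fit_history_model() needs at least 4 rows")
  y <- data[[target]]
  A <- cbind(`(Intercept)` = rep(1, nrow(data)),
             mood_lag1 = data$mood_lag1, mood_lag2 = data$mood_lag2)
  fit <- ols_core(A, y, allow_deficient = TRUE)
  new_mood_model("history", fit$coef[1],
                 c(mood_lag1 = unname(fit$coef[2]),
                   mood_lag2 = unname(fit$coef[3])),
                 length(y),
                 residuals = fit$residuals, leverages = fit$leverages)
}

#' @export
predict.mood_model <- function(object, newdata, ...) {
  pred <- rep(object$intercept, nrow(newdata))
  if (length(object$coefficients)) {
    X <- as.matrix(newdata[, names(object$coefficients), drop = FALSE])
    pred <- pred + drop(X %*% object$coefficients)
  }
  pred
}

#' @export
print.mood_model <- function(x, ...) {
  cat("<mood_model:", x$family, "> n_train =", x$n_train,
      ",", length(x$coefficients), "predictor(s)\n")
  if (!is.null(x$trace) && nrow(x$trace)) {
    cat("  selection (", x$criterion, "): ",
        paste(x$trace$variable, collapse = " + "), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a fitted mood model
#'
#' @param x A `mood_model`.
#' @param ... Unused.
#' @return A tibble with one row per term (intercept first): `term`,
#'   `estimate`.
#' @method tidy mood_model
#' @export
tidy.mood_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = unname(c(x$intercept, x$coefficients)))
}

#' Glance at a fitted mood model
#'
#' @param x A `mood_model`.
#' @param ... Unused.
#' @return One-row tibble: family, number of training rows, number of
#'   selected predictors, in-sample MSE, and the PRESS leave-one-out MSE
#'   (NA when leverages are unavailable or degenerate).
#' @method glance mood_model
#' @export
glance.mood_model <- function(x, ...) {
  cv <- tryCatch(press_cv_mse(x), error = function(e) NA_real_)
  tibble::tibble(family = x$family,
                 n_train = x$n_train,
                 n_predictors = length(x$coefficients),
                 mse_train = if (is.null(x$residuals)) NA_real_
                             else mean(x$residuals^2),
                 cv_mse = cv)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
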