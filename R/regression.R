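#' Build a regression design matrix from a cohort
#'
#' Time-agnostic mode regresses SLEDAI-2k at each visit on that visit's 17
#' parameters (plus intercept: 18 free parameters). Time-dependent mode adds
#' the 17 parameters of the same patient's prior visit (34 coefficients plus
#' intercept: 35 free parameters); each patient's first visit is dropped and
#' lagging never crosses patients. Patients with fewer than 2 visits
#' contribute no time-dependent rows (reported via `message()`).
#'
#' @param cohort a z-normalized `sle_cohort`.
#' @param mode `"time_agnostic"` or `"time_dependent"`.
#' @return A list of class `design_matrix` with `x` (numeric matrix including
#'   an `(Intercept)` column; prior-visit columns carry a `lag_` prefix),
#'   `y` (SLEDAI-2k response), `row_key` (data.frame of `patient_id`, `day`)
#'   and `mode`.
#' @export
build_design <- function(cohort, mode = c("time_agnostic", "time_dependent")) {
  stopifnot(inherits(cohort, "sle_cohort"))
  if (!isTRUE(cohort$normalized)) {
    stop("cohort must be z-normalized before building a design")
  }
  mode <- match.arg(mode)
  v <- cohort$visits
  vals <- as.matrix(v[, parameter_panel(), drop = FALSE])
  if (mode == "time_agnostic") {
    x <- cbind("(Intercept)" = 1, vals)
    y <- v$sledai
    key <- v[, c("patient_id", "day")]
  } else {
    idx <- split(seq_len(nrow(v)), v$patient_id)
    short <- names(idx)[lengths(idx) < 2]
    if (length(short) > 0) {
      message("patient(s) with a single visit contribute no lagged rows: ",
              paste(short, collapse = ", "))
    }
    cur <- unlist(lapply(idx, function(i) i[-1]), use.names = FALSE)
    prev <- unlist(lapply(idx, function(i) i[-length(i)]), use.names = FALSE)
    lagged <- vals[prev, , drop = FALSE]
    colnames(lagged) <- paste0("lag_", parameter_panel())
    x <- cbind("(Intercept)" = 1, vals[cur, , drop = FALSE], lagged)
    y <- v$sledai[cur]
    key <- v[cur, c("patient_id", "day")]
  }
  rownames(x) <- NULL
  rownames(key) <- NULL
  structure(list(x = x, y = y, row_key = key, mode = mode),
            class = "design_matrix")
}

#' Ordinary least squares fit of a design
#'
#' Deterministic OLS minimizing the residual sum of squares. A
#' rank-deficient design is an error naming the aliased (collinear) columns.
#'
#' @param design a `design_matrix` (or a list with `x`, `y`).
#' @return A list with `coefficients` (named, intercept first), `fitted` and
#'   `residuals`.
#' @export
fit_linear <- function(design) {
  x <- design$x; y <- design$y
  if (nrow(x) <= ncol(x)) {
    stop("need more rows than free parameters to fit")
  }
  fit <- stats::lm.fit(x, y)
  if (fit$rank < ncol(x)) {
    aliased <- colnames(x)[is.na(fit$coefficients)]
    stop("design is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  list(coefficients = fit$coefficients,
       fitted = as.vector(x %*% fit$coefficients),
       residuals = y - as.vector(x %*% fit$coefficients))
}

#' Leave-one-patient-out cross-validated predictions
#'
#' For each patient, fits the model on every other patient's rows and
#' predicts all of the held-out patient's eligible visits, so no patient ever
#' informs their own prediction. A fold whose training fit fails is skipped
#' with a warning and recorded in the `fold_log` attribute.
#'
#' @param cohort a z-normalized `sle_cohort` with at least 3 patients.
#' @param mode regression mode, as in [build_design()].
#' @return data.frame of class `prediction_set` with columns `patient_id`,
#'   `day`, `actual`, `predicted`, `residual` (actual - predicted).
#' @export
lopo_cv <- function(cohort, mode = c("time_agnostic", "time_dependent")) {
  mode <- match.arg(mode)
  if (n_patients(cohort) < 3) stop("need at least 3 patients for LOPO")
  design <- suppressMessages(build_design(cohort, mode))
  ids <- unique(design$row_key$patient_id)
  out <- vector("list", length(ids))
  fold_log <- character(0)
  for (s in seq_along(ids)) {
    p <- ids[s]
    test <- design$row_key$patient_id == p
    fit <- tryCatch(
      fit_linear(list(x = design$x[!test, , drop = FALSE],
                      y = design$y[!test])),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("LOPO fold for patient %s skipped: %s",
                      p, conditionMessage(fit)))
      fold_log <- c(fold_log, sprintf("%s: %s", p, conditionMessage(fit)))
      next
    }
    pred <- as.vector(design$x[test, , drop = FALSE] %*% fit$coefficients)
    out[[s]] <- data.frame(patient_id = p,
                           day = design$row_key$day[test],
                           actual = design$y[test],
                           predicted = pred,
                           residual = design$y[test] - pred)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "fold_log") <- fold_log
  class(res) <- c("prediction_set", "data.frame")
  res
}

#' Error summary of a prediction set
#'
#' Mean square error (the mean squared Euclidean distance between each
#' observation and its prediction) and mean absolute error of the residuals.
#'
#' @param pred a `prediction_set` (or any data.frame with a `residual`
#'   column).
#' @return A list with `mean_square`, `mean_absolute` and `n`.
#' @export
error_summary <- function(pred) {
  r <- pred$residual
  if (is.null(r) || length(r) == 0) stop("prediction set is empty")
  list(mean_square = mean(r^2), mean_absolute = mean(abs(r)), n = length(r))
}

#' Patient-level bootstrap of out-of-sample prediction error
#'
#' Repeatedly splits the PATIENTS (never individual visits, which would leak
#' a patient across the split) into a training and a test fraction, fits the
#' model on the training rows and scores mean-square error on the test rows.
#' With the same `seed` the sequence of patient splits is identical across
#' calls, so scores for two modes are paired by iteration.
#'
#' @param cohort a z-normalized `sle_cohort`.
#' @param mode regression mode, as in [build_design()].
#' @param n_iter number of bootstrap iterations (default 1000).
#' @param train_frac fraction of patients assigned to training (default 0.8).
#' @param seed optional integer seed.
#' @return Numeric vector of `n_iter` mean-square error scores, with a
#'   `resampled` attribute counting degenerate splits that were redrawn.
#' @export
bootstrap_error <- function(cohort, mode = c("time_agnostic", "time_dependent"),
                            n_iter = 1000L, train_frac = 0.8, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_iter >= 1, train_frac > 0, train_frac < 1)
  design <- suppressMessages(build_design(cohort, mode))
  ids <- unique(design$row_key$patient_id)
  n_train <- max(1L, round(train_frac * length(ids)))
  if (n_train >= length(ids)) n_train <- length(ids) - 1L
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }
  scores <- numeric(n_iter)
  resampled <- 0L
  pid <- design$row_key$patient_id
  for (it in seq_len(n_iter)) {
    repeat {
      train_ids <- sample(ids, n_train)
      tr <- pid %in% train_ids
      if (sum(tr) > ncol(design$x) && sum(!tr) > 0) break
      resampled <- resampled + 1L
      if (resampled > 100L * n_iter) stop("could not draw a usable split")
    }
    fit <- stats::lm.fit(design$x[tr, , drop = FALSE], design$y[tr])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    resid <- design$y[!tr] - as.vector(design$x[!tr, , drop = FALSE] %*% beta)
    scores[it] <- mean(resid^2)
  }
  if (resampled > 0) {
    message(resampled, " degenerate split(s) redrawn")
  }
  attr(scores, "resampled") <- resampled
  scores
}

#' Compare two paired bootstrap error distributions
#'
#' Paired differences of per-iteration scores (`scores_a - scores_b`), their
#' 2.5/97.5 percentile interval, and a two-sided bootstrap p-value
#' `2 * min(frac <= 0, frac >= 0)` with a continuity floor of `1/n_iter`.
#'
#' @param scores_a,scores_b equal-length score vectors produced with the same
#'   seed (paired by iteration).
#' @return A list with `mean_diff`, `ci_low`, `ci_high`, `p`.
#' @export
compare_models <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors must have equal length")
  }
  d <- as.vector(scores_a) - as.vector(scores_b)
  ci <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
  p <- 2 * min(mean(d <= 0), mean(d >= 0))
  p <- min(1, max(p, 1 / length(d)))
  list(mean_diff = mean(d), ci_low = ci[1], ci_high = ci[2], p = p)
}
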