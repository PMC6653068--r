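#' Convert an assay value to fold above the upper limit of normal
#'
#' Anti-dsDNA titres from different assays are made comparable by dividing
#' each value by its assay's upper limit of normal (ULN), so 1.0 means "at
#' the ULN".
#'
#' @param value assay value(s), >= 0.
#' @param uln upper limit of normal for the assay, > 0 (recycled).
#' @return `value / uln`, dimensionless.
#' @export
#' @examples
#' fold_uln(75, 30)  # 2.5
fold_uln <- function(value, uln) {
  if (any(uln <= 0)) stop("uln must be positive")
  if (any(value < 0)) stop("value must be nonnegative")
  value / uln
}

#' Drop patients with too few visits
#'
#' Retains exactly the patients with at least `min_visits` complete visits
#' (the analysis inclusion rule; default 3) and drops the rest, including
#' their characteristics rows. Excluded patient ids are reported via
#' `message()`. Idempotent.
#'
#' @param cohort an `sle_cohort`.
#' @param min_visits inclusion threshold.
#' @return The filtered `sle_cohort`.
#' @export
filter_cohort <- function(cohort, min_visits = 3L) {
  stopifnot(inherits(cohort, "sle_cohort"))
  counts <- table(cohort$visits$patient_id)
  keep <- names(counts)[counts >= min_visits]
  dropped <- setdiff(names(counts), keep)
  if (length(dropped) > 0) {
    message("excluding patient(s) with fewer than ", min_visits, " visits: ",
            paste(dropped, collapse = ", "))
  }
  visits <- cohort$visits[cohort$visits$patient_id %in% keep, , drop = FALSE]
  ch <- cohort$characteristics
  if (!is.null(ch)) ch <- ch[ch$patient_id %in% keep, , drop = FALSE]
  sle_cohort(visits, ch, normalized = cohort$normalized)
}

#' Cohort-wide z-normalization of the 17 parameters
#'
#' Each parameter is centred and scaled to mean 0, sample sd 1 (n - 1
#' denominator) pooled over ALL visits of ALL patients — not per patient.
#' SLEDAI-2k is left untouched. A constant parameter (sd 0) is set to all
#' zeros with a warning. Refuses to run twice: the input must not already be
#' normalized.
#'
#' @param cohort a raw `sle_cohort`.
#' @return The normalized `sle_cohort` (with `normalized = TRUE`); the
#'   centring/scaling vectors are kept in attributes `norm_center` and
#'   `norm_scale`.
#' @export
z_normalize <- function(cohort) {
  stopifnot(inherits(cohort, "sle_cohort"))
  if (isTRUE(cohort$normalized)) {
    stop("cohort is already z-normalized")
  }
  v <- cohort$visits
  vals <- as.matrix(v[, parameter_panel(), drop = FALSE])
  mu <- colMeans(vals)
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant parameter(s) set to zero: ",
            paste(colnames(vals)[sds == 0], collapse = ", "))
  }
  scale_ <- ifelse(sds == 0, 1, sds)
  z <- sweep(sweep(vals, 2, mu, "-"), 2, scale_, "/")
  z[, sds == 0] <- 0
  v[, parameter_panel()] <- z
  out <- sle_cohort(v, cohort$characteristics, normalized = TRUE)
  attr(out, "norm_center") <- mu
  attr(out, "norm_scale") <- sds
  out
}

#' Per-patient summary vectors for magnitude-based analysis
#'
#' Collapses each patient's unequal-length visit series to a fixed-length
#' 17-vector: the per-parameter mean (default) or median of that patient's
#' z-scored visits. These vectors feed the pairwise Euclidean distance of
#' laboratory profiles.
#'
#' @param cohort a normalized `sle_cohort`.
#' @param stat aggregation statistic, `"mean"` (default) or `"median"`.
#' @return Numeric matrix, one row per patient (rownames = patient ids),
#'   17 columns in panel order.
#' @export
summarize_patients <- function(cohort, stat = c("mean", "median")) {
  stopifnot(inherits(cohort, "sle_cohort"))
  if (!isTRUE(cohort$normalized)) {
    stop("cohort must be z-normalized before summarizing")
  }
  stat <- match.arg(stat)
  f <- if (stat == "mean") colMeans else function(m) apply(m, 2, stats::median)
  mats <- patient_matrices(cohort)
  out <- t(vapply(mats, f, numeric(17)))
  colnames(out) <- parameter_panel()
  out
}
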