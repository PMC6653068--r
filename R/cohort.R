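#' Construct a longitudinal SLE cohort
#'
#' A cohort couples a per-visit table (one row per patient visit, carrying the
#' 17 biomarker parameters and the SLEDAI-2k disease-activity score) with an
#' optional per-patient table of binary clinical characteristics used for
#' association analysis. Visits are stored sorted by patient id and then by
#' day (integer days since that patient's first included visit, day 0).
#'
#' @param visits data.frame with columns `patient_id`, `day`, `sledai` and the
#'   17 columns of [parameter_panel()], in any column order.
#' @param characteristics optional data.frame with a `patient_id` column and
#'   one 0/1 column per binary clinical flag.
#' @param normalized logical; `TRUE` when the 17 parameter columns hold
#'   cohort-wide z-scores rather than raw values.
#' @return An object of class `sle_cohort`: a list with elements `visits`,
#'   `characteristics` and `normalized`.
#' @seealso [read_cohort()], [validate_cohort()], [z_normalize()]
#' @export
sle_cohort <- function(visits, characteristics = NULL, normalized = FALSE) {
  stopifnot(is.data.frame(visits))
  need <- c("patient_id", "day", "sledai", parameter_panel())
  missing_cols <- setdiff(need, names(visits))
  if (length(missing_cols) > 0L) {
    stop("visits table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  visits <- visits[, need, drop = FALSE]
  visits$patient_id <- as.character(visits$patient_id)
  visits <- visits[order(visits$patient_id, visits$day), , drop = FALSE]
  rownames(visits) <- NULL
  if (!is.null(characteristics)) {
    stopifnot(is.data.frame(characteristics))
    if (!"patient_id" %in% names(characteristics)) {
      stop("characteristics table is missing column: patient_id")
    }
    characteristics$patient_id <- as.character(characteristics$patient_id)
    rownames(characteristics) <- NULL
  }
  structure(
    list(visits = visits, characteristics = characteristics,
         normalized = isTRUE(normalized)),
    class = "sle_cohort"
  )
}

#' @export
print.sle_cohort <- function(x, ...) {
  cat(sprintf("<sle_cohort> %d patients, %d visits, %s values\n",
              n_patients(x), nrow(x$visits),
              if (x$normalized) "z-normalized" else "raw"))
  if (!is.null(x$characteristics)) {
    cat(sprintf("  characteristics: %s\n",
                paste(setdiff(names(x$characteristics), "patient_id"),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Patient identifiers of a cohort
#' @param cohort an `sle_cohort`.
#' @return Character vector of unique patient ids, in sorted order.
#' @export
cohort_ids <- function(cohort) {
  unique(cohort$visits$patient_id)
}

#' Number of patients in a cohort
#' @param cohort an `sle_cohort`.
#' @export
n_patients <- function(cohort) {
  length(cohort_ids(cohort))
}

#' Per-patient visit-value matrices
#'
#' Splits the visit table into one numeric matrix per patient
#' (visits x 17 parameters, rows in day order).
#'
#' @param cohort an `sle_cohort`.
#' @return Named list of matrices, one per patient.
#' @export
patient_matrices <- function(cohort) {
  vals <- as.matrix(cohort$visits[, parameter_panel(), drop = FALSE])
  split_idx <- split(seq_len(nrow(vals)), cohort$visits$patient_id)
  lapply(split_idx, function(i) vals[i, , drop = FALSE])
}

#' Validate a cohort against its structural invariants
#'
#' Checks, without ever throwing, that: days are nonnegative and strictly
#' increasing within each patient; every patient has at least `min_visits`
#' visits; SLEDAI-2k is a nonnegative integer; all parameter values are
#' finite; characteristics flags are 0/1 and refer to existing patients; and,
#' when the cohort is marked normalized, every parameter has pooled mean ~0
#' and sample sd ~1.
#'
#' @param cohort an `sle_cohort`.
#' @param min_visits minimum number of visits per patient (default 3, the
#'   inclusion threshold of the analysis).
#' @return Character vector of violation messages; empty when the cohort is
#'   valid. Each message names the offending patient or rule.
#' @export
validate_cohort <- function(cohort, min_visits = 3L) {
  msgs <- character(0)
  if (!inherits(cohort, "sle_cohort")) {
    return("object is not an sle_cohort")
  }
  v <- cohort$visits
  by_pat <- split(seq_len(nrow(v)), v$patient_id)
  for (id in names(by_pat)) {
    idx <- by_pat[[id]]
    days <- v$day[idx]
    if (any(days < 0)) {
      msgs <- c(msgs, sprintf("patient %s: negative visit day", id))
    }
    if (any(duplicated(days))) {
      msgs <- c(msgs, sprintf("patient %s: duplicate visit day", id))
    } else if (is.unsorted(days, strictly = TRUE)) {
      msgs <- c(msgs, sprintf("patient %s: visit days not strictly increasing", id))
    }
    if (length(idx) < min_visits) {
      msgs <- c(msgs, sprintf(
        "patient %s: %d visit(s), fewer than the required %d",
        id, length(idx), min_visits))
    }
    sl <- v$sledai[idx]
    if (any(!is.finite(sl)) || any(sl < 0) || any(sl != round(sl))) {
      msgs <- c(msgs, sprintf("patient %s: sledai must be a nonnegative integer", id))
    }
  }
  vals <- as.matrix(v[, parameter_panel(), drop = FALSE])
  if (any(!is.finite(vals))) {
    bad <- unique(v$patient_id[!stats::complete.cases(vals) |
                                 rowSums(!is.finite(vals)) > 0])
    msgs <- c(msgs, sprintf("patient %s: non-finite parameter value", bad))
  }
  ch <- cohort$characteristics
  if (!is.null(ch)) {
    unknown <- setdiff(ch$patient_id, v$patient_id)
    if (length(unknown) > 0) {
      msgs <- c(msgs, sprintf("characteristics refer to unknown patient %s", unknown))
    }
    for (flag in setdiff(names(ch), "patient_id")) {
      x <- ch[[flag]]
      if (!all(is.na(x) | x %in% c(0, 1))) {
        msgs <- c(msgs, sprintf("characteristic %s: values must be 0/1", flag))
      }
    }
  }
  if (isTRUE(cohort$normalized) && nrow(v) > 1) {
    mu <- colMeans(vals)
    sds <- apply(vals, 2, stats::sd)
    off <- abs(mu) > 1e-6 | (abs(sds - 1) > 1e-6 & sds > 0)
    if (any(off)) {
      msgs <- c(msgs, sprintf(
        "normalized flag set but parameter %s has pooled mean/sd away from 0/1",
        colnames(vals)[off]))
    }
  }
  msgs
}

#' Read a cohort from CSV
#'
#' Reads the per-visit table (and optionally the per-patient characteristics
#' table) from comma-separated UTF-8 files with a header row and "." decimal
#' marks. The 17 parameter columns may appear in any order and are mapped onto
#' the fixed [parameter_panel()] order; rows are grouped by patient and sorted
#' by day. A JSON metadata sidecar written by [write_cohort()] (if present
#' next to `visits_path`) restores the `normalized` flag.
#'
#' Rows with empty or non-numeric parameter cells are rejected with the row
#' number, unless `on_missing = "drop_patient"`, in which case the whole
#' offending patient is dropped with a warning (no imputation is ever done).
#'
#' @param visits_path path to the visits CSV
#'   (`patient_id,day,sledai,<17 parameters>`).
#' @param characteristics_path optional path to the characteristics CSV
#'   (`patient_id,<binary flags>`).
#' @param on_missing `"error"` (default) or `"drop_patient"`.
#' @return A validated `sle_cohort`.
#' @export
read_cohort <- function(visits_path, characteristics_path = NULL,
                        on_missing = c("error", "drop_patient")) {
  on_missing <- match.arg(on_missing)
  raw <- utils::read.csv(visits_path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("patient_id", "day", "sledai", parameter_panel())
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("visits CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), need)
  if (length(extra) > 0) {
    stop("visits CSV has unexpected column(s): ", paste(extra, collapse = ", "))
  }
  num_cols <- c("day", "sledai", parameter_panel())
  parsed <- raw
  bad_rows <- integer(0)
  for (col in num_cols) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x))
    bad_rows <- union(bad_rows, bad)
    parsed[[col]] <- x
  }
  if (length(bad_rows) > 0) {
    if (on_missing == "error") {
      stop(sprintf("non-numeric or empty cell(s) in visits CSV at data row(s) %s",
                   paste(sort(bad_rows), collapse = ", ")))
    }
    drop_ids <- unique(raw$patient_id[bad_rows])
    warning(sprintf("dropping patient(s) with unreadable cells: %s",
                    paste(drop_ids, collapse = ", ")))
    parsed <- parsed[!parsed$patient_id %in% drop_ids, , drop = FALSE]
  }
  if (anyDuplicated(parsed[, c("patient_id", "day")]) > 0) {
    dup <- parsed[duplicated(parsed[, c("patient_id", "day")]), ]
    stop(sprintf("duplicate (patient_id, day) pair(s): %s",
                 paste(sprintf("(%s, %s)", dup$patient_id, dup$day), collapse = ", ")))
  }
  characteristics <- NULL
  if (!is.null(characteristics_path)) {
    characteristics <- utils::read.csv(characteristics_path,
                                       check.names = FALSE,
                                       fileEncoding = "UTF-8")
    if (!"patient_id" %in% names(characteristics)) {
      stop("characteristics CSV is missing column: patient_id")
    }
    characteristics$patient_id <- as.character(characteristics$patient_id)
  }
  normalized <- FALSE
  meta_path <- paste0(visits_path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    normalized <- isTRUE(meta$normalized)
  }
  sle_cohort(parsed, characteristics, normalized = normalized)
}

#' Write a cohort to CSV
#'
#' Writes the visits table (values with 15 significant digits, so that a
#' read/write round trip preserves them to floating-point text precision),
#' the characteristics table when present, and a JSON metadata sidecar
#' (`<visits_path>.meta.json`) recording the `normalized` flag and the
#' parameter panel.
#'
#' @param cohort an `sle_cohort`.
#' @param visits_path output path for the visits CSV.
#' @param characteristics_path optional output path for the characteristics
#'   CSV; written only when the cohort carries characteristics or the path is
#'   given (an empty characteristics table yields a header-only file).
#' @return Invisibly, the visits path.
#' @export
write_cohort <- function(cohort, visits_path, characteristics_path = NULL) {
  stopifnot(inherits(cohort, "sle_cohort"))
  v <- cohort$visits
  out <- v
  for (col in parameter_panel()) {
    out[[col]] <- format(v[[col]], digits = 15, scientific = FALSE, trim = TRUE)
  }
  utils::write.csv(out, visits_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  if (!is.null(characteristics_path)) {
    ch <- cohort$characteristics
    if (is.null(ch)) ch <- data.frame(patient_id = character(0))
    utils::write.csv(ch, characteristics_path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  jsonlite::write_json(
    list(normalized = cohort$normalized, panel = parameter_panel()),
    paste0(visits_path, ".meta.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(visits_path)
}
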