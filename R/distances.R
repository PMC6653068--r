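#' Construct a patient distance matrix object
#'
#' @param d symmetric numeric matrix of nonnegative distances with zero
#'   diagonal; dimnames are the patient ids.
#' @param metric tag, `"euclidean_summary"` or `"dtw"`.
#' @return The matrix with class `patient_dist` and a `metric` attribute.
#' @export
patient_dist <- function(d, metric = c("euclidean_summary", "dtw")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- sprintf("obs%d", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(d < -1e-12) || any(abs(diag(d)) > 1e-12)) {
    stop("distances must be nonnegative with zero diagonal")
  }
  structure(d, metric = metric, class = c("patient_dist", "matrix", "array"))
}

#' Pairwise Euclidean distances between patient summary vectors
#'
#' The magnitude-based distance: `d[i, j] = sqrt(sum_k (v_i[k] - v_j[k])^2)`
#' over the 17 per-patient summary values.
#'
#' @param summaries numeric matrix from [summarize_patients()] (rows =
#'   patients, rownames = ids).
#' @return A `patient_dist` with metric `"euclidean_summary"`.
#' @export
euclidean_distance_matrix <- function(summaries) {
  stopifnot(is.matrix(summaries), nrow(summaries) >= 2)
  if (any(!is.finite(summaries))) stop("summary vectors must be finite")
  d <- as.matrix(stats::dist(summaries, method = "euclidean"))
  patient_dist(d, "euclidean_summary")
}

# local squared-Euclidean cost grid between two multivariate series
dtw_local_cost <- function(x, y) {
  L <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * x %*% t(y)
  L[L < 0] <- 0  # guard tiny negative round-off
  L
}

# accumulated-cost DP over the |x| x |y| grid with steps (1,0),(0,1),(1,1)
dtw_accumulate <- function(L) {
  n <- nrow(L); m <- ncol(L)
  D <- matrix(NA_real_, n, m)
  D[1, ] <- cumsum(L[1, ])
  if (n > 1) D[, 1] <- cumsum(L[, 1])
  if (n > 1 && m > 1) {
    for (i in 2:n) {
      for (j in 2:m) {
        D[i, j] <- L[i, j] + min(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      }
    }
  }
  D
}

#' Multivariate dynamic time warping distance between two patients
#'
#' Aligns two z-scored multivariate visit series by dynamic programming,
#' minimizing the total squared Euclidean distance (summed over the 17
#' parameters) over all admissible warping paths with steps (1,0), (0,1) and
#' (1,1), unweighted and unwindowed. Both series start aligned at their first
#' visits; with `open_end = TRUE` (the default) either series may terminate
#' its alignment early (the cost is the minimum over the last row and last
#' column of the accumulated-cost grid), which makes the cost symmetric in
#' its arguments. The returned distance is the raw minimized sum — no square
#' root and no path-length normalization.
#'
#' Ties between equal-cost paths are broken deterministically: the diagonal
#' step is preferred, then advancing the first series, then the second;
#' among equal-cost open endpoints the longer (then more diagonal) alignment
#' wins.
#'
#' @param x,y numeric matrices (visits x parameters) with the same number of
#'   columns, at least one row each.
#' @param open_end logical; allow either series to end its alignment early.
#' @return A list with `cost` (numeric scalar), `path` (two-column integer
#'   matrix of aligned visit-index pairs, starting at (1, 1)) and `open_end`.
#' @export
dtw_distance <- function(x, y, open_end = TRUE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  if (nrow(x) < 1 || nrow(y) < 1) stop("series must have at least one visit")
  if (ncol(x) != ncol(y)) stop("series measure different parameter panels")
  L <- dtw_local_cost(x, y)
  D <- dtw_accumulate(L)
  n <- nrow(L); m <- ncol(L)
  if (open_end) {
    ends <- rbind(cbind(seq_len(n), m), cbind(n, seq_len(m)))
    ends <- ends[!duplicated(ends), , drop = FALSE]
    costs <- D[ends]
    best <- min(costs)
    cand <- ends[costs <= best + 0, , drop = FALSE]
    # prefer the longest, then most diagonal, endpoint
    ord <- order(-(cand[, 1] + cand[, 2]), -pmin(cand[, 1], cand[, 2]))
    end <- cand[ord[1], ]
  } else {
    end <- c(n, m)
    best <- D[n, m]
  }
  # backtrack, preferring diagonal, then (1,0), then (0,1)
  path <- matrix(end, 1, 2)
  i <- end[1]; j <- end[2]
  while (i > 1 || j > 1) {
    if (i > 1 && j > 1) {
      prev <- c(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      step <- which.min(prev)  # first minimum: diagonal preferred
      if (step == 1) { i <- i - 1; j <- j - 1 }
      else if (step == 2) i <- i - 1
      else j <- j - 1
    } else if (i > 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    path <- rbind(c(i, j), path)
  }
  colnames(path) <- c("x_visit", "y_visit")
  list(cost = best, path = path, open_end = open_end)
}

#' Pairwise DTW distance matrix over a cohort
#'
#' Computes [dtw_distance()] for every patient pair of a z-normalized cohort.
#' The default both-ends-open alignment cost is symmetric in the pair, so the
#' matrix entry is simply that cost (equivalently, the minimum of the two
#' orientations).
#'
#' @param cohort a normalized `sle_cohort`.
#' @param open_end passed to [dtw_distance()].
#' @return A `patient_dist` with metric `"dtw"`.
#' @export
dtw_distance_matrix <- function(cohort, open_end = TRUE) {
  stopifnot(inherits(cohort, "sle_cohort"))
  if (!isTRUE(cohort$normalized)) {
    stop("cohort must be z-normalized before DTW")
  }
  mats <- patient_matrices(cohort)
  ids <- names(mats)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    Li <- mats[[i]]
    for (j in (i + 1):n) {
      L <- dtw_local_cost(Li, mats[[j]])
      D <- dtw_accumulate(L)
      cost <- if (open_end) {
        min(min(D[, ncol(D)]), min(D[nrow(D), ]))
      } else {
        D[nrow(D), ncol(D)]
      }
      d[i, j] <- d[j, i] <- cost
    }
  }
  patient_dist(d, "dtw")
}

#' Write / read a distance matrix as CSV with a JSON companion
#'
#' The CSV is square with the ids as header row and first column; the
#' companion `<path>.meta.json` records the metric tag.
#'
#' @param d a `patient_dist`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(d, path) {
  stopifnot(inherits(d, "patient_dist"))
  out <- data.frame(patient_id = rownames(d),
                    format(unclass(d), digits = 15, trim = TRUE),
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(metric = attr(d, "metric")),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(raw$patient_id)
  m <- as.matrix(raw[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  metric <- "euclidean_summary"
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    metric <- jsonlite::read_json(meta_path)$metric
  }
  patient_dist(m, metric)
}
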