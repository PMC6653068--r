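#' Agglomerative hierarchical clustering of a patient distance matrix
#'
#' Standard bottom-up clustering: repeatedly merge the two closest clusters
#' under the linkage rule. Complete linkage (cluster distance = maximum
#' pairwise distance) is the default; single and average linkage are also
#' offered. Merge heights are nondecreasing for all three.
#'
#' @param dist a `patient_dist` (or symmetric matrix with id dimnames).
#' @param linkage `"complete"` (default), `"single"` or `"average"`.
#' @return An object of class `hclust` (leaves = patients, `$labels` = ids).
#' @export
agglomerative_cluster <- function(dist,
                                  linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  d <- unclass(dist)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 2) stop("need at least two patients to cluster")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Cut a dendrogram at a fraction of its total height
#'
#' The cut height is `fraction` times the maximum merge height (the
#' dendrogram's total height); clusters are the connected components formed
#' by merges up to that height, so the number of clusters emerges from the
#' cut rather than being chosen. `fraction = 0.9` mirrors a 90%-height cut.
#'
#' @param dend an `hclust` tree from [agglomerative_cluster()].
#' @param fraction cut fraction in (0, 1].
#' @return Named integer vector of cluster labels in `1..k` (names = patient
#'   ids), with attribute `k` and attribute `cut_height`.
#' @export
cut_at_height_fraction <- function(dend, fraction = 0.9) {
  stopifnot(inherits(dend, "hclust"), fraction > 0, fraction <= 1)
  h <- fraction * max(dend$height)
  labels <- stats::cutree(dend, h = h)
  attr(labels, "k") <- max(labels)
  attr(labels, "cut_height") <- h
  labels
}

#' Connectivity index of a clustering
#'
#' Sums, over every observation i and its `neighbors` nearest neighbours
#' (by distance, excluding self, ties broken by id order), a penalty of 0
#' when the j-th nearest neighbour shares i's cluster and 1/j otherwise.
#' Lower is better; 0 means every neighbourhood is cluster-pure.
#'
#' @param dist a `patient_dist` or symmetric matrix.
#' @param labels cluster labels aligned with the rows of `dist` (named
#'   vectors are matched by id).
#' @param neighbors neighbourhood size (default 10), must be < n.
#' @return Nonnegative numeric scalar.
#' @export
connectivity <- function(dist, labels, neighbors = 10L) {
  d <- unclass(dist)
  n <- nrow(d)
  if (neighbors < 1 || neighbors >= n) {
    stop("neighbors must be at least 1 and smaller than the number of patients")
  }
  labels <- align_labels(labels, rownames(d), n)
  total <- 0
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])  # ties broken by position (id order)
    nn <- seq_len(n)[-i][ord][seq_len(neighbors)]
    mismatch <- labels[nn] != labels[i]
    total <- total + sum(mismatch / seq_len(neighbors))
  }
  total
}

#' Dunn index of a clustering
#'
#' Ratio of the minimal inter-cluster distance (minimum pairwise distance
#' between points of different clusters) to the maximal intra-cluster
#' diameter (maximum pairwise distance within a cluster). Higher is better.
#'
#' @inheritParams connectivity
#' @return Nonnegative numeric scalar.
#' @export
dunn_index <- function(dist, labels) {
  d <- unclass(dist)
  n <- nrow(d)
  labels <- align_labels(labels, rownames(d), n)
  if (length(unique(labels)) < 2) stop("need at least two clusters")
  same <- outer(labels, labels, "==")
  off <- upper.tri(d)
  inter <- d[off & !same]
  intra <- d[off & same]
  if (length(intra) == 0) {
    stop("Dunn index undefined: every cluster is a singleton (diameter 0)")
  }
  min(inter) / max(intra)
}

align_labels <- function(labels, ids, n) {
  if (length(labels) != n) stop("labels length does not match distance matrix")
  if (!is.null(names(labels)) && !is.null(ids)) {
    if (!setequal(names(labels), ids)) {
      stop("label names do not match distance-matrix ids")
    }
    labels <- labels[ids]
  }
  as.vector(labels)
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centres the squared-distance matrix and embeds the patients on the
#' top eigenvectors. When fewer than `dims` positive eigenvalues exist the
#' embedding is padded with zero coordinates and a warning is raised.
#'
#' @param dist a `patient_dist` or symmetric matrix.
#' @param dims embedding dimension (default 2).
#' @return A list of class `embedding2d` with `ids`, `coords`
#'   (n x dims matrix), `method = "classical"` and the eigenvalues `eig`.
#' @export
classical_mds <- function(dist, dims = 2L) {
  d <- unclass(dist)
  n <- nrow(d)
  if (n <= dims) stop("need more patients than embedding dimensions")
  fit <- stats::cmdscale(stats::as.dist(d), k = dims, eig = TRUE)
  coords <- fit$points
  n_pos <- sum(fit$eig > max(fit$eig) * 1e-8)
  if (n_pos < dims) {
    warning(sprintf(
      "only %d positive eigenvalue(s); embedding padded to %d dimension(s)",
      n_pos, dims))
    if (ncol(coords) < dims) {
      coords <- cbind(coords, matrix(0, n, dims - ncol(coords)))
    }
    coords[, seq_len(dims) > n_pos] <- 0
  }
  rownames(coords) <- rownames(d)
  structure(list(ids = rownames(d), coords = coords, method = "classical",
                 eig = fit$eig),
            class = "embedding2d")
}

#' Isotonic (nonmetric) multidimensional scaling
#'
#' Rank-preserving embedding minimizing Kruskal's stress-1 by alternating
#' isotonic regression on the distance ranks with coordinate updates,
#' initialized from [classical_mds()] so the result is deterministic for a
#' given input. Stress is reported as a fraction (0 = perfect rank fit).
#' Zero off-diagonal distances (indistinguishable patients) are nudged to a
#' tiny positive value with a warning, since rank-based stress is undefined
#' on them.
#'
#' @param dist a `patient_dist` or symmetric matrix.
#' @param dims embedding dimension (default 2).
#' @param max_iter maximum number of stress-minimization iterations.
#' @param tol convergence tolerance on the stress decrease.
#' @return A list of class `embedding2d` with `ids`, `coords`, `stress`
#'   (fraction) and `method = "isotonic"`.
#' @export
isotonic_mds <- function(dist, dims = 2L, max_iter = 500L, tol = 1e-9) {
  d <- unclass(dist)
  n <- nrow(d)
  if (n <= dims) stop("need more patients than embedding dimensions")
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    warning("zero off-diagonal distance(s) nudged for nonmetric scaling")
    eps <- min(off[off > 0]) * 1e-6
    d[d == 0] <- eps
    diag(d) <- 0
  }
  init <- classical_mds(d, dims)$coords
  fit <- MASS::isoMDS(stats::as.dist(d), y = init, k = dims,
                      maxit = max_iter, tol = tol, trace = FALSE)
  coords <- fit$points
  rownames(coords) <- rownames(d)
  structure(list(ids = rownames(d), coords = coords,
                 stress = fit$stress / 100, method = "isotonic"),
            class = "embedding2d")
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d> %s MDS of %d patients in %d dims%s\n",
              x$method, length(x$ids), ncol(x$coords),
              if (!is.null(x$stress)) sprintf(", stress %.3g", x$stress) else ""))
  invisible(x)
}

#' Scan candidate numbers of clusters
#'
#' Cuts the dendrogram at each k in `k_range` and tabulates mean silhouette
#' width, connectivity and Dunn index, as plumbing for choosing k.
#'
#' @param dist a `patient_dist` or symmetric matrix.
#' @param k_range integer vector of candidate cluster counts, within 2..n-1.
#' @param linkage linkage rule for the underlying dendrogram.
#' @param neighbors neighbourhood size for [connectivity()].
#' @return data.frame with columns `k`, `silhouette`, `connectivity`, `dunn`.
#' @export
suggest_k <- function(dist, k_range = 2:6,
                      linkage = c("complete", "single", "average"),
                      neighbors = 10L) {
  d <- unclass(dist)
  n <- nrow(d)
  stopifnot(all(k_range >= 2), all(k_range <= n - 1))
  if (max(d) == 0) warning("all patients identical: cluster indices degenerate")
  hc <- agglomerative_cluster(dist, match.arg(linkage))
  rows <- lapply(k_range, function(k) {
    labs <- stats::cutree(hc, k = k)
    sil <- tryCatch(
      mean(cluster::silhouette(labs, stats::as.dist(d))[, "sil_width"]),
      error = function(e) NA_real_)
    conn <- tryCatch(connectivity(d, labs, min(neighbors, n - 1)),
                     error = function(e) NA_real_)
    dn <- tryCatch(dunn_index(d, labs), error = function(e) NA_real_)
    data.frame(k = k, silhouette = sil, connectivity = conn, dunn = dn)
  })
  do.call(rbind, rows)
}
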