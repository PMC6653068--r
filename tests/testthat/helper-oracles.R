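# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# exhaustive enumeration of all admissible warping paths (steps (1,0), (0,1),
# (1,1), start at (1,1)); feasible for grids up to ~6x6
dtw_oracle <- function(x, y, open_end = FALSE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  n <- nrow(x)
  m <- nrow(y)
  best <- Inf
  recurse <- function(i, j, cost) {
    cost <- cost + sum((x[i, ] - y[j, ])^2)
    at_end <- if (open_end) (i == n || j == m) else (i == n && j == m)
    if (at_end) best <<- min(best, cost)
    if (i < n) recurse(i + 1L, j, cost)
    if (j < m) recurse(i, j + 1L, cost)
    if (i < n && j < m) recurse(i + 1L, j + 1L, cost)
  }
  recurse(1L, 1L, 0)
  best
}

# connectivity by direct definition, nearest-neighbour ties by index order
connectivity_oracle <- function(d, labels, neighbors) {
  n <- nrow(d)
  total <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nn <- others[order(d[i, others])][seq_len(neighbors)]
    for (j in seq_len(neighbors)) {
      if (labels[nn[j]] != labels[i]) total <- total + 1 / j
    }
  }
  total
}

# Dunn index by double loops over all point pairs
dunn_oracle <- function(d, labels) {
  n <- nrow(d)
  inter <- Inf
  intra <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (labels[i] == labels[j]) intra <- max(intra, d[i, j])
      else inter <- min(inter, d[i, j])
    }
  }
  inter / intra
}

# naive O(n^3) agglomerative linkage: returns merge heights and the partition
# (label vector) after each merge
naive_linkage <- function(d, method = c("complete", "single", "average")) {
  method <- match.arg(method)
  n <- nrow(d)
  members <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(members) > 1) {
    bh <- Inf
    bi <- bj <- NA
    for (i in seq_len(length(members) - 1)) {
      for (j in (i + 1):length(members)) {
        vals <- d[members[[i]], members[[j]]]
        h <- switch(method, complete = max(vals), single = min(vals),
                    average = mean(vals))
        if (h < bh) {
          bh <- h
          bi <- i
          bj <- j
        }
      }
    }
    members[[bi]] <- c(members[[bi]], members[[bj]])
    members[[bj]] <- NULL
    heights <- c(heights, bh)
    labs <- integer(n)
    for (k in seq_along(members)) labs[members[[k]]] <- k
    partitions <- c(partitions, list(labs))
  }
  list(heights = heights, partitions = partitions)
}

# adjusted Rand by explicit pair counting
ari_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  tot <- s11 + s00 + s10 + s01
  expected <- (s11 + s10) * (s11 + s01) / tot
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  (s11 - expected) / (maxi - expected)
}

# two-sided exact p for a 2x2 table by full enumeration of the conditional
# (hypergeometric) distribution given the margins
exact_p_oracle <- function(a, b, c, d) {
  m1 <- a + b  # exposed row total
  k1 <- a + c  # outcome column total
  N <- a + b + c + d
  support <- max(0, k1 - (N - m1)):min(m1, k1)
  probs <- vapply(support, function(k) {
    choose(m1, k) * choose(N - m1, k1 - k) / choose(N, k1)
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# OLS by explicit normal equations
ols_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# small exactly-linear cohort: sledai is an integer-valued exact linear
# combination of the current (and optionally lagged) parameters
make_linear_cohort <- function(n_pat = 8, n_vis = 5, lagged = FALSE,
                               seed = 11) {
  set.seed(seed)
  panel <- parameter_panel()
  beta <- rep(c(1, -1, 2, 0), length.out = 17)
  gamma <- if (lagged) rep(c(0, 1), length.out = 17) else rep(0, 17)
  rows <- list()
  for (p in seq_len(n_pat)) {
    vals <- matrix(sample(-3:3, n_vis * 17, replace = TRUE), n_vis, 17)
    lagvals <- rbind(0, vals[-n_vis, , drop = FALSE])
    sl <- 10 + vals %*% beta + lagvals %*% gamma
    colnames(vals) <- panel
    rows[[p]] <- data.frame(patient_id = sprintf("L%02d", p),
                            day = seq_len(n_vis) - 1, sledai = as.vector(sl),
                            vals, check.names = FALSE)
  }
  cohort <- sle_cohort(do.call(rbind, rows))
  cohort$normalized <- TRUE  # values are already comparable across patients
  cohort
}

random_patient_dist <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(rnorm(n * 3), n, 3)
  rownames(pts) <- sprintf("R%02d", seq_len(n))
  as.matrix(dist(pts))
}
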