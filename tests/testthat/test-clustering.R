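three_point_dist <- function() {
  d <- matrix(c(0, 1, 10,
                1, 0, 10,
                10, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d
}

test_that("forced merge orders come out of the linkage engine", {
  hc <- agglomerative_cluster(three_point_dist())
  expect_equal(hc$height, c(1, 10))
  expect_equal(sort(cutree(hc, 2)), sort(c(A = 1, B = 1, C = 2)))

  two <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(agglomerative_cluster(two)$height, 3)

  asym <- three_point_dist(); asym[1, 2] <- 5
  expect_error(agglomerative_cluster(asym), "symmetric")
})

test_that("linkage engine matches the naive O(n^3) reference", {
  for (seed in 1:6) {
    d <- random_patient_dist(8, seed = seed)
    for (method in c("complete", "single", "average")) {
      hc <- agglomerative_cluster(d, method)
      ref <- naive_linkage(d, method)
      expect_equal(hc$height, ref$heights, tolerance = 1e-12)
      for (step in seq_along(ref$partitions)) {
        k <- 8 - step
        if (k < 2) next  # agreement is undefined for the single-cluster root
        expect_equal(ari_oracle(cutree(hc, k), ref$partitions[[step]]), 1)
      }
    }
  }
})

test_that("height-fraction cuts behave as documented", {
  hc <- agglomerative_cluster(three_point_dist())
  expect_equal(attr(cut_at_height_fraction(hc, 1.0), "k"), 1L)
  labs <- cut_at_height_fraction(hc, 0.5)  # cut at 5: {A,B} vs {C}
  expect_equal(attr(labs, "k"), 2L)
  expect_equal(unname(labs["A"]), unname(labs["B"]))
  expect_false(labs["A"] == labs["C"])

  # invariance to leaf order: permuting the distance matrix permutes labels
  # but not the partition
  d <- random_patient_dist(10, seed = 77)
  labs1 <- cut_at_height_fraction(agglomerative_cluster(d), 0.7)
  perm <- sample(10)
  dp <- d[perm, perm]
  labs2 <- cut_at_height_fraction(agglomerative_cluster(dp), 0.7)
  expect_equal(ari_oracle(labs1[rownames(d)], labs2[rownames(d)]), 1)
})

test_that("connectivity matches its definition, including the line example", {
  # two tight, well-separated clusters: no penalty at all
  pts <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), ncol = 1)
  rownames(pts) <- sprintf("p%d", 1:6)
  d <- as.matrix(dist(pts))
  labs <- setNames(rep(1:2, each = 3), rownames(pts))
  expect_equal(connectivity(d, labs, neighbors = 2), 0)

  # four collinear points at 0,1,2,3 split down the middle, 2 neighbours:
  # enumerating neighbour lists (ties by id order) gives 1/2 + 1/2 + 1 + 1/2
  line <- as.matrix(dist(matrix(0:3, ncol = 1)))
  dimnames(line) <- list(LETTERS[1:4], LETTERS[1:4])
  labs4 <- setNames(c(1, 1, 2, 2), LETTERS[1:4])
  expect_equal(connectivity(line, labs4, neighbors = 2),
               connectivity_oracle(line, labs4, 2))
  expect_equal(connectivity(line, labs4, neighbors = 2), 2.5)

  expect_error(connectivity(line, labs4, neighbors = 4), "smaller")

  # random labellings are less connected than distance-compact ones
  set.seed(55)
  worse <- replicate(100, {
    pts <- rbind(matrix(rnorm(10, 0), 5), matrix(rnorm(10, 6), 5))
    rownames(pts) <- sprintf("q%d", 1:10)
    dd <- as.matrix(dist(pts))
    compact <- setNames(rep(1:2, each = 5), rownames(pts))
    random <- setNames(sample(compact), rownames(pts))
    connectivity(dd, random, 3) > connectivity(dd, compact, 3)
  })
  expect_gte(mean(worse), 0.95)
})

test_that("Dunn index is min-separation over max-diameter", {
  line <- as.matrix(dist(matrix(c(0, 1, 10, 11), ncol = 1)))
  dimnames(line) <- list(letters[1:4], letters[1:4])
  expect_equal(dunn_index(line, setNames(c(1, 1, 2, 2), letters[1:4])), 9)

  overlap <- as.matrix(dist(matrix(c(0, 5, 4, 9), ncol = 1)))
  dimnames(overlap) <- list(letters[1:4], letters[1:4])
  expect_equal(dunn_index(overlap, setNames(c(1, 1, 2, 2), letters[1:4])), 0.2)

  for (seed in 1:8) {
    d <- random_patient_dist(12, seed = seed + 100)
    labs <- setNames(sample(3, 12, replace = TRUE), rownames(d))
    if (length(unique(labs)) < 2 || max(table(labs)) < 2) next
    expect_equal(dunn_index(d, labs), dunn_oracle(d, unname(labs[rownames(d)])))
  }

  singles <- as.matrix(dist(matrix(c(0, 7), ncol = 1)))
  dimnames(singles) <- list(c("a", "b"), c("a", "b"))
  expect_error(dunn_index(singles, setNames(1:2, c("a", "b"))), "singleton")
})

test_that("classical MDS exactly inverts planar configurations", {
  set.seed(9)
  pts <- matrix(rnorm(10), 5, 2)
  rownames(pts) <- sprintf("m%d", 1:5)
  d <- as.matrix(dist(pts))
  emb <- classical_mds(d)
  expect_lt(max(abs(as.matrix(dist(emb$coords)) - d)), 1e-8)

  # three equidistant points embed as a unit equilateral triangle
  tri <- matrix(1, 3, 3) - diag(3)
  dimnames(tri) <- list(c("u", "v", "w"), c("u", "v", "w"))
  emb3 <- classical_mds(tri)
  expect_lt(max(abs(as.matrix(dist(emb3$coords)) - tri)), 1e-8)

  # rank-2 optimality: residual equals the trailing eigenvalue mass
  pts4 <- matrix(rnorm(16), 4, 4)
  rownames(pts4) <- sprintf("r%d", 1:4)
  d4 <- as.matrix(dist(pts4))
  emb4 <- classical_mds(d4, dims = 2)
  expect_equal(sort(emb4$eig, decreasing = TRUE)[1:2],
               sort(apply(emb4$coords, 2, function(cl) sum(cl^2)),
                    decreasing = TRUE))

  # collinear points have one positive eigenvalue: padded with a warning
  coll <- as.matrix(dist(matrix(c(0, 1, 2), ncol = 1)))
  dimnames(coll) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_warning(embc <- classical_mds(coll), "padded")
  expect_identical(dim(embc$coords), c(3L, 2L))
})

test_that("isotonic MDS reaches near-zero stress on realizable inputs", {
  set.seed(23)
  pts <- matrix(rnorm(16), 8, 2)
  rownames(pts) <- sprintf("i%d", 1:8)
  d <- as.matrix(dist(pts))
  emb <- isotonic_mds(d)
  expect_lt(emb$stress, 1e-6)

  # nonmetric invariance: a monotone transform of the distances leaves a
  # rank-perfect 2-D solution reachable
  emb_sq <- isotonic_mds(d^2)
  expect_lt(emb_sq$stress, 1e-3)

  # deterministic: same input, same embedding
  emb2 <- isotonic_mds(d^2)
  expect_identical(emb$coords, isotonic_mds(d)$coords)
  expect_identical(emb_sq$coords, emb2$coords)
})

test_that("the k scan tabulates indices and flags degeneracy", {
  set.seed(64)
  pts <- rbind(matrix(rnorm(20, 0, 0.3), 10), matrix(rnorm(20, 5, 0.3), 10))
  rownames(pts) <- sprintf("s%02d", 1:20)
  d <- as.matrix(dist(pts))
  tab <- suggest_k(d, 2:5)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$k[which.max(tab$silhouette)], 2)

  flat <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(suggest_k(flat, 2:3), "identical")
})
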