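test_that("euclidean and mahalanobis distances match brute-force oracles", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  rownames(X) <- letters[1:10]
  D <- as.matrix(euclidean_distance(X))
  for (i in 1:10) for (j in 1:10)
    expect_equal(D[i, j], sqrt(sum((X[i, ] - X[j, ])^2)), tolerance = 1e-12)
  expect_equal(as.matrix(euclidean_distance(rbind(c(0, 0), c(3, 4))))[1, 2], 5)

  Y <- matrix(rnorm(60), 20, 3)
  Dm <- as.matrix(mahalanobis_distance(Y))
  expect_equal(Dm, brute_mahalanobis(Y, solve(cov(Y))), tolerance = 1e-9,
               ignore_attr = TRUE)
  # identity covariance: mahalanobis equals euclidean on whitened data
  set.seed(3)
  W <- matrix(rnorm(400), 100, 4)
  W <- W %*% solve(chol(cov(W)))           # sample covariance = identity
  expect_equal(as.matrix(mahalanobis_distance(W)),
               as.matrix(euclidean_distance(W)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # 1-D case: |x_i - x_j| / sqrt(var)
  x <- c(1, 4, 9)
  D1 <- as.matrix(mahalanobis_distance(matrix(x)))
  expect_equal(D1[1, 2], 3 / sd(x), tolerance = 1e-12)
  # singular covariance falls back to the pseudo-inverse
  Xs <- cbind(Y[, 1], Y[, 1], Y[, 2])
  expect_silent(mahalanobis_distance(Xs))
})

test_that("single and complete linkage follow the hand-traced 3-point merges", {
  D <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  D["a", "b"] <- D["b", "a"] <- 1
  D["a", "c"] <- D["c", "a"] <- 2
  D["b", "c"] <- D["c", "b"] <- 3
  ts <- agglomerate(as.dist(D), "single")
  expect_equal(ts$height, c(1, 2))
  tc <- agglomerate(as.dist(D), "complete")
  expect_equal(tc$height, c(1, 3))
  expect_equal(unname(cut_tree(ts, 2)), c(1, 1, 2))
  expect_equal(unname(cut_tree(ts, 3)), 1:3)
  expect_equal(unname(cut_tree(ts, 1)), c(1, 1, 1))
  expect_error(cut_tree(ts, 4), "k must be")
})

test_that("all eight linkages match the naive recompute-from-scratch oracle", {
  for (inst in 1:12) {
    set.seed(100 + inst)
    X <- matrix(rnorm(15 * 3), 15, 3)
    D <- euclidean_distance(X)
    for (m in linkage_methods()) {
      got <- agglomerate(D, m)$height
      want <- naive_agglomerate_heights(X, m)
      expect_equal(got, want, tolerance = 1e-9,
                   label = sprintf("%s heights (instance %d)", m, inst))
    }
  }
})

test_that("linkages shared with stats::hclust give identical heights", {
  set.seed(77)
  X <- matrix(rnorm(25 * 4), 25, 4)
  D <- euclidean_distance(X)
  pairs <- list(single = "single", complete = "complete",
                group_average = "average", weighted_average = "mcquitty",
                ward = "ward.D2")
  for (m in names(pairs)) {
    expect_equal(sort(agglomerate(D, m)$height),
                 sort(hclust(D, pairs[[m]])$height), tolerance = 1e-9,
                 label = m)
  }
  # squared-input conventions for centroid and median
  for (m in c("centroid", "median")) {
    expect_equal(sort(agglomerate(D, m)$height),
                 sort(sqrt(hclust(D^2, m)$height)), tolerance = 1e-9,
                 label = m)
  }
})

test_that("linear linkage heights scale with the distance matrix", {
  set.seed(9)
  X <- matrix(rnorm(30), 10, 3)
  D <- euclidean_distance(X)
  for (m in c("single", "complete", "group_average", "weighted_average",
              "flexible")) {
    h1 <- agglomerate(D, m)$height
    h2 <- agglomerate(D * 3.5, m)$height
    expect_equal(h2, 3.5 * h1, tolerance = 1e-9, label = m)
  }
  # single-linkage heights are monotone non-decreasing
  expect_true(all(diff(agglomerate(D, "single")$height) >= -1e-12))
})

test_that("agglomerate validates input and cut_tree returns every partition size", {
  M <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(agglomerate(M), "symmetric")
  set.seed(4)
  X <- matrix(rnorm(24), 8, 3)
  tr <- agglomerate(euclidean_distance(X), "ward")
  for (k in 1:8) expect_equal(length(unique(cut_tree(tr, k))), k)
})

test_that("neighbor joining recovers additive trees exactly", {
  for (s in 1:20) {
    ad <- random_additive_tree(6, seed = s)
    tr <- neighbor_joining(ad$D)
    got <- ape::cophenetic.phylo(tr)[rownames(ad$D), colnames(ad$D)]
    expect_equal(got, ad$D, tolerance = 1e-9,
                 label = sprintf("path lengths (seed %d)", s))
  }
  # 4-leaf hand case
  ad4 <- random_additive_tree(4, seed = 1)
  tr4 <- neighbor_joining(ad4$D)
  expect_equal(ape::dist.topo(ape::unroot(ad4$tree), tr4)[1], 0,
               ignore_attr = TRUE)
  # star tree: all internal branches zero after clamping
  Dstar <- matrix(2, 5, 5); diag(Dstar) <- 0
  dimnames(Dstar) <- list(letters[1:5], letters[1:5])
  trs <- neighbor_joining(Dstar)
  internal <- trs$edge[, 2] > ape::Ntip(trs)
  expect_true(all(trs$edge.length[internal] < 1e-9))
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
})
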