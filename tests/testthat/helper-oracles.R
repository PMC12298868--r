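# Independent oracles used across the suite. These recompute quantities from
# first principles (set definitions, geometry, brute-force loops) and stay
# independent of the package's implementation paths.

# Naive recompute-from-scratch agglomerative clustering on a point matrix X
# (Euclidean). At every step, all active inter-cluster distances are rebuilt
# from the original data:
#   single/complete/group_average - min/max/mean over leaf pairs
#   weighted_average              - dyadic-weighted mean over leaf pairs
#   centroid/ward                 - cluster-centroid geometry (squared space)
#   median                        - recursive midpoint geometry (squared space)
#   flexible                      - its defining recursion, in an independent
#                                   shrinking-matrix implementation
# Heights for centroid/median/ward are square roots of the squared-space
# merge distances. Returns the height sequence in merge order.
naive_agglomerate_heights <- function(X, method, beta = -0.25) {
  n <- nrow(X)
  D0 <- as.matrix(stats::dist(X))
  members <- as.list(seq_len(n))           # leaf index sets
  wts <- lapply(seq_len(n), function(i) stats::setNames(1, i))
  medpt <- lapply(seq_len(n), function(i) X[i, ])
  Fmat <- D0                               # flexible recursion state
  squared <- method %in% c("centroid", "median", "ward")
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(members)
    M <- matrix(Inf, k, k)
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      A <- members[[a]]; B <- members[[b]]
      sub <- D0[A, B, drop = FALSE]
      M[a, b] <- switch(method,
        single = min(sub),
        complete = max(sub),
        group_average = mean(sub),
        weighted_average = as.numeric(t(wts[[a]]) %*% sub %*% wts[[b]]),
        centroid = sum((colMeans(X[A, , drop = FALSE]) -
                        colMeans(X[B, , drop = FALSE]))^2),
        ward = {
          ca <- colMeans(X[A, , drop = FALSE])
          cb <- colMeans(X[B, , drop = FALSE])
          2 * length(A) * length(B) / (length(A) + length(B)) *
            sum((ca - cb)^2)
        },
        median = sum((medpt[[a]] - medpt[[b]])^2),
        flexible = Fmat[a, b])
    }
    idx <- which(M == min(M), arr.ind = TRUE)[1L, ]
    a <- idx[1L]; b <- idx[2L]
    heights[step] <- if (squared) sqrt(M[a, b]) else M[a, b]
    if (method == "flexible") {
      others <- setdiff(seq_len(k), c(a, b))
      newrow <- (1 - beta) / 2 * (Fmat[a, others] + Fmat[b, others]) +
        beta * Fmat[a, b]
      Fmat <- Fmat[-c(a, b), -c(a, b), drop = FALSE]
      Fmat <- rbind(cbind(Fmat, newrow), c(newrow, 0))
    }
    merged <- c(members[[a]], members[[b]])
    new_wts <- c(wts[[a]] / 2, wts[[b]] / 2)
    new_med <- (medpt[[a]] + medpt[[b]]) / 2
    members <- c(members[-c(a, b)], list(merged))
    wts <- c(wts[-c(a, b)], list(new_wts))
    medpt <- c(medpt[-c(a, b)], list(new_med))
  }
  heights
}

# Random unrooted binary tree with strictly positive branch lengths and its
# additive (path-length) distance matrix.
random_additive_tree <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_leaves, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 2)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# Brute-force pairwise squared Mahalanobis via an explicit loop.
brute_mahalanobis <- function(X, Sinv) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- X[i, ] - X[j, ]
    D[i, j] <- sqrt(drop(t(v) %*% Sinv %*% v))
  }
  D
}

# Brute-force GSC by per-pair, per-locus counting.
brute_gsc <- function(calls) {
  n <- nrow(calls)
  out <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
    s <- 1 - abs(calls[i, ok] - calls[j, ok]) / 2
    out[i, j] <- out[j, i] <- mean(s)
  }
  out
}

# Small structured genotype fixture shared by several tests.
small_geno <- function(seed = 42, n = 30, L = 200) {
  simulate_genotypes(geno_sim_config(
    n_accessions = n, n_loci = L, n_subpops = 3, fst = 0.2,
    chrom_sizes = c(ceiling(L / 2), floor(L / 2)), missing_rate = 0.01,
    seed = seed))
}
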