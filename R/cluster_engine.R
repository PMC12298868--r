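#' Euclidean distance matrix between accessions
#'
#' @param X numeric matrix (accessions x traits, typically z-standardized)
#'   or trait_matrix; no missing values (impute upstream).
#' @return \code{dist} object with accession labels.
#' @export
euclidean_distance <- function(X) {
  if (inherits(X, "trait_matrix")) X <- X$values
  X <- as.matrix(X)
  if (anyDuplicated(rownames(X))) stop("duplicate accession ids")
  if (anyNA(X)) stop("missing values present; impute before distances")
  stats::dist(X, method = "euclidean")
}

#' Pairwise Mahalanobis distance between accessions
#'
#' d(i,j) = sqrt((x_i - x_j)' S^- (x_i - x_j)) with S the sample covariance
#' of the rows. S^- is the ordinary inverse when S is well conditioned, the
#' Moore-Penrose pseudo-inverse when singular, or (S + lambda I)^-1 when a
#' ridge \code{cov_regularization} lambda > 0 is given.
#'
#' @param X numeric matrix or trait_matrix, no missing values.
#' @param cov_regularization ridge lambda >= 0 added to the covariance
#'   diagonal before inversion.
#' @return \code{dist} object.
#' @export
mahalanobis_distance <- function(X, cov_regularization = 0) {
  if (inherits(X, "trait_matrix")) X <- X$values
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing values present; impute before distances")
  if (nrow(X) < 2L) stop("need at least 2 accessions")
  stopifnot(cov_regularization >= 0)
  S <- stats::cov(X)
  Sinv <- if (cov_regularization > 0) {
    solve(S + diag(cov_regularization, ncol(S)))
  } else {
    inv <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(inv) || rcond(S) < 1e-12) MASS::ginv(S) else inv
  }
  W <- X %*% Sinv
  q <- rowSums(W * X)
  D2 <- outer(q, q, `+`) - 2 * W %*% t(X)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  dimnames(D) <- list(rownames(X), rownames(X))
  stats::as.dist(D)
}

lw_params <- function(method, flexible_beta, ni, nj, nk) {
  switch(method,
    single           = c(0.5, 0.5, 0, -0.5),
    complete         = c(0.5, 0.5, 0, 0.5),
    median           = c(0.5, 0.5, -0.25, 0),
    centroid         = c(ni / (ni + nj), nj / (ni + nj),
                         -ni * nj / (ni + nj)^2, 0),
    group_average    = c(ni / (ni + nj), nj / (ni + nj), 0, 0),
    weighted_average = c(0.5, 0.5, 0, 0),
    flexible         = c((1 - flexible_beta) / 2, (1 - flexible_beta) / 2,
                         flexible_beta, 0),
    ward             = c((ni + nk) / (ni + nj + nk),
                         (nj + nk) / (ni + nj + nk),
                         -nk / (ni + nj + nk), 0),
    stop("unknown linkage method: ", method)
  )
}

#' Linkage methods of the agglomeration engine
#' @return character vector of supported method names.
#' @export
linkage_methods <- function() {
  c("single", "complete", "median", "centroid", "group_average",
    "weighted_average", "flexible", "ward")
}

# methods whose Lance-Williams recurrence operates on squared distances;
# reported merge heights are square-rooted back to the input scale
lw_squared_methods <- c("median", "centroid", "ward")

#' Agglomerative clustering via the Lance-Williams recurrence
#'
#' Repeatedly merges the globally nearest pair of clusters and updates
#' inter-cluster distances by d(k, ij) = a_i d(k,i) + a_j d(k,j) + b d(i,j)
#' + g |d(k,i) - d(k,j)|, with parameters per method: single (1/2, 1/2, 0,
#' -1/2), complete (1/2, 1/2, 0, 1/2), median (1/2, 1/2, -1/4, 0), centroid
#' (n_i/(n_i+n_j), n_j/(n_i+n_j), -n_i n_j/(n_i+n_j)^2, 0), group_average
#' (n_i/(n_i+n_j), n_j/(n_i+n_j), 0, 0), weighted_average (1/2, 1/2, 0, 0),
#' flexible ((1-beta)/2, (1-beta)/2, beta, 0), ward ((n_i+n_k)/N,
#' (n_j+n_k)/N, -n_k/N, 0) with N = n_i+n_j+n_k. The ward, centroid and
#' median recurrences run on squared distances (the scale on which their
#' parameters are geometrically exact) and reported heights are square
#' roots, matching the \code{ward.D2}/squared-input conventions of
#' \code{stats::hclust}. Nearest-pair ties are broken by the smallest
#' (i, j) index pair, scanning rows first.
#'
#' @param D \code{dist} object or symmetric numeric matrix with zero
#'   diagonal.
#' @param method one of \code{linkage_methods()}.
#' @param flexible_beta beta for the flexible method (default -0.25).
#' @return object of class \code{merge_tree}: list with \code{merge}
#'   (hclust-convention (n-1) x 2), \code{height}, \code{size} (members per
#'   merged cluster), \code{labels}, \code{method}.
#' @export
agglomerate <- function(D, method = "ward", flexible_beta = -0.25) {
  method <- match.arg(method, linkage_methods())
  if (inherits(D, "dist")) {
    labels <- attr(D, "Labels")
    M <- as.matrix(D)
  } else {
    M <- as.matrix(D)
    if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8)))
      stop("distance matrix must be symmetric")
    labels <- rownames(M)
  }
  n <- nrow(M)
  if (n < 2L) stop("need at least 2 items")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  squared <- method %in% lw_squared_methods
  if (squared) M <- M^2
  diag(M) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  code <- -seq_len(n)               # hclust convention: negative = leaf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  msize <- integer(n - 1L)
  for (step in seq_len(n - 1L)) {
    # row-major scan of the transposed matrix = lexicographic (i, j) ties
    idx <- which.min(t(M))
    j <- (idx - 1L) %/% n + 1L
    i <- idx - (j - 1L) * n
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    dij <- M[i, j]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- if (squared) sqrt(dij) else dij
    ni <- sizes[i]; nj <- sizes[j]
    ks <- which(active); ks <- ks[ks != i & ks != j]
    if (length(ks)) {
      nk <- sizes[ks]
      a <- vapply(nk, function(nkk)
        lw_params(method, flexible_beta, ni, nj, nkk), numeric(4L))
      dk <- a[1L, ] * M[ks, i] + a[2L, ] * M[ks, j] + a[3L, ] * dij +
        a[4L, ] * abs(M[ks, i] - M[ks, j])
      M[i, ks] <- dk
      M[ks, i] <- dk
    }
    active[j] <- FALSE
    M[j, ] <- Inf
    M[, j] <- Inf
    sizes[i] <- ni + nj
    code[i] <- step
    msize[step] <- sizes[i]
  }
  structure(list(merge = merge, height = height, size = msize,
                 labels = labels, method = method),
            class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("merge_tree (%s linkage): %d leaves, %d merges\n",
              x$method, length(x$labels), nrow(x$merge)))
  invisible(x)
}

#' @export
as.hclust.merge_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = tree_leaf_order(x$merge),
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = "unknown"),
            class = "hclust")
}

tree_leaf_order <- function(merge) {
  expand <- function(row) {
    out <- integer(0)
    for (v in merge[row, ]) {
      out <- c(out, if (v < 0) -v else expand(v))
    }
    out
  }
  expand(nrow(merge))
}

#' Cut a merge tree into k clusters
#'
#' Undoes the last k - 1 merges: cluster membership is defined by the first
#' n - k merges, regardless of heights, so non-monotone trees (centroid,
#' median) cut deterministically. Clusters are numbered 1..k in order of
#' first appearance along the leaf id list.
#'
#' @param tree merge_tree.
#' @param k number of clusters, 1 <= k <= n.
#' @return named integer vector of cluster labels.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "merge_tree"))
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  parent <- seq_len(n)
  find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
  cluster_rep <- integer(n - 1L)     # representative leaf of each merge row
  nmerge <- n - k
  for (s in seq_len(n - 1L)) {
    a <- tree$merge[s, 1L]; b <- tree$merge[s, 2L]
    ra <- if (a < 0) -a else cluster_rep[a]
    rb <- if (b < 0) -b else cluster_rep[b]
    if (s <= nmerge) {
      ra <- find(ra); rb <- find(rb)
      parent[rb] <- ra
      cluster_rep[s] <- ra
    } else {
      cluster_rep[s] <- find(ra)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  lab <- integer(n)
  nxt <- 0L
  seen <- integer(0)
  for (i in seq_len(n)) {
    r <- roots[i]
    pos <- match(r, seen)
    if (is.na(pos)) {
      nxt <- nxt + 1L
      seen[nxt] <- r
      pos <- nxt
    }
    lab[i] <- pos
  }
  stats::setNames(lab, tree$labels)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \code{ape::nj}) with negative branch
#' lengths clamped to zero. On additive distances the generating tree is
#' recovered exactly.
#'
#' @param D \code{dist} object or symmetric matrix, n >= 3 accessions.
#' @return unrooted \code{phylo} tree.
#' @export
neighbor_joining <- function(D) {
  M <- as.matrix(D)
  if (nrow(M) < 3L) stop("neighbor joining needs at least 3 accessions")
  tree <- ape::nj(stats::as.dist(M))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Write a tree in newick format
#' @param tree phylo object
#' @param path output path
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
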