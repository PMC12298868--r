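# round-half-away-from-zero (base round() is banker's rounding)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Define a core-sampling strategy
#'
#' @param distance \code{"euclidean"} or \code{"mahalanobis"}.
#' @param ratio sampling ratio in (0, 1].
#' @param allocation within-cluster representative choice:
#'   \code{"random"} (seeded uniform draw) or \code{"deviation"} (member
#'   with the maximum squared deviation from the cluster centroid).
#' @param linkage one of \code{linkage_methods()}.
#' @param seed RNG seed used by random allocation.
#' @param flexible_beta beta for the flexible linkage.
#' @return list of class \code{sampling_strategy}.
#' @export
sampling_strategy <- function(distance = "mahalanobis", ratio = 0.2,
                              allocation = "deviation", linkage = "flexible",
                              seed = 1L, flexible_beta = -0.25) {
  distance <- match.arg(distance, c("euclidean", "mahalanobis"))
  allocation <- match.arg(allocation, c("random", "deviation"))
  linkage <- match.arg(linkage, linkage_methods())
  if (ratio <= 0 || ratio > 1) stop("ratio must be in (0, 1]")
  structure(list(distance = distance, ratio = ratio, allocation = allocation,
                 linkage = linkage, seed = as.integer(seed),
                 flexible_beta = flexible_beta),
            class = "sampling_strategy")
}

strategy_label <- function(s) {
  sprintf("%s+%d%%+%s+%s", s$distance, round(100 * s$ratio), s$allocation,
          s$linkage)
}

#' Sample a phenotypic core collection by stepwise cluster cutting
#'
#' Z-standardizes the trait table, builds the strategy's distance matrix,
#' agglomerates with the strategy's linkage, cuts the dendrogram into
#' k = round(ratio n) clusters (half-away-from-zero rounding) and selects
#' one representative per cluster: a seeded uniform draw (random
#' allocation) or the member with the maximum sum of squared deviations
#' from the cluster centroid in standardized trait space (deviation
#' allocation; retains maximal variance). Ties in deviation allocation
#' break on the earliest accession in id order. Singleton clusters
#' contribute their sole member.
#'
#' @param tm trait_matrix.
#' @param strategy sampling_strategy.
#' @param tree optional precomputed merge_tree for this distance/linkage
#'   (reused across ratios/allocations in a grid).
#' @return list of class \code{core_set}: \code{selected}, \code{reserve},
#'   \code{strategy}, \code{clusters}.
#' @export
sample_core <- function(tm, strategy, tree = NULL) {
  stopifnot(inherits(tm, "trait_matrix"), inherits(strategy, "sampling_strategy"))
  n <- nrow(tm$values)
  k <- round_half_up(strategy$ratio * n)
  if (k < 1L) stop("ratio too small: core would be empty")
  if (k > n) stop("core size exceeds panel size")
  Z <- zstandardize(tm)$values
  if (is.null(tree)) {
    D <- switch(strategy$distance,
                euclidean = euclidean_distance(Z),
                mahalanobis = mahalanobis_distance(Z))
    tree <- agglomerate(D, strategy$linkage, strategy$flexible_beta)
  }
  labels <- cut_tree(tree, k)
  ids <- rownames(Z)
  if (strategy$allocation == "random") set.seed(strategy$seed)
  selected <- vapply(seq_len(k), function(cl) {
    members <- ids[labels == cl]
    if (length(members) == 1L) return(members)
    if (strategy$allocation == "random") {
      members[sample.int(length(members), 1L)]
    } else {
      sub <- Z[members, , drop = FALSE]
      centroid <- colMeans(sub)
      dev <- rowSums(sweep(sub, 2L, centroid)^2)
      members[which.max(dev)]          # which.max: first (smallest id) tie
    }
  }, character(1L))
  structure(list(selected = selected, reserve = setdiff(ids, selected),
                 strategy = strategy, clusters = labels),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set [%s]: %d selected, %d reserve\n",
              strategy_label(x$strategy), length(x$selected),
              length(x$reserve)))
  invisible(x)
}

#' Enumerate and run a grid of sampling strategies
#'
#' Cartesian product of the supplied factor lists, enumerated in a fixed
#' deterministic order (distance, then ratio, then allocation, then
#' linkage, last factor varying fastest). Merge trees are computed once per
#' (distance, linkage) pair and reused across ratios and allocations.
#'
#' @param tm trait_matrix.
#' @param distances,ratios,allocations,linkages non-empty factor vectors.
#' @param seed seed for random allocation.
#' @return list of core_set objects, named by strategy label.
#' @export
strategy_grid <- function(tm,
                          distances = c("euclidean", "mahalanobis"),
                          ratios = c(0.1, 0.15, 0.2, 0.25, 0.3),
                          allocations = c("random", "deviation"),
                          linkages = c("flexible", "ward"),
                          seed = 1L) {
  if (!length(distances) || !length(ratios) || !length(allocations) ||
      !length(linkages))
    stop("all strategy factors must be non-empty")
  Z <- zstandardize(tm)$values
  trees <- list()
  for (d in distances) {
    D <- switch(d, euclidean = euclidean_distance(Z),
                mahalanobis = mahalanobis_distance(Z))
    for (l in linkages) trees[[paste(d, l)]] <- agglomerate(D, l)
  }
  out <- list()
  for (d in distances) for (r in ratios) for (a in allocations)
    for (l in linkages) {
      s <- sampling_strategy(d, r, a, l, seed = seed)
      out[[strategy_label(s)]] <- sample_core(tm, s,
                                              tree = trees[[paste(d, l)]])
    }
  out
}
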