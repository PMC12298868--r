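#' Min-max membership function of stress indicators
#'
#' U = (x - min) / (max - min) for higher-better indicators and
#' U = (max - x) / (max - min) for lower-better ones, per indicator over
#' the evaluated accessions. Constant indicators are undefined and dropped
#' with a warning.
#'
#' @param im trait_matrix of indicators (directions taken from the object
#'   unless overridden).
#' @param direction optional character vector overriding per-indicator
#'   directions.
#' @return n x q membership matrix U in [0, 1].
#' @export
membership <- function(im, direction = NULL) {
  stopifnot(inherits(im, "trait_matrix"))
  X <- im$values
  if (is.null(direction)) direction <- im$direction
  direction <- rep(direction, length.out = ncol(X))
  rng <- apply(X, 2L, range, na.rm = TRUE)
  span <- rng[2L, ] - rng[1L, ]
  drop <- which(span == 0)
  if (length(drop)) {
    warning("dropping constant indicator(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
    direction <- direction[-drop]
    rng <- rng[, -drop, drop = FALSE]
    span <- span[-drop]
    if (ncol(X) == 0L) stop("no usable indicators left")
  }
  U <- sweep(sweep(X, 2L, rng[1L, ]), 2L, span, `/`)
  lower <- direction == "lower"
  U[, lower] <- 1 - U[, lower, drop = FALSE]
  U
}

#' Weighted comprehensive evaluation value D
#'
#' D_i = sum_j w_j U_ij. Weights are either equal (1/q) or PCA
#' contribution rates: w_j proportional to sum_c (lambda_c / sum lambda)
#' e_jc^2 over the components of a PCA of the indicator matrix (squared
#' eigenvector entries weighted by eigenvalue share), normalized to sum 1.
#'
#' @param U membership matrix from \code{\link{membership}}.
#' @param weights \code{"pca_contribution"} (default), \code{"equal"}, or a
#'   numeric vector of length q (normalized internally).
#' @return list with \code{d} (named vector in [0, 1]) and \code{weights}.
#' @export
comprehensive_d <- function(U, weights = "pca_contribution") {
  q <- ncol(U)
  w <- if (is.numeric(weights)) {
    if (length(weights) != q) stop("need one weight per indicator")
    weights / sum(weights)
  } else {
    switch(match.arg(weights, c("pca_contribution", "equal")),
      equal = rep(1 / q, q),
      pca_contribution = {
        pc <- pca_matrix(U, standardize = TRUE)
        share <- pc$eigenvalues / sum(pc$eigenvalues)
        raw <- as.numeric(pc$rotation^2 %*% share)
        raw / sum(raw)
      })
  }
  if (abs(sum(w) - 1) > 1e-9) stop("internal error: weights do not sum to 1")
  names(w) <- colnames(U)
  list(d = stats::setNames(as.numeric(U %*% w), rownames(U)), weights = w)
}

#' Classify accessions into five tolerance groups
#'
#' Ward clustering (via \code{\link{agglomerate}}) of the 1-D Euclidean
#' distances between comprehensive D values into five groups, labelled
#' I..V by descending group mean D (I = highly tolerant ... V = highly
#' sensitive). The tolerant set is groups I-III.
#'
#' @param d named numeric vector of comprehensive values.
#' @param k number of groups (default 5).
#' @return list of class \code{tolerance_groups}: \code{group} (factor
#'   I..V per accession), \code{group_means}, \code{counts},
#'   \code{tolerance} (HT/T/MT/S/HS per accession), \code{tolerant_ids}.
#' @export
classify_tolerance <- function(d, k = 5L) {
  if (length(d) < k)
    stop("need at least ", k, " accessions; lower k for smaller panels")
  if (is.null(names(d))) names(d) <- sprintf("acc%03d", seq_along(d))
  D <- stats::dist(matrix(d, ncol = 1L, dimnames = list(names(d), "d")))
  tree <- agglomerate(D, "ward")
  raw <- cut_tree(tree, k)
  means <- tapply(d, raw, mean)
  # relabel clusters I..V by descending mean D
  ord <- order(means, decreasing = TRUE)
  relabel <- match(raw, ord)
  roman <- as.character(utils::as.roman(seq_len(k)))
  group <- factor(roman[relabel], levels = roman)
  tol_names <- c("HT", "T", "MT", "S", "HS")[seq_len(k)]
  tolerance <- stats::setNames(tol_names[relabel], names(d))
  tolerant <- names(d)[relabel <= min(3L, k)]
  structure(list(group = stats::setNames(group, names(d)),
                 group_means = stats::setNames(as.numeric(means[ord]),
                                               roman),
                 counts = stats::setNames(as.integer(table(relabel)), roman),
                 tolerance = tolerance, tolerant_ids = tolerant),
            class = "tolerance_groups")
}

#' @export
print.tolerance_groups <- function(x, ...) {
  cat("tolerance groups (mean D, n):\n")
  for (g in names(x$group_means))
    cat(sprintf("  %-3s %.3f  n=%d\n", g, x$group_means[g], x$counts[g]))
  cat(length(x$tolerant_ids), "accessions in tolerant groups I-III\n")
  invisible(x)
}
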