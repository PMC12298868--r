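#' Shannon-Weaver diversity index of a quantitative trait
#'
#' Bins a continuous trait into ten frequency classes centred on the trait
#' mean and computes the Shannon-Weaver index H' = -sum p_i ln p_i over the
#' occupied classes. The default scheme, standard in germplasm diversity
#' surveys, uses class 1 = (-Inf, mean - 2 sd), classes 2..9 in half-sd
#' steps across [mean - 2 sd, mean + 2 sd), and class 10 = [mean + 2 sd,
#' Inf). A constant trait (sd = 0) occupies one class and scores 0.
#'
#' @param x numeric vector; missing values dropped.
#' @param breaks optional custom break points (including -Inf/Inf ends);
#'   overrides the default ten-class scheme.
#' @return H' in [0, ln(number of classes)].
#' @export
shannon_weaver_gdi <- function(x, breaks = NULL) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least 2 non-missing values")
  if (is.null(breaks)) {
    m <- mean(x)
    s <- stats::sd(x)
    if (s == 0) return(0)
    breaks <- c(-Inf, m + seq(-2, 2, by = 0.5) * s, Inf)
  }
  cls <- cut(x, breaks = breaks, right = FALSE, labels = FALSE)
  p <- tabulate(cls, nbins = length(breaks) - 1L) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

sample_excess_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^4) / m2^2 - 3
}

#' Descriptive statistics and diversity of every trait
#'
#' Per-trait mean, median, variance, sample SD, min, max, moment skewness,
#' excess kurtosis (normal = 0), coefficient of variation
#' CV% = 100 sd / mean, and the Shannon-Weaver diversity index. Missing
#' values are dropped per trait. A trait with mean 0 has an undefined CV and
#' is flagged (CV = NA) rather than reported as 0; a constant trait has
#' sd = 0, CV = 0 and undefined (NA) skewness/kurtosis.
#'
#' @param tm trait_matrix.
#' @return data.frame, one row per trait, with a \code{flag} column naming
#'   any degeneracy (\code{"cv_undefined"}, \code{"constant"}).
#' @export
summarize_traits <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  X <- tm$values
  out <- lapply(colnames(X), function(tr) {
    x <- X[, tr]
    x <- x[!is.na(x)]
    if (length(x) < 2L)
      stop("trait ", tr, " has fewer than 2 non-missing values")
    mu <- mean(x)
    s <- stats::sd(x)
    flag <- ""
    cv <- if (mu == 0) {
      flag <- "cv_undefined"
      NA_real_
    } else 100 * s / mu
    if (s == 0) {
      flag <- paste0(flag, if (nzchar(flag)) ";", "constant")
      cv <- if (mu != 0) 0 else cv
    }
    data.frame(trait = tr, n = length(x), mean = mu, median = stats::median(x),
               variance = stats::var(x), sd = s, min = min(x), max = max(x),
               skewness = sample_skewness(x),
               kurtosis = sample_excess_kurtosis(x),
               cv_percent = cv, gdi = shannon_weaver_gdi(x), flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pairwise Pearson correlations among traits
#'
#' Pearson r on pairwise-complete observations with two-sided p-values from
#' the t approximation t = r sqrt((n-2)/(1-r^2)). Zero-variance traits give
#' undefined correlations and are flagged with a warning.
#'
#' @param tm trait_matrix.
#' @return list with matrices \code{r}, \code{p}, \code{n} (pair counts).
#' @export
correlate_traits <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  X <- tm$values
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("zero-variance trait(s), correlations undefined: ",
            paste(colnames(X)[which(sds == 0)], collapse = ", "))
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(X))
  if (any(npair[upper.tri(npair)] < 3L))
    stop("need at least 3 paired observations per trait pair")
  tstat <- r * sqrt((npair - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = npair - 2)
  diag(r) <- 1
  diag(p) <- 0
  list(r = r, p = p, n = npair)
}

#' Principal component analysis of a trait table
#'
#' Eigendecomposition of the trait correlation matrix (or covariance matrix
#' when \code{standardize = FALSE}). Missing values are mean-imputed per
#' trait before decomposition. Components are ordered by descending
#' eigenvalue; the contribution of component i is 100 lambda_i / sum(lambda).
#' Loadings are eigenvectors scaled by sqrt(lambda) (correlation-style
#' loadings).
#'
#' @param tm trait_matrix.
#' @param standardize analyse the correlation (TRUE) or covariance matrix.
#' @return object of class \code{pca_result}: list with \code{eigenvalues},
#'   \code{loadings} (m x m), \code{rotation} (eigenvectors),
#'   \code{contribution_percent}, \code{cumulative_percent}, \code{scores}
#'   (n x m accession scores).
#' @export
pca_traits <- function(tm, standardize = TRUE) {
  stopifnot(inherits(tm, "trait_matrix"))
  X <- impute_means(tm$values)
  pca_matrix(X, standardize = standardize)
}

# shared PCA core for trait tables and indicator matrices
pca_matrix <- function(X, standardize = TRUE) {
  S <- if (standardize) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance column(s) cannot be standardized: ",
           paste(colnames(X)[sds == 0], collapse = ", "))
    stats::cor(X)
  } else {
    stats::cov(X)
  }
  eig <- eigen(S, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  vec <- eig$vectors
  dimnames(vec) <- list(colnames(X), paste0("PC", seq_len(ncol(X))))
  contrib <- 100 * ev / sum(ev)
  Xc <- scale(X, center = TRUE, scale = if (standardize) apply(X, 2L, stats::sd) else FALSE)
  structure(list(
    eigenvalues = ev,
    rotation = vec,
    loadings = sweep(vec, 2L, sqrt(ev), `*`),
    contribution_percent = contrib,
    cumulative_percent = cumsum(contrib),
    scores = Xc %*% vec
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("PCA:", length(x$eigenvalues), "components\n")
  print(round(data.frame(eigenvalue = x$eigenvalues[1:k],
                         contribution = x$contribution_percent[1:k],
                         cumulative = x$cumulative_percent[1:k]), 3))
  invisible(x)
}

impute_means <- function(X) {
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  X
}

#' Z-score standardization of a trait table
#'
#' Centres every trait to mean 0 and scales to sample SD 1 (n - 1
#' denominator). Constant traits cannot be scaled and are dropped with a
#' warning.
#'
#' @param tm trait_matrix.
#' @return trait_matrix of standardized values.
#' @export
zstandardize <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  X <- tm$values
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  drop <- which(sds == 0 | is.na(sds))
  if (length(drop)) {
    warning("dropping constant trait(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
    if (ncol(X) == 0L) stop("no non-constant traits left")
  }
  Z <- scale(X)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  trait_matrix(Z, tm$direction[colnames(X)])
}
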