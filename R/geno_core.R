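#' Modified Rogers distance between accessions
#'
#' For biallelic loci with within-accession alternate-allele frequencies
#' x = call / 2 in {0, 0.5, 1}, the modified Rogers distance over the L'
#' loci co-called in both accessions is d(a, b) = sqrt((1 / L') sum_l
#' (x_al - x_bl)^2) (the squared frequency difference summed over both
#' alleles of a locus is 2 (x_a - x_b)^2, and the canonical 1/(2L')
#' normalizer cancels the 2). Opposite homozygotes at every locus give the
#' maximum d = 1.
#'
#' @param g genotype_matrix (filtered).
#' @return \code{dist} object.
#' @export
modified_rogers_distance <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  pg <- pairwise_geno_sums(g$calls, scale = 0.5)
  if (any(pg$n_co == 0))
    stop("accession pair(s) with zero co-called loci; distance undefined")
  D2 <- pg$ss / pg$n_co
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  diag(D) <- 0
  dimnames(D) <- list(rownames(g$calls), rownames(g$calls))
  stats::as.dist(D)
}

#' Percentage of (locus, allele) pairs retained by a core
#'
#' An allele is observed at a locus if any non-missing call carries it
#' (reference: codes 0/1; alternate: codes 1/2). Coverage = 100 x pairs
#' observed in the core / pairs observed in the full panel.
#'
#' @param core_ids accession ids in the core.
#' @param g genotype_matrix of the full panel.
#' @return percentage in (0, 100].
#' @export
allele_coverage <- function(core_ids, g) {
  stopifnot(inherits(g, "genotype_matrix"), length(core_ids) > 0)
  if (!all(core_ids %in% rownames(g$calls))) stop("unknown core id(s)")
  count_alleles <- function(calls) {
    ref <- colSums(calls <= 1L, na.rm = TRUE) > 0
    alt <- colSums(calls >= 1L, na.rm = TRUE) > 0
    sum(ref) + sum(alt)
  }
  100 * count_alleles(g$calls[core_ids, , drop = FALSE]) /
    count_alleles(g$calls)
}

core_objective <- function(Dm, sel) {
  sub <- Dm[sel, sel, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

#' Select a genotypic core by entry-to-nearest-entry maximization
#'
#' Maximizes the mean distance from each core entry to its nearest other
#' entry (E-NE) over modified Rogers distances: a greedy build starting
#' from the maximally distant pair, adding at each step the accession whose
#' inclusion gives the highest objective, followed by steepest-ascent
#' single swaps until no swap improves or \code{max_iters} swaps are done.
#' Fully deterministic: ties break on the smallest id index.
#'
#' @param g genotype_matrix (filtered).
#' @param ratio sampling ratio in (0, 1]; core size = round(ratio n),
#'   half-away-from-zero.
#' @param max_iters swap budget for the local search (default 1000).
#' @param D optional precomputed \code{dist} (modified Rogers) to reuse.
#' @return list of class \code{geno_core_result}: \code{selected},
#'   \code{ratio}, \code{objective}, \code{allele_coverage_percent},
#'   \code{diversity} (panel He/Ho/I of the core), \code{n_swaps}.
#' @export
select_geno_core <- function(g, ratio, max_iters = 1000L, D = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$calls)
  k <- round_half_up(ratio * n)
  if (k < 2L) stop("core size round(ratio * n) must be >= 2")
  if (k > n) stop("ratio gives core larger than the panel")
  ids <- rownames(g$calls)
  if (is.null(D)) D <- modified_rogers_distance(g)
  Dm <- as.matrix(D)
  # mean E-NE objective of set B extended by each column-candidate of Dm:
  # obj(o) = (sum_i min(nn_i, D_io) + min_i D_io) / (|B| + 1), vectorized
  extend_objective <- function(B, nnB, cand) {
    Dbo <- Dm[B, cand, drop = FALSE]
    (colSums(pmin(Dbo, nnB)) + apply(Dbo, 2L, min)) / (length(B) + 1L)
  }
  nn_within <- function(B) {
    sub <- Dm[B, B, drop = FALSE]
    diag(sub) <- Inf
    apply(sub, 1L, min)
  }
  if (k == n) {
    sel <- seq_len(n)
  } else {
    # greedy: start from the most distant pair (lexicographic ties)
    idx <- which.max(t(Dm))
    j <- (idx - 1L) %/% n + 1L
    i <- idx - (j - 1L) * n
    sel <- sort(c(i, j))
    pool <- setdiff(seq_len(n), sel)
    while (length(sel) < k) {
      gains <- extend_objective(sel, nn_within(sel), pool)
      best <- pool[which.max(gains)]
      sel <- c(sel, best)
      pool <- setdiff(pool, best)
    }
    # steepest-ascent single swaps
    obj <- core_objective(Dm, sel)
    iters <- 0L
    repeat {
      if (iters >= max_iters) break
      best_gain <- 0
      best_swap <- NULL
      out_pool <- setdiff(seq_len(n), sel)
      for (s_pos in seq_along(sel)) {
        B <- sel[-s_pos]
        vals <- extend_objective(B, nn_within(B), out_pool)
        w <- which.max(vals)
        if (vals[w] > obj + best_gain + 1e-12) {
          best_gain <- vals[w] - obj
          best_swap <- c(s_pos, out_pool[w])
        }
      }
      if (is.null(best_swap)) break
      sel[best_swap[1L]] <- best_swap[2L]
      obj <- obj + best_gain
      iters <- iters + 1L
    }
  }
  sel_ids <- ids[sort(sel)]
  core_g <- genotype_matrix(g$calls[sel_ids, , drop = FALSE],
                            sel_ids, g$loci)
  structure(list(selected = sel_ids, ratio = ratio,
                 objective = core_objective(Dm, sort(sel)),
                 allele_coverage_percent = allele_coverage(sel_ids, g),
                 diversity = diversity_stats(core_g)$panel,
                 n_swaps = if (k == n) 0L else iters),
            class = "geno_core_result")
}

#' @export
print.geno_core_result <- function(x, ...) {
  cat(sprintf(
    "genotypic core: %d accessions (ratio %.2f), E-NE %.4f, coverage %.2f%%\n",
    length(x$selected), x$ratio, x$objective, x$allele_coverage_percent))
  invisible(x)
}

#' Integrate phenotypic and genotypic cores
#'
#' Final core = union of the two selections; accessions in neither form the
#' reserve set.
#'
#' @param pheno_ids,geno_ids accession id vectors.
#' @param all_ids full panel ids.
#' @return list of class \code{integrated_core}: \code{final},
#'   \code{overlap}, \code{reserve}, and counts.
#' @export
integrate_cores <- function(pheno_ids, geno_ids, all_ids) {
  unknown <- setdiff(c(pheno_ids, geno_ids), all_ids)
  if (length(unknown))
    stop("unknown accession id(s): ", paste(utils::head(unknown, 5L),
                                            collapse = ", "))
  final <- union(pheno_ids, geno_ids)
  overlap <- intersect(pheno_ids, geno_ids)
  reserve <- setdiff(all_ids, final)
  structure(list(final = final, overlap = overlap, reserve = reserve,
                 counts = c(pheno = length(unique(pheno_ids)),
                            geno = length(unique(geno_ids)),
                            overlap = length(overlap),
                            final = length(final),
                            reserve = length(reserve),
                            total = length(all_ids)),
                 percent_of_total = 100 * length(final) / length(all_ids)),
            class = "integrated_core")
}

#' @export
print.integrated_core <- function(x, ...) {
  cat(sprintf(
    "integrated core: %d accessions (%.2f%% of %d); pheno %d, geno %d, overlap %d, reserve %d\n",
    x$counts["final"], x$percent_of_total, x$counts["total"],
    x$counts["pheno"], x$counts["geno"], x$counts["overlap"],
    x$counts["reserve"]))
  invisible(x)
}
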