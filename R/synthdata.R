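#' Configuration for phenotype simulation
#'
#' @param traits data.frame with columns \code{trait}, \code{mean},
#'   \code{sd}, and optionally \code{direction}; defaults to the 19-trait
#'   maize reference table shipped with the package (per-trait means and SDs
#'   of a 588-accession inbred panel).
#' @param n_accessions number of accessions (default 588).
#' @param correlation trait correlation matrix (unit diagonal, positive
#'   semi-definite); default identity. The reference panel's correlation
#'   matrix is unknown, so no non-trivial default is assumed.
#' @param seed integer RNG seed.
#' @return list of class \code{pheno_sim_config}.
#' @export
pheno_sim_config <- function(traits = NULL, n_accessions = 588,
                             correlation = NULL, seed = 1L) {
  if (is.null(traits)) {
    traits <- utils::read.csv(system.file("extdata",
      "maize_trait_reference.csv", package = "germcore"))
  }
  stopifnot(all(c("trait", "mean", "sd") %in% names(traits)))
  if (is.null(traits$direction)) traits$direction <- "higher"
  m <- nrow(traits)
  if (is.null(correlation)) correlation <- diag(m)
  correlation <- as.matrix(correlation)
  if (n_accessions < 2L) stop("n_accessions must be >= 2")
  if (any(traits$sd < 0)) stop("target sd must be >= 0")
  if (!isTRUE(all.equal(diag(correlation), rep(1, m), tolerance = 1e-9)))
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf(
      "correlation matrix is not positive semi-definite (eigenvalue %.3g)",
      min(ev)))
  structure(list(traits = traits, n_accessions = as.integer(n_accessions),
                 correlation = correlation, seed = as.integer(seed)),
            class = "pheno_sim_config")
}

#' Simulate a quantitative trait table
#'
#' Draws correlated standard normals through a Gaussian copula (matrix
#' square root of the configured correlation), then affinely rescales every
#' column so the realized sample mean and sample SD equal the targets
#' exactly. Exact rescaling makes CV checks against the configured
#' (mean, sd) pairs deterministic. Trait marginals are normal; skewness is
#' not injected.
#'
#' @param config pheno_sim_config.
#' @return trait_matrix with attribute \code{seed}.
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "pheno_sim_config"))
  set.seed(config$seed)
  n <- config$n_accessions
  m <- nrow(config$traits)
  Z <- matrix(stats::rnorm(n * m), n, m)
  eig <- eigen(config$correlation, symmetric = TRUE)
  root <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), m) %*% t(eig$vectors)
  Z <- Z %*% root
  X <- matrix(0, n, m, dimnames = list(sprintf("acc%03d", seq_len(n)),
                                       config$traits$trait))
  for (j in seq_len(m)) {
    z <- Z[, j]
    s <- stats::sd(z)
    z <- if (s > 0) (z - mean(z)) / s else rep(0, n)
    X[, j] <- z * config$traits$sd[j] + config$traits$mean[j]
  }
  tm <- trait_matrix(X, config$traits$direction)
  attr(tm, "seed") <- config$seed
  tm
}

#' Configuration for structured genotype simulation
#'
#' Defaults emulate a Maize6H-60K-scale inbred panel: 588 accessions, 7439
#' post-filter loci over 10 chromosomes (1218 on chromosome 1 down to 476 on
#' chromosome 10), K = 6 subpopulations, Fst 0.1, residual heterozygosity
#' 3\% (panel Ho about 0.03), expected heterozygosity about 0.40 from the
#' ancestral MAF range, and under-1\% missingness.
#'
#' @param n_accessions,n_loci panel dimensions.
#' @param n_subpops number of Balding-Nichols subpopulations K.
#' @param fst differentiation parameter F in (0, 1).
#' @param ancestral_maf_range (lo, hi) in (0, 0.5] for ancestral allele
#'   frequencies.
#' @param residual_het_rate probability an inbred call is heterozygous.
#' @param missing_rate per-call missingness probability.
#' @param chrom_sizes locus counts per chromosome (must sum to
#'   \code{n_loci}); default splits \code{n_loci} proportionally to the
#'   reference panel's chromosome counts.
#' @param seed integer RNG seed.
#' @return list of class \code{geno_sim_config}.
#' @export
geno_sim_config <- function(n_accessions = 588, n_loci = 7439,
                            n_subpops = 6, fst = 0.1,
                            ancestral_maf_range = c(0.13, 0.5),
                            residual_het_rate = 0.03, missing_rate = 0.005,
                            chrom_sizes = NULL, seed = 1L) {
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1)")
  probs <- c(residual_het_rate, missing_rate)
  if (any(probs < 0 | probs > 1)) stop("rates must be probabilities")
  if (ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      ancestral_maf_range[1] > ancestral_maf_range[2])
    stop("ancestral_maf_range must lie in (0, 0.5]")
  if (is.null(chrom_sizes)) {
    ref <- c(1218, 900, 850, 800, 750, 700, 650, 600, 495, 476)
    chrom_sizes <- round_largest_remainder(ref / sum(ref), n_loci)
  }
  if (sum(chrom_sizes) != n_loci)
    stop("chrom_sizes must sum to n_loci")
  structure(list(n_accessions = as.integer(n_accessions),
                 n_loci = as.integer(n_loci),
                 n_subpops = as.integer(n_subpops), fst = fst,
                 ancestral_maf_range = ancestral_maf_range,
                 residual_het_rate = residual_het_rate,
                 missing_rate = missing_rate,
                 chrom_sizes = as.integer(chrom_sizes),
                 seed = as.integer(seed)),
            class = "geno_sim_config")
}

#' Simulate a structured biallelic SNP panel
#'
#' Balding-Nichols model: per locus an ancestral frequency p is drawn
#' uniformly from \code{ancestral_maf_range}; each subpopulation's
#' frequency is Beta(p (1-F)/F, (1-p)(1-F)/F). Accessions are assigned to
#' subpopulations in (approximately) equal blocks. Inbred lines draw a
#' homozygous genotype from their subpopulation frequency except that a
#' call is heterozygous with probability \code{residual_het_rate}; calls
#' are then masked missing with probability \code{missing_rate}. Loci get
#' chromosomes per \code{chrom_sizes} and sorted uniform positions.
#'
#' @param config geno_sim_config.
#' @return genotype_matrix with attributes \code{subpop} (true labels) and
#'   \code{seed}.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "geno_sim_config"))
  set.seed(config$seed)
  n <- config$n_accessions
  L <- config$n_loci
  K <- config$n_subpops
  fst <- config$fst
  p_anc <- stats::runif(L, config$ancestral_maf_range[1],
                        config$ancestral_maf_range[2])
  shape_scale <- (1 - fst) / fst
  # subpop x locus alternate-allele frequencies
  P <- matrix(stats::rbeta(K * L, rep(p_anc, each = K) * shape_scale,
                           rep(1 - p_anc, each = K) * shape_scale), K, L)
  subpop <- rep(seq_len(K), length.out = n)
  calls <- matrix(0L, n, L)
  for (k in seq_len(K)) {
    rows <- which(subpop == k)
    hom_alt <- matrix(stats::rbinom(length(rows) * L, 1L,
                                    rep(P[k, ], each = length(rows))),
                      length(rows), L)
    calls[rows, ] <- 2L * hom_alt
  }
  if (config$residual_het_rate > 0) {
    het <- matrix(stats::runif(n * L) < config$residual_het_rate, n, L)
    calls[het] <- 1L
  }
  if (config$missing_rate > 0) {
    calls[matrix(stats::runif(n * L) < config$missing_rate, n, L)] <- NA_integer_
  }
  ids <- sprintf("acc%03d", seq_len(n))
  chrom <- rep(seq_along(config$chrom_sizes), config$chrom_sizes)
  pos <- unlist(lapply(config$chrom_sizes, function(sz)
    sort(sample.int(3e8L, sz))), use.names = FALSE)
  loci <- data.frame(id = sprintf("snp%05d", seq_len(L)),
                     chrom = chrom, pos = pos,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, ids, loci)
  attr(g, "subpop") <- stats::setNames(subpop, ids)
  attr(g, "subpop_freq") <- P
  attr(g, "seed") <- config$seed
  g
}

#' Configuration for germination stress-indicator simulation
#'
#' @param group_means 5 x q matrix of latent-group indicator means (rows =
#'   tolerance groups, best to worst); default a 6-indicator gradient.
#' @param group_proportions 5 probabilities summing to 1; default the
#'   observed tolerance-class proportions of a 172-accession core
#'   (4/14/47/64/43).
#' @param n_accessions number of accessions (default 172).
#' @param noise_sd within-group Gaussian noise SD (>= 0).
#' @param seed integer RNG seed.
#' @return list of class \code{stress_sim_config}.
#' @export
stress_sim_config <- function(group_means = NULL,
                              group_proportions = c(4, 14, 47, 64, 43) / 172,
                              n_accessions = 172, noise_sd = 0.05, seed = 1L) {
  if (is.null(group_means)) {
    base <- c(1.0, 0.8, 0.6, 0.4, 0.2)
    group_means <- outer(base, rep(1, 6))
    colnames(group_means) <- c("germination_potential", "germination_rate",
                               "seedling_length", "root_length",
                               "fresh_weight", "vigor_index")
  }
  group_means <- as.matrix(group_means)
  if (nrow(group_means) != 5L) stop("group_means must have 5 rows")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (abs(sum(group_proportions) - 1) > 1e-9)
    stop("group_proportions must sum to 1")
  structure(list(group_means = group_means,
                 group_proportions = group_proportions,
                 n_accessions = as.integer(n_accessions),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "stress_sim_config")
}

round_largest_remainder <- function(p, n) {
  raw <- p * n
  out <- floor(raw)
  short <- n - sum(out)
  if (short > 0) {
    add <- order(raw - out, decreasing = TRUE)[seq_len(short)]
    out[add] <- out[add] + 1
  }
  as.integer(out)
}

#' Simulate germination stress indicators with latent tolerance groups
#'
#' Accessions are assigned to 5 latent groups with counts given by
#' largest-remainder rounding of \code{group_proportions * n} (so exact
#' proportions yield exact counts); each indicator is the group mean plus
#' Gaussian noise.
#'
#' @param config stress_sim_config.
#' @return list with \code{indicators} (trait_matrix, all higher-better)
#'   and \code{groups} (true group label per accession, 1 = most tolerant).
#' @export
simulate_germination <- function(config) {
  stopifnot(inherits(config, "stress_sim_config"))
  set.seed(config$seed)
  n <- config$n_accessions
  q <- ncol(config$group_means)
  counts <- round_largest_remainder(config$group_proportions, n)
  groups <- sample(rep(seq_len(5L), counts))
  X <- config$group_means[groups, , drop = FALSE] +
    matrix(stats::rnorm(n * q, sd = config$noise_sd), n, q)
  dimnames(X) <- list(sprintf("acc%03d", seq_len(n)),
                      colnames(config$group_means))
  list(indicators = trait_matrix(X, "higher"),
       groups = stats::setNames(groups, rownames(X)))
}

#' Simulate a STRUCTURE-style log-likelihood table over K
#'
#' Mean L(K) is piecewise linear in K with a slope change only at
#' \code{true_k} (steep improvement before, shallow after, the typical
#' profile of structured panels), plus Gaussian replicate noise. Feeds
#' \code{\link{evanno_delta_k}}.
#'
#' @param true_k location of the slope change.
#' @param k_range (Kmin, Kmax), default c(1, 10).
#' @param reps replicate runs per K (>= 3, needed for the replicate SD).
#' @param base_ll mean log-likelihood at Kmin.
#' @param slope_before,slope_after per-K slope before/at and after
#'   \code{true_k}.
#' @param noise_sd replicate noise SD.
#' @param seed integer RNG seed.
#' @return data.frame of class \code{k_run_table}: columns K, rep, logL.
#' @export
simulate_structure_likelihoods <- function(true_k, k_range = c(1, 10),
                                           reps = 3, base_ll = -50000,
                                           slope_before = 1000,
                                           slope_after = 100,
                                           noise_sd = 30, seed = 1L) {
  if (reps < 3L) stop("reps must be >= 3 (delta-K needs a replicate SD)")
  ks <- seq(k_range[1], k_range[2])
  if (true_k < k_range[1] || true_k > k_range[2])
    stop("true_k must lie within k_range")
  set.seed(seed)
  mean_ll <- base_ll + ifelse(ks <= true_k,
                              (ks - k_range[1]) * slope_before,
                              (true_k - k_range[1]) * slope_before +
                                (ks - true_k) * slope_after)
  tab <- expand.grid(rep = seq_len(reps), K = ks)[, c("K", "rep")]
  tab$logL <- mean_ll[match(tab$K, ks)] +
    stats::rnorm(nrow(tab), sd = noise_sd)
  class(tab) <- c("k_run_table", "data.frame")
  tab
}
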