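#' Accession-by-locus biallelic genotype matrix
#'
#' Calls are coded 0 = reference homozygote, 1 = heterozygote, 2 = alternate
#' homozygote, NA = missing. Loci carry 1-based positions.
#'
#' @param calls integer matrix (accessions x loci) with codes 0/1/2/NA.
#' @param ids accession ids (default rownames).
#' @param loci data.frame with columns \code{id}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}.
#' @return object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(calls, ids = rownames(calls), loci) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(ids)) ids <- sprintf("acc%03d", seq_len(nrow(calls)))
  stopifnot(!anyDuplicated(ids), nrow(loci) == ncol(calls))
  if (!all(calls %in% c(0L, 1L, 2L) | is.na(calls)))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (any(loci$pos < 0)) stop("locus positions must be non-negative")
  dimnames(calls) <- list(ids, loci$id)
  structure(list(calls = calls, loci = as.data.frame(loci)),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d loci (%d chromosomes)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$loci$chrom))))
  invisible(x)
}

geno_code_from_gt <- function(gt) {
  # "0/0","0|0" -> 0; "0/1","1|0" -> 1; "1/1" -> 2; "./." or NA -> NA
  gt <- sub(":.*$", "", gt)
  a <- substr(gt, 1L, 1L)
  b <- substr(gt, 3L, 3L)
  out <- suppressWarnings(as.integer(a) + as.integer(b))
  out[is.na(gt) | a == "." | b == "."] <- NA_integer_
  out
}

#' Read genotypes from VCF or HapMap-like TSV
#'
#' VCF parsing uses \pkg{vcfR}; only the GT field is used and phased and
#' unphased calls are treated identically. Multi-allelic records are
#' dropped (count reported via message). The HapMap-like TSV format is the
#' one produced by \code{\link{write_genotypes}}: columns \code{rs},
#' \code{alleles} (ref/alt), \code{chrom}, \code{pos}, then one column per
#' accession holding two-letter genotypes (\code{NN} = missing).
#'
#' @param path input file.
#' @param format \code{"vcf"} or \code{"hapmap_tsv"}.
#' @return genotype_matrix
#' @export
read_genotypes <- function(path, format = c("vcf", "hapmap_tsv")) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi))
      message("dropped ", sum(multi), " multi-allelic locus/loci")
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    calls <- apply(gt, 2L, geno_code_from_gt)
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1L,
                                             dimnames = list(NULL, names(calls)))
    loci <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       ref = fix[, "REF"], alt = fix[, "ALT"],
                       stringsAsFactors = FALSE)
    genotype_matrix(t(calls), colnames(gt), loci)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    need <- c("rs", "alleles", "chrom", "pos")
    if (!all(need %in% names(df)))
      stop("malformed HapMap-like file: missing column(s) ",
           paste(setdiff(need, names(df)), collapse = ", "))
    al <- strsplit(df$alleles, "/", fixed = TRUE)
    ref <- vapply(al, `[`, "", 1L)
    alt <- vapply(al, `[`, "", 2L)
    samp <- setdiff(names(df), need)
    calls <- matrix(NA_integer_, length(samp), nrow(df))
    for (j in seq_len(nrow(df))) {
      g <- as.character(df[j, samp])
      code <- rep(NA_integer_, length(g))
      code[g == paste0(ref[j], ref[j])] <- 0L
      code[g == paste0(ref[j], alt[j]) | g == paste0(alt[j], ref[j])] <- 1L
      code[g == paste0(alt[j], alt[j])] <- 2L
      bad <- !is.na(g) & g != "NN" & is.na(code)
      if (any(bad))
        stop("malformed genotype at line ", j + 1L, ": ",
             g[bad][1L])
      calls[, j] <- code
    }
    loci <- data.frame(id = df$rs, chrom = df$chrom, pos = as.integer(df$pos),
                       ref = ref, alt = alt, stringsAsFactors = FALSE)
    genotype_matrix(calls, samp, loci)
  }
}

#' Write genotypes as minimal VCF or HapMap-like TSV
#'
#' The VCF writer emits a plain-text GT-only VCF 4.2 file.
#'
#' @param g genotype_matrix.
#' @param path output file.
#' @param format \code{"vcf"} or \code{"hapmap_tsv"}.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "hapmap_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "genotype_matrix"))
  ids <- rownames(g$calls)
  if (format == "vcf") {
    gt_strings <- c("0/0", "0/1", "1/1")
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t"))
    body <- vapply(seq_len(ncol(g$calls)), function(j) {
      code <- g$calls[, j]
      gt <- ifelse(is.na(code), "./.", gt_strings[code + 1L])
      paste(c(g$loci$chrom[j], g$loci$pos[j], g$loci$id[j], g$loci$ref[j],
              g$loci$alt[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
    }, character(1L))
    writeLines(c(lines, body), path)
  } else {
    mat <- vapply(seq_len(ncol(g$calls)), function(j) {
      code <- g$calls[, j]
      r <- g$loci$ref[j]; a <- g$loci$alt[j]
      c(paste0(r, r), paste0(r, a), paste0(a, a))[code + 1L]
    }, character(nrow(g$calls)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
    mat[is.na(mat)] <- "NN"
    df <- data.frame(rs = g$loci$id,
                     alleles = paste0(g$loci$ref, "/", g$loci$alt),
                     chrom = g$loci$chrom, pos = g$loci$pos,
                     t(mat), check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df)[-(1:4)] <- ids
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

locus_allele_freq <- function(g) {
  called <- colSums(!is.na(g$calls))
  alt <- colSums(g$calls, na.rm = TRUE)    # alt allele count = 2*hom_alt + het
  p_alt <- alt / (2 * called)
  list(called = called, p_alt = p_alt, maf = pmin(p_alt, 1 - p_alt))
}

#' Filter loci on minor allele frequency and missingness
#'
#' Keeps loci with MAF strictly greater than \code{maf_min} and missing
#' proportion strictly less than \code{pms_max}. MAF is computed on allele
#' counts over non-missing calls: p = (2 hom_alt + het) / (2 n_called),
#' MAF = min(p, 1 - p). All-missing loci are dropped and counted.
#'
#' @param g genotype_matrix.
#' @param maf_min MAF threshold (default 0.01, strict).
#' @param pms_max missing-rate threshold (default 0.01, strict).
#' @return genotype_matrix with attribute \code{filter_counts} (kept,
#'   removed_maf, removed_missing, removed_all_missing).
#' @export
filter_loci <- function(g, maf_min = 0.01, pms_max = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$calls)
  af <- locus_allele_freq(g)
  miss <- 1 - af$called / n
  all_missing <- af$called == 0L
  maf <- af$maf
  maf[all_missing] <- -Inf
  keep <- !all_missing & maf > maf_min & miss < pms_max
  out <- genotype_matrix(g$calls[, keep, drop = FALSE],
                         rownames(g$calls), g$loci[keep, , drop = FALSE])
  attr(out, "filter_counts") <- c(
    kept = sum(keep),
    removed_maf = sum(!all_missing & maf <= maf_min),
    removed_missing = sum(!all_missing & maf > maf_min & miss >= pms_max),
    removed_all_missing = sum(all_missing))
  out
}

#' Per-locus and panel diversity statistics
#'
#' Per locus: expected heterozygosity He = 1 - p^2 - q^2, observed
#' heterozygosity Ho = het / called, Shannon information index
#' I = -(p ln p + q ln q) with 0 ln 0 = 0, MAF and missing rate. Panel
#' values are unweighted means over loci with at least 2 called accessions.
#'
#' @param g genotype_matrix (typically filtered).
#' @return list with \code{per_locus} data.frame and \code{panel} named
#'   vector (he, ho, shannon_i, maf, missing_rate, n_loci).
#' @export
diversity_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$calls)
  af <- locus_allele_freq(g)
  het <- colSums(g$calls == 1L, na.rm = TRUE)
  p <- af$p_alt
  he <- 1 - p^2 - (1 - p)^2
  ho <- het / af$called
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  shannon <- -(xlx(p) + xlx(1 - p))
  per_locus <- data.frame(locus = g$loci$id, chrom = g$loci$chrom,
                          pos = g$loci$pos, called = af$called,
                          maf = af$maf, missing_rate = 1 - af$called / n,
                          he = he, ho = ho, shannon_i = shannon,
                          stringsAsFactors = FALSE)
  ok <- af$called >= 2L                 # under-called loci: panel means only
  panel <- c(he = mean(he[ok]), ho = mean(ho[ok]),
             shannon_i = mean(shannon[ok]), maf = mean(af$maf[ok]),
             missing_rate = mean(1 - af$called[ok] / n), n_loci = sum(ok))
  list(per_locus = per_locus, panel = panel)
}

# pairwise co-called counts and sum of |g_i - g_j| style quantities via
# crossproducts with NA -> 0 masking
pairwise_geno_sums <- function(calls, scale = 1) {
  G <- calls * scale
  G[is.na(G)] <- 0
  M <- (!is.na(calls)) * 1
  G2 <- G^2
  n_co <- M %*% t(M)
  # sum over co-called loci of (g_i - g_j)^2
  ss <- G2 %*% t(M) + M %*% t(G2) - 2 * G %*% t(G)
  list(n_co = n_co, ss = ss, M = M)
}

#' Genetic similarity coefficient (IBS allele sharing) matrix
#'
#' GSC(a, b) = mean over loci called in both accessions of the
#' allele-sharing score: 1 for identical genotype codes, 0.5 for codes
#' differing by one (one shared allele), 0 for opposite homozygotes.
#' Equivalently 1 - |g_a - g_b| / 2 averaged over co-called loci.
#'
#' @param g genotype_matrix.
#' @return symmetric matrix of GSC values in [0, 1] with unit diagonal.
#' @export
gsc_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$calls) < 2L) stop("need at least 2 accessions")
  calls <- g$calls
  pg <- pairwise_geno_sums(calls)
  # |g_a - g_b| = (g_a - g_b)^2 - 2 * [opposite homozygotes]
  I0 <- (calls == 0L) * 1; I0[is.na(calls)] <- 0
  I2 <- (calls == 2L) * 1; I2[is.na(calls)] <- 0
  opp <- I0 %*% t(I2) + I2 %*% t(I0)
  abs_sum <- pg$ss - 2 * opp
  if (any(pg$n_co == 0))
    warning("accession pair(s) with zero co-called loci; GSC undefined (NA)")
  gsc <- 1 - 0.5 * abs_sum / pg$n_co
  gsc[pg$n_co == 0] <- NA_real_
  diag(gsc) <- 1
  dimnames(gsc) <- list(rownames(calls), rownames(calls))
  gsc
}

#' SNP counts per chromosome and per window
#'
#' @param g genotype_matrix.
#' @param window window width in bp; windows are half-open
#'   [start, start + window) from position 1.
#' @return list with \code{per_chrom} (chromosome, n_snps) and
#'   \code{windows} (chromosome, start, end, n_snps; zero-count windows up
#'   to each chromosome's last locus included).
#' @export
snp_density <- function(g, window = 1e6) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (window <= 0) stop("window must be positive")
  loci <- g$loci
  per_chrom <- as.data.frame(table(chrom = loci$chrom),
                             stringsAsFactors = FALSE)
  names(per_chrom) <- c("chrom", "n_snps")
  win <- do.call(rbind, lapply(split(loci, loci$chrom), function(d) {
    nwin <- ceiling(max(d$pos) / window)
    idx <- pmin((d$pos - 1) %/% window + 1, nwin)
    data.frame(chrom = d$chrom[1],
               start = (seq_len(nwin) - 1) * window + 1,
               end = seq_len(nwin) * window,
               n_snps = tabulate(idx, nbins = nwin))
  }))
  rownames(win) <- NULL
  list(per_chrom = per_chrom, windows = win)
}

#' Principal component analysis of a genotype matrix
#'
#' Mean-imputes missing calls per locus, column-centres the call matrix and
#' decomposes it by SVD. Variance explained per component is reported.
#'
#' @param g genotype_matrix (typically filtered).
#' @param n_components number of components to retain in the score matrix.
#' @return list with \code{scores} (n x c), \code{variance_percent},
#'   \code{cumulative_percent}, \code{sdev}.
#' @export
genotype_pca <- function(g, n_components = 10L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (ncol(g$calls) < 2L) stop("need at least 2 loci")
  X <- impute_means(g$calls * 1.0)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  varp <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  c_use <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(c_use), drop = FALSE],
       variance_percent = varp, cumulative_percent = cumsum(varp),
       sdev = pc$sdev)
}

#' Evanno delta-K from a replicate log-likelihood table
#'
#' For mean replicate log-likelihoods Lbar(K): L'(K) = Lbar(K) - Lbar(K-1),
#' |L''(K)| = |L'(K+1) - L'(K)|, delta-K = |L''(K)| / sd(L(K)) over
#' replicates, defined only for interior K. A zero replicate SD makes
#' delta-K infinite at that K (flagged with a warning).
#'
#' @param tab data.frame with columns K, rep, logL (contiguous K range,
#'   >= 3 K values, >= 3 replicates per K).
#' @return list with \code{table} (K, mean_logL, sd_logL, delta_k) and
#'   \code{best_k} (argmax of delta-K over interior K).
#' @export
evanno_delta_k <- function(tab) {
  stopifnot(all(c("K", "rep", "logL") %in% names(tab)))
  ks <- sort(unique(tab$K))
  if (length(ks) < 3L) stop("need at least 3 K values")
  if (!all(diff(ks) == 1L)) stop("K range must be contiguous")
  reps <- tapply(tab$logL, tab$K, length)
  if (any(reps < 3L)) stop("need >= 3 replicates per K")
  mu <- tapply(tab$logL, tab$K, mean)[as.character(ks)]
  sdv <- tapply(tab$logL, tab$K, stats::sd)[as.character(ks)]
  d1 <- c(NA, diff(mu))                       # L'(K), defined for K >= 2
  d2 <- abs(c(NA, diff(d1)[-1], NA))          # |L''(K)|, interior K only
  if (any(sdv == 0 & !is.na(d2)))
    warning("zero replicate SD at interior K; delta-K infinite there")
  delta <- d2 / sdv
  out <- data.frame(K = ks, mean_logL = as.numeric(mu),
                    sd_logL = as.numeric(sdv), delta_k = as.numeric(delta))
  interior <- which(!is.na(delta))
  best <- ks[interior[which.max(delta[interior])]]
  list(table = out, best_k = best)
}
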