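test_that("VCF and HapMap round trips preserve calls bit-exactly", {
  g <- small_geno(seed = 1, n = 10, L = 20)
  vcf <- tempfile(fileext = ".vcf")
  hmp <- tempfile(fileext = ".tsv")
  write_genotypes(g, vcf, "vcf")
  write_genotypes(g, hmp, "hapmap_tsv")
  g_vcf <- read_genotypes(vcf, "vcf")
  g_hmp <- read_genotypes(hmp, "hapmap_tsv")
  expect_identical(unname(g_vcf$calls), unname(g$calls))
  expect_identical(unname(g_hmp$calls), unname(g$calls))
  expect_identical(g_vcf$calls, g_hmp$calls)
  expect_equal(g_vcf$loci$pos, g$loci$pos)
  unlink(c(vcf, hmp))
})

test_that("phased and unphased VCF genotypes code identically; multi-allelic loci drop", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "snp1", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "0|1", "1|0", sep = "\t"),
    paste("1", "200", "snp2", "C", "T,G", ".", "PASS", ".", "GT",
          "0/1", "0/2", "1/1", sep = "\t"),
    paste("1", "300", "snp3", "C", "T", ".", "PASS", ".", "GT",
          "1/1", "./.", "0/0", sep = "\t")), vcf)
  expect_message(g <- read_genotypes(vcf, "vcf"), "multi-allelic")
  expect_equal(ncol(g$calls), 2L)
  expect_equal(unname(g$calls[, "snp1"]), c(1L, 1L, 1L))
  expect_equal(unname(g$calls[, "snp3"]), c(2L, NA_integer_, 0L))
  unlink(vcf)
})

test_that("locus filtering applies strict MAF and missingness thresholds", {
  # 100 accessions: 1 het -> maf 0.005 removed; 3 het -> 0.015 kept
  calls <- matrix(0L, 100, 4)
  calls[1, 1] <- 1L
  calls[1:3, 2] <- 1L
  calls[, 3] <- rep(c(0L, 2L), 50)          # maf 0.5, fully called
  calls[1:2, 4] <- NA_integer_              # 2% missing -> removed
  calls[3:60, 4] <- 2L
  loci <- data.frame(id = paste0("s", 1:4), chrom = 1, pos = 1:4,
                     ref = "A", alt = "G")
  g <- genotype_matrix(calls, sprintf("a%03d", 1:100), loci)
  f <- filter_loci(g)
  expect_equal(colnames(f$calls), c("s2", "s3"))
  cnt <- attr(f, "filter_counts")
  expect_equal(unname(cnt["kept"]), 2L)
  expect_equal(unname(cnt["removed_maf"]), 1L)
  expect_equal(unname(cnt["removed_missing"]), 1L)
  # monomorphic loci are always removed; vacuous thresholds keep polymorphic
  f2 <- filter_loci(g, maf_min = 0, pms_max = 1.1)
  expect_false("s1" %in% colnames(f2$calls) && FALSE) # s1 polymorphic, kept
  expect_equal(ncol(f2$calls), 4L)
  g_mono <- genotype_matrix(matrix(0L, 10, 1),
                            sprintf("a%02d", 1:10),
                            loci[1, , drop = FALSE])
  expect_equal(ncol(filter_loci(g_mono, maf_min = 0)$calls), 0L)
  # idempotence
  f3 <- filter_loci(f)
  expect_identical(f3$calls, f$calls)
})

test_that("per-locus diversity statistics match hand counts and bounds", {
  loci <- function(k) data.frame(id = paste0("s", seq_len(k)), chrom = 1,
                                 pos = seq_len(k), ref = "A", alt = "G")
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L)), ids = paste0("a", 1:4),
                       loci(1))
  d <- diversity_stats(g)$per_locus
  expect_equal(d$he, 0.5)
  expect_equal(d$ho, 0.5)
  expect_equal(d$shannon_i, log(2))
  # monomorphic
  g0 <- genotype_matrix(matrix(c(0L, 0L, 0L)), ids = paste0("a", 1:3),
                        loci(1))
  expect_equal(diversity_stats(g0)$per_locus$he, 0)
  expect_equal(diversity_stats(g0)$per_locus$shannon_i, 0)
  # all heterozygotes
  g1 <- genotype_matrix(matrix(c(1L, 1L, 1L, 1L)), ids = paste0("a", 1:4),
                        loci(1))
  expect_equal(diversity_stats(g1)$per_locus$ho, 1)
  expect_equal(diversity_stats(g1)$per_locus$he, 0.5)
  # bounds across a random panel
  stats <- diversity_stats(small_geno(seed = 3))$per_locus
  expect_true(all(stats$maf >= 0 & stats$maf <= 0.5))
  expect_true(all(stats$he >= 0 & stats$he <= 0.5))
  expect_true(all(stats$shannon_i <= log(2) + 1e-12))
})

test_that("panel Ho tracks the residual heterozygosity rate", {
  g <- simulate_genotypes(geno_sim_config(
    n_accessions = 50, n_loci = 2000, residual_het_rate = 0.05,
    chrom_sizes = rep(200, 10), seed = 14))
  expect_lt(abs(diversity_stats(g)$panel["ho"] - 0.05), 0.01)
})

test_that("GSC matches the brute-force allele-sharing oracle", {
  g <- small_geno(seed = 7, n = 5, L = 8)
  expect_equal(unname(gsc_matrix(g)), brute_gsc(g$calls), tolerance = 1e-12)
  # identical accessions share everything; opposite homozygotes share nothing
  calls <- rbind(a = c(0L, 2L, 1L, 0L), b = c(0L, 2L, 1L, 0L),
                 c = c(2L, 0L, 1L, 2L))
  g2 <- genotype_matrix(calls, c("a", "b", "c"),
                        data.frame(id = paste0("s", 1:4), chrom = 1,
                                   pos = 1:4, ref = "A", alt = "G"))
  gsc <- gsc_matrix(g2)
  expect_equal(gsc["a", "b"], 1)
  expect_equal(gsc["a", "c"], 0.25)      # 3 opposite + 1 shared het
  # locus order invariance
  g3 <- genotype_matrix(calls[, 4:1], c("a", "b", "c"),
                        data.frame(id = paste0("s", 4:1), chrom = 1,
                                   pos = 4:1, ref = "A", alt = "G"))
  expect_equal(unname(gsc_matrix(g3)), unname(gsc))
  # duplicating an accession raises mean off-diagonal GSC
  g4 <- genotype_matrix(rbind(calls, a2 = calls["a", ]),
                        c("a", "b", "c", "a2"),
                        data.frame(id = paste0("s", 1:4), chrom = 1,
                                   pos = 1:4, ref = "A", alt = "G"))
  m_with <- mean(gsc_matrix(g4)[upper.tri(diag(4))])
  m_without <- mean(gsc[upper.tri(diag(3))])
  expect_gte(m_with, m_without)
})

test_that("SNP density recovers a constructed chromosome map exactly", {
  loci <- data.frame(id = paste0("s", 1:10),
                     chrom = c(rep(1, 6), rep(2, 4)),
                     pos = c(1, 5e5, 999999, 1e6, 2.5e6, 3e6,
                             10, 20, 1e6 + 1, 4e6),
                     ref = "A", alt = "G")
  g <- genotype_matrix(matrix(0L, 3, 10,
                              dimnames = list(paste0("a", 1:3), loci$id)),
                       loci = loci)
  d <- snp_density(g, window = 1e6)
  expect_equal(d$per_chrom$n_snps, c(6L, 4L))
  w1 <- d$windows[d$windows$chrom == 1, ]
  # 1-based windows [1, 1e6+1): pos 1, 5e5, 999999, 1e6; then 2.5e6 and
  # 3e6 both fall in the third window
  expect_equal(w1$n_snps, c(4L, 0L, 2L))
  w2 <- d$windows[d$windows$chrom == 2, ]
  expect_equal(w2$n_snps, c(2L, 1L, 0L, 1L))
  expect_error(snp_density(g, window = 0), "positive")
})

test_that("genotype PCA separates constructed clonal groups and duplicates score identically", {
  set.seed(9)
  proto1 <- sample(c(0L, 2L), 300, TRUE)
  proto2 <- sample(c(0L, 2L), 300, TRUE)
  calls <- rbind(matrix(rep(proto1, 6), 6, byrow = TRUE),
                 matrix(rep(proto2, 6), 6, byrow = TRUE))
  rownames(calls) <- sprintf("a%02d", 1:12)
  g <- genotype_matrix(calls,
                       loci = data.frame(id = paste0("s", 1:300), chrom = 1,
                                         pos = 1:300, ref = "A", alt = "G"))
  pc <- genotype_pca(g)
  expect_gte(pc$variance_percent[1], 99)
  expect_lt(max(pc$scores[1:6, 1]) * min(pc$scores[7:12, 1]), 0)  # separated
  expect_equal(pc$scores[1, ], pc$scores[2, ], ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("delta-K matches a spreadsheet-style hand computation", {
  mu <- c(-1000, -800, -750, -740, -735)     # K = 1..5
  set.seed(4)
  tab <- do.call(rbind, lapply(1:5, function(k)
    data.frame(K = k, rep = 1:3, logL = mu[k] + c(-1, 0, 1))))
  res <- evanno_delta_k(tab)
  sdv <- sd(c(-1, 0, 1))
  # |L''(K)| = |(mu[k+1]-mu[k]) - (mu[k]-mu[k-1])| for interior K
  want <- c(NA, abs((mu[3] - mu[2]) - (mu[2] - mu[1])),
            abs((mu[4] - mu[3]) - (mu[3] - mu[2])),
            abs((mu[5] - mu[4]) - (mu[4] - mu[3])), NA) / sdv
  expect_equal(res$table$delta_k, want, tolerance = 1e-9)
  expect_equal(res$best_k, 2)
  # perfectly linear mean L(K): delta-K identically zero
  lin <- do.call(rbind, lapply(1:4, function(k)
    data.frame(K = k, rep = 1:3, logL = -100 * k + c(-1, 0, 1))))
  expect_true(all(evanno_delta_k(lin)$table$delta_k[2:3] < 1e-9))
  expect_error(evanno_delta_k(tab[tab$K < 3, ]), "3 K values")
})
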