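#!/usr/bin/env Rscript
# Phenotypic core construction: screen the eight linkage methods at a 10%
# ratio, then run the full strategy grid (distance x ratio x allocation x
# the two best linkages) and rank all strategies by MD/VD/CR/VR.
suppressMessages(library(germcore))

seed <- 2026
tm <- read_traits("results/traits.csv")

## stage 1: linkage screen at euclidean distance, 10% ratio, deviation
screen <- strategy_grid(tm, distances = "euclidean", ratios = 0.1,
                        allocations = "deviation",
                        linkages = linkage_methods(), seed = seed)
screen_ev <- lapply(screen, function(cs)
  evaluate_core(subset_accessions(tm, cs$selected), tm))
screen_rank <- rank_strategies(screen_ev)
write.csv(screen_rank, "results/linkage_screen.csv", row.names = FALSE)
top2 <- sub(".*\\+", "", screen_rank$strategy[1:2])
cat("linkage screen (10% ratio): best two linkages:",
    paste(top2, collapse = ", "), "\n")

## stage 2: full grid over the screened linkages
grid <- strategy_grid(tm, distances = c("euclidean", "mahalanobis"),
                      ratios = c(0.1, 0.15, 0.2, 0.25, 0.3),
                      allocations = c("random", "deviation"),
                      linkages = top2, seed = seed)
evals <- lapply(grid, function(cs)
  evaluate_core(subset_accessions(tm, cs$selected), tm))
ranking <- rank_strategies(evals)
write.csv(ranking, "results/strategy_ranking.csv", row.names = FALSE)
cat(sprintf("evaluated %d strategies; all MD <= %.2f%%\n",
            nrow(ranking), max(ranking$md)))
cat(sprintf("best strategy: %s (MD %.2f, VD %.2f, CR %.2f, VR %.2f)\n",
            ranking$strategy[1], ranking$md[1], ranking$vd[1],
            ranking$cr[1], ranking$vr[1]))

best <- grid[[ranking$strategy[1]]]
writeLines(best$selected, "results/pheno_core_ids.csv")
cmp <- compare_pca(subset_accessions(tm, best$selected), tm)
cat(sprintf("top-5 cumulative PCA contribution: core %.2f%% vs population %.2f%%\n",
            cmp$cumulative_core, cmp$cumulative_full))
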