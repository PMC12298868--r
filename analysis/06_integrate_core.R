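#!/usr/bin/env Rscript
# Integrate the phenotypic and genotypic selections into the final core
# collection; everything else becomes the reserve set.
suppressMessages(library(germcore))

pheno_ids <- readLines("results/pheno_core_ids.csv")
geno_ids <- readLines("results/geno_core_ids.csv")
tm <- read_traits("results/traits.csv")
all_ids <- rownames(tm$values)

ic <- integrate_cores(pheno_ids, geno_ids, all_ids)
print(ic)
writeLines(ic$final, "results/integrated_core_ids.csv")
writeLines(ic$reserve, "results/reserve_ids.csv")

# the integrated core should still represent the population phenotypically
ev <- evaluate_core(subset_accessions(tm, ic$final), tm)
print(ev)
cat(sprintf("integrated core verdict: %s (MD %.2f%% < 20, CR %.2f%% > 80)\n",
            ev$verdict, ev$md_percent, ev$cr_percent))
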