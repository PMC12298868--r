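#!/usr/bin/env Rscript
# Phenotypic diversity of the simulated panel: descriptive statistics,
# coefficients of variation, Shannon-Weaver diversity indices, trait
# correlations and PCA.
suppressMessages(library(germcore))

tm <- read_traits("results/traits.csv")
s <- summarize_traits(tm)
write.csv(s, "results/trait_summary.csv", row.names = FALSE)

cat(sprintf("CV ranges from %.2f%% (%s) to %.2f%% (%s)\n",
            min(s$cv_percent), s$trait[which.min(s$cv_percent)],
            max(s$cv_percent), s$trait[which.max(s$cv_percent)]))
cat(sprintf("Shannon-Weaver GDI ranges %.3f - %.3f across the 19 traits\n",
            min(s$gdi), max(s$gdi)))

corr <- correlate_traits(tm)
write.csv(round(corr$r, 4), "results/trait_correlation.csv")
sig <- mean(corr$p[upper.tri(corr$p)] < 0.05)
cat(sprintf("%.1f%% of trait pairs significantly correlated (p < 0.05)\n",
            100 * sig))

pc <- pca_traits(tm)
n_big <- sum(pc$eigenvalues > 1)
cat(sprintf("%d principal components with eigenvalue > 1; cumulative contribution %.2f%%\n",
            n_big, pc$cumulative_percent[n_big]))
write.csv(data.frame(component = seq_along(pc$eigenvalues),
                     eigenvalue = pc$eigenvalues,
                     contribution = pc$contribution_percent,
                     cumulative = pc$cumulative_percent),
          "results/trait_pca.csv", row.names = FALSE)
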