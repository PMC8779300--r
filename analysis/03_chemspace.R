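#!/usr/bin/env Rscript
# Chemical-space analysis of the simulated library: drug-range scaling,
# PCA with variable contributions, PERMANOVA of the category separation,
# and per-NP mean Jaccard similarity to the drug cloud.

suppressPackageStartupMessages(library(npdrugspace))

seed <- 20220103
descriptors <- read_descriptor_csv("results/descriptors.csv")

scaled <- drug_range_scale(descriptors)
pca <- run_pca(scaled, n_axes = 2)
pm <- permanova(scaled, n_perm = 999, seed = seed)
jac <- mean_jaccard_to_drugs(
  scaled, ids = scaled$ids[scaled$categories == "np"])

scores <- data.frame(id = scaled$ids, category = scaled$categories,
                     pca$scores[, 1:2])
write_scores_csv(scores, "results/pca_scores.csv")
contrib <- data.frame(id = rownames(pca$variable_contributions_pct),
                      pca$variable_contributions_pct,
                      check.names = FALSE)
write_scores_csv(contrib, "results/pca_contributions.csv")
write_scores_csv(jac, "results/jaccard_similarity.csv")

cat(sprintf("PCA: first two axes explain %.1f%% of the variance\n",
            sum(pca$axis_variance_pct[1:2])))
top <- order(pca$variable_contributions_pct[, 1], decreasing = TRUE)[1:3]
cat("  top PC1 contributors (baseline 100/",
    length(scaled$variables), " = ",
    sprintf("%.2f", 100 / length(scaled$variables)), "%): ",
    paste(sprintf("%s (%.1f%%)", rownames(pca$variable_contributions_pct)[top],
                  pca$variable_contributions_pct[top, 1]), collapse = ", "),
    "\n", sep = "")
cat(sprintf("PERMANOVA: F%d,%d = %.1f, r2 = %.3f, p = %.3g (%d permutations)\n",
            pm$df_among, pm$df_within, pm$F, pm$r2, pm$p, pm$n_perm))
cat(sprintf("Mean Jaccard to drugs over %d NPs: median %.3f (range %.3f-%.3f)\n",
            nrow(jac), median(jac$mean_jaccard), min(jac$mean_jaccard),
            max(jac$mean_jaccard)))
cat("Scores written to results/.\n")
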