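#!/usr/bin/env Rscript
# Composite scoring: structural similarity (fingerprint + MCS Tanimoto) of
# each NP to the drugs, the summed drug index over the five z-standardised
# components, and quadrant classification of the tails.

suppressPackageStartupMessages(library(npdrugspace))

seed <- 20220104
properties <- read_scores_csv("results/properties.csv")
endpoints <- read_endpoint_csv("results/endpoints.csv")
descriptors <- read_descriptor_csv("results/descriptors.csv")
structures <- read.table("results/structures.smi",
                         col.names = c("smiles", "id"))
mols <- molecule_set(structures$id, structures$smiles,
                     properties$category[match(structures$id, properties$id)])

res <- score_library(mols, properties, descriptors, endpoints,
                     time_cap = 1, drug_sample = 10, seed = seed)
write_scores_csv(res$report, "results/composite_report.csv")

comp <- res$composite
cat(sprintf("Summed drug index over %d NPs: mean %.2e, SD %.2f\n",
            nrow(comp), mean(comp$summed), sd(comp$summed)))
cat("Quadrant counts:\n")
print(table(comp$quadrant))
cat("Top 5 NPs by summed index:\n")
print(res$report[1:5, c("id", "summed", "qed", "quadrant", "mean_jaccard",
                        "tanimoto_index", "rdl", "ro5")], digits = 3)
cat("Full ranked report written to results/composite_report.csv.\n")
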