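#!/usr/bin/env Rscript
# Build the synthetic study library: drug / NP / toxin compound sets with
# descriptor, property and ADMET endpoint tables, plus fixture structures.
# Writes the tables under results/.

suppressPackageStartupMessages(library(npdrugspace))

seed <- 20220101
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_drug = 200, n_np = 560, n_toxin = 200, seed = seed)
lib <- simulate_library(cfg)
mols <- assign_fixture_structures(cfg)

write_descriptor_csv(lib$descriptors, "results/descriptors.csv")
write_scores_csv(lib$properties, "results/properties.csv")
write_endpoint_csv(bind_endpoint_tables(lib$endpoints), "results/endpoints.csv")
writeLines(paste(mols$smiles, mols$id), "results/structures.smi")

cat("Simulated library (seed ", seed, "):\n", sep = "")
cat("  drugs: ", cfg$n_drug, ", NPs: ", cfg$n_np,
    ", toxins: ", cfg$n_toxin, "\n", sep = "")
cat("  descriptors: ", cfg$descriptor_dim, " variables, group shift delta = ",
    cfg$delta, "\n", sep = "")
cat("  endpoints: ", cfg$n_endpoints, " binary ADMET endpoints\n", sep = "")
cat("  drug median MW: ",
    round(median(lib$properties$MW[lib$properties$category == "drug"])),
    " Da; NP 95th pct MW: ",
    round(quantile(lib$properties$MW[lib$properties$category == "np"], 0.95)),
    " Da\n", sep = "")
cat("Tables written to results/.\n")
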