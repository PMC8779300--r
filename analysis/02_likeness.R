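#!/usr/bin/env Rscript
# Drug-likeness scoring of the simulated library: QED, RDL, rule-of-five
# violation counts, ADMET-score; Kruskal-Wallis comparison across compound
# categories. Reads the tables written by 01_simulate.R.

suppressPackageStartupMessages(library(npdrugspace))

properties <- read_scores_csv("results/properties.csv")
endpoints <- read_endpoint_csv("results/endpoints.csv")

profiles <- likeness_profiles(properties, endpoints)
write_scores_csv(profiles, "results/likeness_profiles.csv")

cat("Likeness profiles for ", nrow(profiles), " compounds\n", sep = "")
for (idx in c("qed", "rdl", "admet_std")) {
  med <- tapply(profiles[[idx]], profiles$category, median)
  kw <- kruskal.test(profiles[[idx]], factor(profiles$category))
  cat(sprintf("  %-9s medians: drug %.3f | np %.3f | toxin %.3f  (KW chi2 = %.1f, p = %.3g)\n",
              idx, med[["drug"]], med[["np"]], med[["toxin"]],
              kw$statistic, kw$p.value))
}
exceed <- tapply(profiles$ro5 > 0, profiles$category, mean)
cat(sprintf("  Ro5 >= 1 exceedance: drug %.0f%% | np %.0f%% | toxin %.0f%%\n",
            100 * exceed[["drug"]], 100 * exceed[["np"]],
            100 * exceed[["toxin"]]))
cat(sprintf("  QED-RDL correlation (all compounds): %.3f\n",
            cor(profiles$qed, profiles$rdl)))
cat("Profiles written to results/likeness_profiles.csv.\n")
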