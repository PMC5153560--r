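#!/usr/bin/env Rscript
# Scatter plots of the key metric-score relationships.

library(striatex)

clinical <- read.csv("results/clinical.csv", stringsAsFactors = FALSE)
features <- read.csv("results/features.csv", stringsAsFactors = FALSE)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

# conventional benchmark: putamen uptake with and without controls
plot_scatter(features, clinical, "uptake", "updrs3",
             "results/figures/putamen_uptake_updrs_all.png",
             region = "putamen", side = "more", subset = "PD+HC")
plot_scatter(features, clinical, "uptake", "updrs3",
             "results/figures/putamen_uptake_updrs_pd.png",
             region = "putamen", side = "more", subset = "PD")

# caudate texture within patients
for (metric in c("uptake", "entropy", "contrast", "dissimilarity",
                 "homogeneity")) {
  plot_scatter(features, clinical, metric, "updrs3",
               sprintf("results/figures/caudate_%s_updrs_pd.png", metric),
               region = "caudate", side = "more", subset = "PD")
}

cat("Wrote", length(list.files("results/figures")),
    "figures to results/figures/\n")
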