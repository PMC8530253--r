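#!/usr/bin/env Rscript
# Stage 3 — per-clinician sociometrics.
#
# Computes eigenvector centrality, betweenness centrality and eccentricity
# for every clinician in each period network and summarises them by
# specialty. Tables land under results/sociometrics/.

library(collabnet)

net_dir <- "results/networks"
data_dir <- "results/data"
out <- "results/sociometrics"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

roster <- utils::read.csv(file.path(data_dir, "roster.csv"),
                          colClasses = "character")

for (per in c("pre", "intra")) {
  net <- read_network_graphml(file.path(net_dir,
                                        paste0("network_", per, ".graphml")),
                              period_label = per)
  tab <- sociometric_table(net)
  write_sociometrics(tab, file.path(out, paste0("sociometrics_", per, ".csv")))
  summ <- summarize_by_specialty(tab, roster)
  utils::write.csv(summ, file.path(out, paste0("by_specialty_", per, ".csv")),
                   row.names = FALSE)
  cat(sprintf(
    "%s: median eccentricity %d; nurse median eigenvector %.3f; neonatologist median betweenness %.4f\n",
    per, median(tab$eccentricity),
    median(tab$eigenvector[tab$specialty == "nicu_nurse"]),
    median(tab$betweenness[tab$specialty == "neonatologist"])))
}
cat("sociometric tables written under", out, "\n")
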