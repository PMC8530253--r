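#!/usr/bin/env Rscript
# Stage 4 — pre/intra hypothesis tests and outcome comparison.
#
# Runs the specialty-level family (6 specialties x 3 metrics, Bonferroni
# m = 18), the network-level family over specialty means (m = 3), and the
# patient-outcome comparison (Mann-Whitney on LOS plus a descriptive
# demographics/disposition table). Results land under results/comparison/.

library(collabnet)

soc_dir <- "results/sociometrics"
data_dir <- "results/data"
out <- "results/comparison"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

read_soc <- function(per) {
  tab <- utils::read.csv(file.path(soc_dir,
                                   paste0("sociometrics_", per, ".csv")),
                         stringsAsFactors = FALSE)
  tab$period <- per
  tab
}
pre <- read_soc("pre"); intra <- read_soc("intra")

sl <- specialty_level_compare(pre, intra)
nl <- network_level_compare(pre, intra)
pat_pre <- read_patients(file.path(data_dir, "patients_pre_like.csv"))
pat_intra <- read_patients(file.path(data_dir, "patients_intra_like.csv"))
oc <- outcomes_compare(pat_pre[!pat_pre$excluded, ],
                       pat_intra[!pat_intra$excluded, ])

all_tests <- rbind(sl, nl, oc$tests)
write_comparisons(all_tests, file.path(out, "comparisons.csv"))
utils::write.csv(oc$descriptive, file.path(out, "outcomes_descriptive.csv"),
                 row.names = FALSE)

sig <- all_tests[all_tests$p_adjusted < 0.05, ]
cat(nrow(all_tests), "tests run;", nrow(sig),
    "significant after Bonferroni within each design family:\n")
for (i in seq_len(nrow(sig))) {
  r <- sig[i, ]
  cat(sprintf("  %s %s%s: median %.4g (pre) vs %.4g (intra), p_adj %.4g\n",
              r$design, r$metric,
              if (!is.na(r$specialty)) paste0(" [", r$specialty, "]") else "",
              r$median_pre, r$median_intra, r$p_adjusted))
}
cat(sprintf("LOS: median %.1f vs %.1f days, raw p %.3f\n",
            oc$los$median[1], oc$los$median[2], oc$tests$p_raw))
cat("comparison tables written under", out, "\n")
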