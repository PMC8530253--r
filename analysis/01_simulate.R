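#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohorts.
#
# Generates the matched pre/intra synthetic NICU cohorts at the default
# study sizes (386 and 326 admissions over the two 4-month windows) and
# writes the raw audit logs and patient tables under results/data/.

library(collabnet)

seed <- 20190901L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (lab in c("pre_like", "intra_like")) {
  cfg <- preset(lab, seed = seed)
  co <- simulate_cohort(cfg, seed = seed)
  write_events(co$events, file.path(out, paste0("events_", lab, ".csv")))
  write_patients(co$patients, file.path(out, paste0("patients_", lab, ".csv")))
  utils::write.csv(co$roster, file.path(out, "roster.csv"), row.names = FALSE)
  cat(sprintf(
    "%s: %d patients (LOS median %.0f d, IQR %.1f-%.1f), %d events, %d active clinicians\n",
    lab, nrow(co$patients), median(co$patients$los_days),
    quantile(co$patients$los_days, 0.25), quantile(co$patients$los_days, 0.75),
    nrow(co$events), length(unique(co$events$clinician_id))))
}
cat("cohort files written under", out, "\n")
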