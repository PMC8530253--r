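#!/usr/bin/env Rscript
# Stage 2 — build the collaboration networks.
#
# Reads the simulated audit logs, partitions events into the pre/intra
# study windows, reduces them to patient-day units, and projects each
# period into its weighted clinician collaboration network (tie = same
# patient, same calendar day; weight = shared patient days). Networks are
# exported as GraphML, GEXF and edge-list CSV under results/networks/.

library(collabnet)

data_dir <- "results/data"
out <- "results/networks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

roster <- utils::read.csv(file.path(data_dir, "roster.csv"),
                          colClasses = "character")
periods <- default_periods()

for (pair in list(c("pre_like", "pre"), c("intra_like", "intra"))) {
  lab <- pair[1]; per <- pair[2]
  ev <- read_events(file.path(data_dir, paste0("events_", lab, ".csv")))
  pt <- read_patients(file.path(data_dir, paste0("patients_", lab, ".csv")))
  ev <- filter_patients(ev, pt)
  parts <- partition_by_period(ev, periods)
  pd <- to_patient_days(parts[[per]])
  net <- build_network(pd, roster, period_label = per)
  st <- network_stats(net)
  cat(sprintf(
    "%s: %d events in window (%d outside), %d patient days -> %d clinicians, %d ties, total weight %d, %d component(s)\n",
    per, nrow(parts[[per]]), attr(parts, "dropped"), nrow(pd),
    st$n_nodes, st$n_edges, st$total_weight, st$n_components))
  for (fmt in c("graphml", "gexf", "edgelist")) {
    ext <- c(graphml = "graphml", gexf = "gexf", edgelist = "csv")[[fmt]]
    write_network(net, file.path(out, paste0("network_", per, ".", ext)), fmt)
  }
}
cat("network files written under", out, "\n")
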