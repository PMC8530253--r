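# collabnet

Care teams leave a complete behavioural trace in the electronic health
record: every order, note, medication administration and measurement is a
timestamped action by an identifiable clinician on an identifiable
patient. `collabnet` turns those audit logs into weighted clinician
collaboration networks and asks how the structure of a care team changed
between two periods — the motivating case being a neonatal intensive care
unit (NICU) before and during the COVID-19 pandemic. It is written for
clinical-informatics and health-services researchers who have an action
log and a patient table and want a reproducible, tested pipeline instead
of a one-off Gephi session.

## The method

1. **Tie rule.** Clinicians *a* and *b* are tied iff both acted on the
   same patient's record on the same calendar day. The edge weight is the
   number of distinct (patient, day) pairs they share — repeat actions
   within a day collapse to one *patient-day* unit. One static network
   per study period; nodes carry specialty labels.
2. **Sociometrics**, computed from first principles per clinician:
   eigenvector centrality (power iteration per connected component,
   max-normalised; hub/leadership role), betweenness centrality
   (Brandes' algorithm over hop-count shortest paths, normalised by
   $(n-1)(n-2)/2$ per component; bridging role) and eccentricity
   (max BFS distance within the component; collaboration difficulty).
3. **Comparison.** Mann-Whitney U tests (exact enumeration for small
   tie-free samples, tie-corrected normal approximation otherwise) in
   two designs: per-specialty arrays of clinician values (6 specialties
   × 3 metrics, Bonferroni m = 18) and arrays of specialty means
   (m = 3); plus a Mann-Whitney test on length of stay and a descriptive
   demographics/disposition table.

Because real audit logs are protected health data, the package ships a
seeded synthetic NICU generator (`preset("pre_like")`,
`preset("intra_like")`) whose two staffing regimes — pod-based nursing
with high vs low cross-coverage, narrow vs wide neonatologist census
territories — reproduce the directional structural contrasts the method
is designed to detect. See `vignettes/collaboration-networks.Rmd` for the
model, every tunable parameter, and what the synthetic data does and
does not emulate.

## Worked example

The numbered scripts under `analysis/` run the whole study; each is a
thin driver over exported functions and writes tables under `results/`.

```sh
Rscript analysis/01_simulate.R        # matched synthetic cohorts
Rscript analysis/02_build_networks.R  # per-period collaboration networks
Rscript analysis/03_sociometrics.R    # centralities + eccentricity
Rscript analysis/04_compare.R         # hypothesis tests, outcome table
Rscript analysis/05_regime_experiments.R  # multi-seed replication study
```

Output of stages 1–3 (seed 20190901):

```
pre_like: 386 patients (LOS median 11 d, IQR 4.0-24.0), 89977 events, 204 active clinicians
intra_like: 326 patients (LOS median 8 d, IQR 3.0-21.0), 81359 events, 201 active clinicians
pre: 70229 events in window (16096 outside), 22892 patient days -> 202 clinicians, 6338 ties, total weight 35374, 1 component(s)
intra: 57530 events in window (22094 outside), 18695 patient days -> 200 clinicians, 2765 ties, total weight 28405, 1 component(s)
pre: median eccentricity 2; nurse median eigenvector 0.455; neonatologist median betweenness 0.0236
intra: median eccentricity 3; nurse median eigenvector 0.315; neonatologist median betweenness 0.0672
```

Reading: in the intra-period regime the unit's pods decouple — every
clinician is farther from the farthest colleague (median eccentricity 3
vs 2), bedside nurses lose their hub position (median eigenvector 0.315
vs 0.455), and neonatologists, now rounding across pods, become the
bridges (median betweenness 0.0672 vs 0.0236). Stage 4 prints the test
table: all three contrasts survive Bonferroni correction within the
18-test specialty-level family (nurse eigenvector p_adj 8.4e-08, nurse
eccentricity p_adj 5.8e-25, neonatologist betweenness p_adj 0.039),
while length of stay does not differ (median 11 vs 8 days, raw p 0.122 —
the two cohorts draw from nearly identical LOS distributions).

The same pipeline runs from files instead of the generator: point the
YAML config's `inputs:` block at an events CSV
(`clinician_id,specialty,patient_id,timestamp,action_category`) and a
patient CSV, and call `run_pipeline(config, out_dir)` — see
`inst/extdata/demo_config.yaml` for the full format.

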