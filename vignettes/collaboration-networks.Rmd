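---
title: "Measuring care-team collaboration from EHR audit logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring care-team collaboration from EHR audit logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Every action a clinician commits to a patient's electronic health record —
documenting a condition or procedure, placing an order, administering a
medication, writing a note, recording a measurement — leaves a timestamped
trace. `collabnet` treats those traces as evidence of collaboration: two
clinicians who act on the same patient's record on the same calendar day
are taken to have a working relationship around that patient. The unit of
counting is the *patient day* (one patient on one calendar day); multiple
actions by one clinician on one patient in one day collapse to a single
patient-day unit, so the tie weight between two clinicians is the
cumulative number of distinct patient days they shared, not the number of
clicks either of them produced.

Each study period (by default September–December 2019 and March–June
2020, configurable for other disruption studies) yields one static
weighted undirected network whose nodes are the clinicians active in that
window, labelled by specialty. Three per-clinician sociometrics quantify
the structure:

* **Eigenvector centrality** — the leading eigenvector of the adjacency
  matrix; a clinician scores high when connected to other well-connected
  clinicians. Read as leadership or hub role in information sharing.
* **Betweenness centrality** — the share of all-pairs shortest paths
  passing through the clinician (Brandes' algorithm, fractional counting
  over tied paths, normalised by $(n-1)(n-2)/2$ within the clinician's
  connected component). Read as bridging a wide spectrum of patients and
  sub-teams.
* **Eccentricity** — the maximum hop distance from the clinician to any
  other clinician in the same component. Read as collaboration
  difficulty: a larger radius means more intermediaries to reach the
  farthest colleague.

Two periods are compared with Mann-Whitney U tests in two designs: the
*specialty-level* design pools the per-clinician values of one specialty
in each period (6 specialties × 3 metrics = 18 tests, Bonferroni within
the family), and the *network-level* design compares the arrays of
per-specialty means (3 tests). Patient outcomes are compared with a
Mann-Whitney test on length of stay plus a descriptive
demographics/disposition table.

## Numerical and algorithmic choices

**Day binning.** A tie requires action on the *same calendar day* in a
single configured timezone, not within a rolling 24-hour window. The
patient-day counting unit presupposes discrete days; rolling windows are
a non-goal (`day_binning: calendar` is the only supported mode).

**Paths are hop-based.** Patient-day weights are similarities, not
costs; inverting them into distances would be an uncited transformation.
Betweenness and eccentricity therefore use unweighted shortest paths.

**Eigenvector centrality is unweighted by default.** Both modes are
implemented and tested (`weighted = TRUE` uses tie weights). The default
is the binary adjacency for two reasons. First, it is the convention of
the graph tooling this analysis is calibrated against. Second, on
strongly modular staffing graphs the weighted leading eigenvector
localises on the single heaviest sub-team: one pod's clinicians score
near 1 and everyone else near 0, so specialty medians degenerate into
noise about which pod happened to be heaviest. The unweighted eigenvector
spreads across the network and yields stable specialty contrasts.

**Power iteration with a spectral shift.** Scores are computed per
connected component by power iteration on $A + I$. Pure power iteration
oscillates on bipartite components (a star alternates between two
states forever); adding the identity shifts all eigenvalues up by one,
breaking the $\pm\lambda_1$ symmetry without changing the leading
eigenvector. Iteration stops when successive max-normalised iterates
differ by less than `tol` (default 1e-10) in the max-norm, errs after
`max_iter` (default 10 000) iterations, and starts from the uniform
vector — fully deterministic. Scores are max-normalised to 1 *within
each component*; a global normalisation would zero out every component
that does not hold the dominant eigenvalue and make specialty medians
artifactual. Isolated nodes score 0, have eccentricity 0 and betweenness
0 (as do dyad members, whose component has no third party to bridge).

**Mann-Whitney U.** U is computed from midranks. With `method = "auto"`
the p-value comes from full enumeration of the
$\binom{n_x+n_y}{n_x}$ group labelings when both samples have at most 8
observations and no ties, otherwise from the normal approximation with
tie-corrected variance and a continuity correction of 1/2. Ties are
certain for integer eccentricities, so those tests always take the
normal path. The approximation tracks the exact p to within 0.02 for
group sizes of 5 and above; below that the discrete null distribution is
too coarse for any normal curve to track, which is an intrinsic property
of the approximation, not an implementation choice. All tests are
two-sided by default ("95% CI" in this literature means $\alpha = 0.05$);
one-sided alternatives are available. The Bonferroni family is the set of
tests actually run within one design — 18 for the full specialty-level
family, fewer if a specialty is absent from a period (skips are logged),
3 for the network-level family — never pooled across designs.

## What the synthetic generator emulates

The cohorts this package is developed and tested against are synthetic:
the generator emulates the *statistical structure* the analysis assumes,
because the real audit logs it is designed for are protected health
data. A `regime_config` fixes a cohort size, an admission window,
length-of-stay targets, a clinician roster (defaults: 120 NICU nurses,
12 nurse practitioners, 20 residents, 16 respiratory therapists, 8
cardiac ICU nurses, 6 neonatologists, 24 support staff — a plausible
single-unit scale, documented as arbitrary), and a staffing mechanism:

* Patients and pod-based staff are dealt round-robin across `pod_count`
  care pods (default 6).
* Each patient day receives `nurses_per_patient_day` bedside nurses from
  the home pod — preferentially the admission-assigned primary nurse
  (`nurse_continuity_prob`) — with non-primary slots crossing pods with
  probability `nurse_cross_coverage_prob`.
* One neonatologist covers each patient day. Physicians hold stable
  contiguous pod territories whose width is the daily census block
  `physician_patients_per_day` relative to the steady-state per-pod
  census; wider blocks span more pods and make physicians the bridges
  between otherwise separate sub-teams.
* Nurse practitioners, residents, respiratory therapists, cardiac ICU
  nurses and support staff cover patient days with per-role
  probabilities, crossing pods with `pod_mixing_prob`.
* Every clinician carries a log-normal activity propensity
  (`activity_sdlog`, default 1): a full-time core and a per-diem
  periphery, which is what gives real rosters their wide within-specialty
  spread of centralities. Without it, all members of a specialty are
  statistically identical and any seed-to-seed fluctuation of global
  network structure shows up as a spurious specialty difference.
* Each assignment emits 1–5 events over the six action categories;
  length of stay is log-normal with `meanlog = log(median)` and
  `sdlog = log(q_{75}/q_{25})/(2\,z_{0.75})` so the sample median and IQR
  land near their targets; demographics, dispositions and the exclusion
  flag follow configured proportions (the patient tables carry an
  `unknown` sex category at 17.6% because the cohort table this is
  calibrated to reports female and male at 41.2% each, implying an
  unreported remainder — an inference, not a reported number).

The two shipped presets differ only in staffing structure and cohort
targets. `pre_like` (386 admissions, LOS median 10 d, IQR 4–20): high
nurse cross-coverage (0.30), pod-width physician territories, moderate
pod mixing (0.15). `intra_like` (326 admissions, LOS median 9 d, IQR
3.3–21.8): cross-coverage and mixing cut to 0.02, physician territories
widened to span roughly two pods, higher primary-nurse continuity, a 3%
exclusion flag rate. Under `pre_like`, cross-covering nurses knit the
pods together — short paths, nurse hubs, physicians bridging little.
Under `intra_like`, pods are isolated and physicians become the main
inter-pod bridges: median eccentricity rises, nurse eigenvector
centrality falls, neonatologist betweenness rises. These are the three
directional contrasts the pipeline is expected to detect, and the
package's acceptance suite verifies all three (plus rejection of the
corresponding specialty-level tests) in at least 90% of 20 matched-seed
pairs at the default sizes.

The mechanism is deliberately the simplest one that can tune the three
effects independently; its parameters are honest knobs, not estimates of
any real unit's staffing. Seeding is hierarchical: one root seed, with
per-stage substreams derived deterministically, so adding a stage never
perturbs earlier stages and identical (config, seed) pairs produce
byte-identical CSVs.

## What passing tests do and do not show

Because the pods, territories and activity propensities only *emulate*
staffing structure, the synthetic networks are denser and smaller than a
real 4-month hospital extract, which contains thousands of actors most
of whom touch a handful of patients. Absolute magnitudes differ
accordingly: synthetic median eccentricities sit around 2–3 (pre) versus
3–4 (intra) rather than the 3 versus 4 of a real unit, and synthetic
centrality medians are larger than real ones because the roster is
small. Passing the acceptance suite shows that the pipeline recovers
*directions and test decisions* under a controlled generative model with
the assumed structure — not that the generator reproduces any particular
hospital. The type-I error study (200 pre-vs-pre pairs at 50 patients,
family-wise rejection rate at Bonferroni-adjusted $\alpha$ within two
binomial standard errors of 5%) shows the test design does not
manufacture differences from seed noise alone; it cannot rule out
anticonservatism on real networks whose clinicians are correlated in
ways the generator does not model.

A real deployment replaces the `simulate` block of the pipeline
configuration with paths to an events CSV and a patient CSV in the
documented schema; everything downstream is identical.

## Problem sizes used by the shipped experiments

The analysis scripts under `analysis/` run one matched pair at the
default cohort sizes (386/326 patients, ≈200 active clinicians, ≈40 000
events per period), 20 matched pairs for directional recovery, and a
50-pair null study; the acceptance suite runs the null study at 200
pairs. These sizes were chosen so each experiment completes in minutes
on one CPU while leaving the binomial error of the estimated rates well
inside the margins being asserted.

## Known limitations

* Rolling 24-hour tie windows, directed or time-resolved networks, and
  per-action-category edge attributes are out of scope.
* Only hop-based paths are offered for betweenness/eccentricity; a
  weighted-path variant would need a defensible weight-to-distance
  transformation.
* The exclusion flag models a cohort filter (e.g. infection status) as a
  simple per-patient boolean; no infection dynamics are modelled.
* GEXF is write-only; round-trips are supported via edge-list CSV and
  GraphML.
* Specialty labels are single-valued per clinician per dataset; dual
  appointments are not representable.
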