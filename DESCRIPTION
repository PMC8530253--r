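Package: collabnet
Title: Clinician Collaboration Networks from EHR Audit Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted clinician collaboration networks from electronic
    health record (EHR) action logs using the same-patient/same-day tie rule,
    computes per-clinician sociometrics (eigenvector centrality, betweenness
    centrality, eccentricity) from first principles, and compares two study
    periods at the specialty and network level with Mann-Whitney U tests under
    Bonferroni correction. Ships a seeded synthetic neonatal intensive care
    unit (NICU) audit-log generator with two staffing regimes so the full
    pipeline is testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
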