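# Seeded synthetic NICU audit-log generator. Two staffing regimes
# (pre_like / intra_like) produce the directional structural contrasts the
# analysis is designed to detect: cross-covering nurses knit care pods
# together in pre_like, while intra_like isolates pods and widens
# neonatologist census blocks so that physicians become the bridges.
# The staffing mechanism is deliberately the simplest one that can tune
# nurse hub strength, physician bridging and network diameter
# independently; it is not an estimate of any real unit's staffing.

#' Build a regime configuration
#'
#' All knobs of the generator with validation. Use [preset()] for the two
#' shipped regimes.
#'
#' @param label regime name.
#' @param n_patients number of admissions.
#' @param admission_window length-2 Date vector (first/last admission day).
#' @param los_median,los_iqr target sample median and c(q25, q75) of length
#'   of stay in days (log-normal draw).
#' @param roster_sizes named list of clinician counts per specialty; must
#'   cover the six NICU specialties, may add `support`.
#' @param nurses_per_patient_day bedside nurses assigned per patient day.
#' @param nurse_continuity_prob probability the first nurse slot is the
#'   patient's primary nurse rather than another nurse of the home pod.
#' @param nurse_cross_coverage_prob probability a non-primary nurse slot is
#'   staffed from a different pod.
#' @param physician_patients_per_day census-block width of one
#'   neonatologist's daily rounds; wider blocks span more pods.
#' @param pod_count number of care pods (sub-teams).
#' @param pod_mixing_prob probability an NP/resident/RT/cardiac assignment
#'   crosses pods.
#' @param np_coverage_prob,resident_coverage_prob,rt_coverage_prob
#'   per-patient-day staffing probabilities for nurse practitioners,
#'   residents and respiratory therapists.
#' @param cardiac_consult_prob per-patient-day probability of a cardiac ICU
#'   nurse consult.
#' @param consult_event_rate per-patient-day probability of a support-staff
#'   touch.
#' @param activity_sdlog log-scale standard deviation of the per-clinician
#'   activity propensity (log-normal) governing how often a pod member is
#'   the one drawn for an assignment; 0 means a homogeneous roster, larger
#'   values mean a full-time core plus a per-diem periphery. Applies to
#'   pod-based specialties, not neonatologists.
#' @param unknown_sex_fraction fraction of records with sex recorded as
#'   unknown.
#' @param excluded_prob probability a patient carries the exclusion flag
#'   (e.g. COVID-19 positive).
#' @param race_probs,ethnicity_probs,disposition_probs named probability
#'   vectors over the respective levels.
#' @param age_zero_prob probability age at admission is 0 days; the rest is
#'   geometric with mean `age_mean_days`, capped at `age_max_days`.
#' @param age_mean_days,age_max_days see `age_zero_prob`.
#' @param seed default root seed carried by the config.
#' @return A validated `regime_config` list.
#' @export
regime_config <- function(label,
                          n_patients,
                          admission_window,
                          los_median = 10, los_iqr = c(4, 20),
                          roster_sizes = default_roster_sizes(),
                          nurses_per_patient_day = 2L,
                          nurse_continuity_prob = 0.6,
                          nurse_cross_coverage_prob = 0.25,
                          physician_patients_per_day = 12L,
                          pod_count = 6L,
                          pod_mixing_prob = 0.15,
                          np_coverage_prob = 0.3,
                          resident_coverage_prob = 0.35,
                          rt_coverage_prob = 0.25,
                          cardiac_consult_prob = 0.04,
                          consult_event_rate = 0.03,
                          activity_sdlog = 1,
                          unknown_sex_fraction = 0.176,
                          excluded_prob = 0,
                          race_probs = c(white = 0.668, african_american = 0.166,
                                         asian = 0.041, other = 0.125),
                          ethnicity_probs = c(non_hispanic = 0.858,
                                              latino = 0.129, unknown = 0.013),
                          disposition_probs = c(home = 0.917, expired = 0.070,
                                                hospice = 0.005,
                                                short_term_hospital = 0.008,
                                                other = 0),
                          age_zero_prob = 0.75,
                          age_mean_days = 15, age_max_days = 150,
                          seed = 1L) {
  cfg <- as.list(environment())
  cfg$admission_window <- as.Date(admission_window)
  probs <- c(nurse_continuity_prob, nurse_cross_coverage_prob, pod_mixing_prob,
             np_coverage_prob, resident_coverage_prob, rt_coverage_prob,
             cardiac_consult_prob, consult_event_rate, unknown_sex_fraction,
             excluded_prob, age_zero_prob, race_probs, ethnicity_probs,
             disposition_probs)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (n_patients < 1L) stop("n_patients must be >= 1")
  if (length(cfg$admission_window) != 2L || any(is.na(cfg$admission_window)) ||
      cfg$admission_window[1] > cfg$admission_window[2]) {
    stop("admission_window must be two ordered dates")
  }
  if (los_iqr[2] <= los_iqr[1] || los_iqr[1] <= 0) {
    stop("infeasible LOS targets: IQR must be positive and increasing")
  }
  need <- nicu_specialties()
  if (!all(need %in% names(roster_sizes))) {
    stop("roster_sizes must name all of: ", paste(need, collapse = ", "))
  }
  if (any(unlist(roster_sizes) < 0)) stop("roster sizes must be >= 0")
  if (pod_count < 1L || nurses_per_patient_day < 1L ||
      physician_patients_per_day < 1L) {
    stop("counts must be >= 1")
  }
  if (activity_sdlog < 0) stop("activity_sdlog must be >= 0")
  structure(cfg, class = "regime_config")
}

#' Default clinician roster sizes
#'
#' Plausible single-unit NICU scale; the true specialty counts of any real
#' unit are not modelled.
#' @export
default_roster_sizes <- function() {
  list(nicu_nurse = 120L, nurse_practitioner = 12L, resident = 20L,
       respiratory_therapist = 16L, cardiac_icu_nurse = 8L,
       neonatologist = 6L, support = 24L)
}

#' Shipped regime presets
#'
#' `pre_like`: high nurse cross-coverage, pod-width physician census
#' blocks, mild pod mixing — nurses knit pods together (high nurse
#' eigenvector centrality, short paths). `intra_like`: cross-coverage and
#' pod mixing cut sharply, physician census blocks widened — pods become
#' isolated (higher eccentricity) and neonatologists become the bridges
#' (higher physician betweenness), while nurse hub strength drops.
#' Cohort sizes and admission windows default to the two study windows.
#'
#' @param label `"pre_like"` or `"intra_like"`.
#' @param n_patients override the preset cohort size.
#' @param seed root seed carried by the config.
#' @return A `regime_config`.
#' @export
preset <- function(label = c("pre_like", "intra_like"), n_patients = NULL,
                   seed = 1L) {
  label <- match.arg(label)
  if (label == "pre_like") {
    regime_config(
      label = "pre_like",
      n_patients = n_patients %||% 386L,
      admission_window = c("2019-09-01", "2019-12-31"),
      los_median = 10, los_iqr = c(4, 20),
      nurse_continuity_prob = 0.6,
      nurse_cross_coverage_prob = 0.30,
      physician_patients_per_day = 8L,
      pod_mixing_prob = 0.15,
      consult_event_rate = 0.03,
      excluded_prob = 0,
      disposition_probs = c(home = 0.917, expired = 0.070, hospice = 0.005,
                            short_term_hospital = 0.008, other = 0),
      seed = seed)
  } else {
    regime_config(
      label = "intra_like",
      n_patients = n_patients %||% 326L,
      admission_window = c("2020-03-01", "2020-06-30"),
      los_median = 9, los_iqr = c(3.3, 21.8),
      nurse_continuity_prob = 0.85,
      nurse_cross_coverage_prob = 0.02,
      physician_patients_per_day = 16L,
      pod_mixing_prob = 0.02,
      consult_event_rate = 0.01,
      excluded_prob = 0.03,
      race_probs = c(white = 0.709, african_american = 0.132, asian = 0.018,
                     other = 0.141),
      ethnicity_probs = c(non_hispanic = 0.868, latino = 0.098,
                          unknown = 0.034),
      disposition_probs = c(home = 0.917, expired = 0.049, hospice = 0.006,
                            short_term_hospital = 0.025, other = 0.003),
      seed = seed)
  }
}

#' Build a clinician roster for a regime
#'
#' Ids are `<specialty>_<k>`; pod-based specialties (nurses, NPs,
#' residents, RTs, cardiac ICU nurses) are dealt round-robin across pods,
#' neonatologists and support staff are unit-wide (pod NA).
#'
#' @param config a `regime_config`.
#' @return Data frame `clinician_id`, `specialty`, `pod`.
#' @export
make_roster <- function(config) {
  podless <- "neonatologist"
  rows <- lapply(names(config$roster_sizes), function(sp) {
    k <- config$roster_sizes[[sp]]
    if (k == 0L) return(NULL)
    data.frame(clinician_id = sprintf("%s_%03d", sp, seq_len(k)),
               specialty = sp,
               pod = if (sp %in% podless) NA_integer_
                     else ((seq_len(k) - 1L) %% config$pod_count) + 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic patient table
#'
#' Admission dates are uniform over the admission window; LOS is log-normal
#' parameterised so the sample median and IQR land near the configured
#' targets (meanlog = log(median), sdlog = log(q75/q25) / (2 * qnorm(0.75)),
#' rounded up to at least 1 day); demographics, disposition and the
#' exclusion flag follow the configured proportions. Deterministic given
#' (config, seed).
#'
#' @param config a `regime_config`.
#' @param seed root seed (default: the config's).
#' @return Patient table in the standard schema plus `los_days` and `pod`.
#' @export
generate_patients <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "regime_config"))
  with_seed(substream(seed, paste0("patients:", config$label)), {
    n <- config$n_patients
    win <- config$admission_window
    admit <- win[1] + sample.int(as.integer(win[2] - win[1]) + 1L, n,
                                 replace = TRUE) - 1L
    sdlog <- log(config$los_iqr[2] / config$los_iqr[1]) / (2 * stats::qnorm(0.75))
    los <- pmax(1L, as.integer(round(stats::rlnorm(
      n, meanlog = log(config$los_median), sdlog = sdlog))))
    sex <- ifelse(stats::runif(n) < config$unknown_sex_fraction, "unknown",
                  sample(c("female", "male"), n, replace = TRUE))
    age <- ifelse(stats::runif(n) < config$age_zero_prob, 0L,
                  pmin(config$age_max_days,
                       1L + stats::rgeom(n, 1 / config$age_mean_days)))
    pt <- data.frame(
      patient_id = sprintf("p%04d", seq_len(n)),
      admit_date = admit,
      discharge_date = admit + los,
      sex = sex,
      race = sample(names(config$race_probs), n, replace = TRUE,
                    prob = config$race_probs),
      ethnicity = sample(names(config$ethnicity_probs), n, replace = TRUE,
                         prob = config$ethnicity_probs),
      age_days = as.integer(age),
      disposition = sample(names(config$disposition_probs), n, replace = TRUE,
                           prob = config$disposition_probs),
      excluded = stats::runif(n) < config$excluded_prob,
      stringsAsFactors = FALSE)
    pt$los_days <- as.integer(pt$discharge_date - pt$admit_date)
    pt$pod = ((seq_len(n) - 1L) %% config$pod_count) + 1L
    pt
  })
}

# Deterministic pod assignment for patients arriving without one
# (e.g. read back from the on-disk schema, which does not carry pods).
patient_pods <- function(patients, pod_count) {
  if ("pod" %in% names(patients)) return(patients$pod)
  ids <- sort(patients$patient_id)
  (match(patients$patient_id, ids) - 1L) %% pod_count + 1L
}

# Draw one clinician per row from the row's pod (vectorised over rows),
# optionally with per-member activity weights.
sample_from_pods <- function(pods, members_by_pod, weights_by_pod = NULL) {
  u <- stats::runif(length(pods))
  if (is.null(weights_by_pod)) {
    sizes <- vapply(members_by_pod, length, integer(1))
    idx <- ceiling(u * sizes[pods])
    return(vapply(seq_along(pods), function(i) members_by_pod[[pods[i]]][idx[i]],
                  character(1)))
  }
  cumw <- lapply(weights_by_pod, function(w) cumsum(w) / sum(w))
  vapply(seq_along(pods), function(i) {
    p <- pods[i]
    members_by_pod[[p]][findInterval(u[i], cumw[[p]]) + 1L]
  }, character(1))
}

#' Generate a synthetic action-event log
#'
#' For every hospitalised patient day: bedside nurses are drawn from the
#' patient's home pod (first slot preferentially the admission-assigned
#' primary nurse; further slots cross pods with
#' `nurse_cross_coverage_prob`); one neonatologist covers the patient via
#' daily census blocks of `physician_patients_per_day` patients, blocks
#' laid over the pod-ordered census with a rotating duty roster — wider
#' blocks span more pods; NPs, residents, RTs and cardiac ICU nurses staff
#' patient days with their coverage probabilities, crossing pods with
#' `pod_mixing_prob`; support staff touch records at `consult_event_rate`.
#' Each assignment emits 1-5 timestamped events over the six action
#' categories. Deterministic given (patients, roster, config, seed).
#'
#' @param patients patient table from [generate_patients()].
#' @param roster roster from [make_roster()].
#' @param config a `regime_config`.
#' @param seed root seed (default: the config's).
#' @return Event table in the standard schema (validated, sorted, with
#'   `day`).
#' @export
generate_events <- function(patients, roster, config, seed = config$seed) {
  stopifnot(inherits(config, "regime_config"))
  for (sp in c("nicu_nurse", "neonatologist")) {
    if (sum(roster$specialty == sp) < 1L) {
      stop("roster too small to satisfy staffing: no ", sp)
    }
  }
  by_pod <- function(sp) {
    lapply(seq_len(config$pod_count), function(p) {
      ids <- roster$clinician_id[roster$specialty == sp &
                                 (is.na(roster$pod) | roster$pod == p)]
      if (length(ids) == 0L) roster$clinician_id[roster$specialty == sp] else ids
    })
  }
  nurses_pod <- by_pod("nicu_nurse")
  np_pod <- by_pod("nurse_practitioner")
  res_pod <- by_pod("resident")
  rt_pod <- by_pod("respiratory_therapist")
  card_pod <- by_pod("cardiac_icu_nurse")
  physicians <- roster$clinician_id[roster$specialty == "neonatologist"]
  support_pod <- if (any(roster$specialty == "support")) by_pod("support") else NULL

  with_seed(substream(seed, paste0("events:", config$label)), {
    # per-clinician activity propensity: a full-time core and a per-diem
    # periphery within every pod-based specialty
    act <- stats::setNames(
      stats::rlnorm(nrow(roster), 0, config$activity_sdlog),
      roster$clinician_id)
    wts <- function(pool) lapply(pool, function(ids) unname(act[ids]))
    nurses_w <- wts(nurses_pod); np_w <- wts(np_pod); res_w <- wts(res_pod)
    rt_w <- wts(rt_pod); card_w <- wts(card_pod)
    support_w <- if (is.null(support_pod)) NULL else wts(support_pod)

    pods <- patient_pods(patients, config$pod_count)
    # primary bedside nurse fixed at admission, from the home pod
    primary <- sample_from_pods(pods, nurses_pod, nurses_w)

    # patient-day grid
    reps <- patients$los_days
    grid <- data.frame(
      patient_id = rep(patients$patient_id, reps),
      day = as.Date(unlist(mapply(
        function(a, l) as.integer(a) + seq_len(l) - 1L,
        patients$admit_date, reps, SIMPLIFY = FALSE)), origin = "1970-01-01"),
      pod = rep(pods, reps),
      primary = rep(primary, reps),
      stringsAsFactors = FALSE)
    ng <- nrow(grid)

    assign_rows <- list()
    other_pod <- function(p) {
      if (config$pod_count == 1L) return(p)
      q <- p + sample.int(config$pod_count - 1L, length(p), replace = TRUE)
      (q - 1L) %% config$pod_count + 1L
    }

    # nurse slots
    for (slot in seq_len(config$nurses_per_patient_day)) {
      if (slot == 1L) {
        keep_primary <- stats::runif(ng) < config$nurse_continuity_prob
        drawn <- sample_from_pods(grid$pod, nurses_pod, nurses_w)
        nurse <- ifelse(keep_primary, grid$primary, drawn)
      } else {
        cross <- stats::runif(ng) < config$nurse_cross_coverage_prob
        pod_slot <- ifelse(cross, other_pod(grid$pod), grid$pod)
        nurse <- sample_from_pods(pod_slot, nurses_pod, nurses_w)
      }
      assign_rows[[length(assign_rows) + 1L]] <-
        data.frame(clinician_id = nurse, patient_id = grid$patient_id,
                   day = grid$day, stringsAsFactors = FALSE)
    }

    # Neonatologist rounds: each physician holds a stable contiguous pod
    # territory whose width tracks the daily census block
    # physician_patients_per_day — wider blocks span more pods. Each
    # patient day draws one physician uniformly among those whose
    # territory covers the patient's pod, so caseloads stay balanced while
    # territory width alone controls how many pods a physician bridges.
    n_phys <- length(physicians)
    phys_start <- ((seq_len(n_phys) - 1L) %% config$pod_count) + 1L
    # Territory width in pods is a regime property: the census-block size
    # relative to the steady-state per-pod census (total patient days over
    # the admission window), not the fluctuating daily census.
    steady_census <- nrow(grid) /
      (as.integer(config$admission_window[2] - config$admission_window[1]) + 1L)
    width <- max(1L, min(config$pod_count,
                         ceiling(config$physician_patients_per_day /
                                 max(1, steady_census / config$pod_count))))
    covers <- lapply(seq_len(config$pod_count), function(q) {
      which(vapply(phys_start, function(s)
        q %in% (((s - 1L) + seq_len(width) - 1L) %% config$pod_count + 1L),
        logical(1)))
    })
    pick <- vapply(grid$pod, function(q) {
      el <- covers[[q]]
      el[ceiling(stats::runif(1) * length(el))]
    }, integer(1))
    assign_rows[[length(assign_rows) + 1L]] <- data.frame(
      clinician_id = physicians[pick],
      patient_id = grid$patient_id,
      day = grid$day, stringsAsFactors = FALSE)

    # pod-based ancillary staffing
    ancillary <- function(pool_by_pod, pool_w, prob) {
      hit <- which(stats::runif(ng) < prob)
      if (length(hit) == 0L) return(NULL)
      cross <- stats::runif(length(hit)) < config$pod_mixing_prob
      pod_slot <- ifelse(cross, other_pod(grid$pod[hit]), grid$pod[hit])
      data.frame(clinician_id = sample_from_pods(pod_slot, pool_by_pod, pool_w),
                 patient_id = grid$patient_id[hit],
                 day = grid$day[hit], stringsAsFactors = FALSE)
    }
    assign_rows[[length(assign_rows) + 1L]] <- ancillary(np_pod, np_w, config$np_coverage_prob)
    assign_rows[[length(assign_rows) + 1L]] <- ancillary(res_pod, res_w, config$resident_coverage_prob)
    assign_rows[[length(assign_rows) + 1L]] <- ancillary(rt_pod, rt_w, config$rt_coverage_prob)
    assign_rows[[length(assign_rows) + 1L]] <- ancillary(card_pod, card_w, config$cardiac_consult_prob)

    # support-staff touches (pod-based, crossing pods like other ancillary)
    if (!is.null(support_pod) && config$consult_event_rate > 0) {
      assign_rows[[length(assign_rows) + 1L]] <-
        ancillary(support_pod, support_w, config$consult_event_rate)
    }

    asg <- do.call(rbind, assign_rows)
    # expand each assignment into 1-5 categorised, timestamped events
    n_ev <- sample.int(5L, nrow(asg), replace = TRUE)
    ev <- asg[rep(seq_len(nrow(asg)), n_ev), , drop = FALSE]
    cat_probs <- c(condition = 0.06, procedure = 0.06, medication = 0.20,
                   note = 0.24, order = 0.14, measurement = 0.30)
    ev$action_category <- sample(names(cat_probs), nrow(ev), replace = TRUE,
                                 prob = cat_probs)
    ev$timestamp <- sprintf("%s %02d:%02d:00", format(ev$day, "%Y-%m-%d"),
                            sample(0:23, nrow(ev), replace = TRUE),
                            sample(0:59, nrow(ev), replace = TRUE))
    ev$specialty <- roster$specialty[match(ev$clinician_id, roster$clinician_id)]
    validate_events(ev[event_columns()],
                    source = paste0("generator:", config$label))
  })
}

#' Generate a full synthetic cohort (patients + events)
#'
#' @param config a `regime_config`.
#' @param seed root seed (default: the config's).
#' @param roster optional roster (default [make_roster()] of the config).
#' @return List with `patients`, `events`, `roster`, `config`.
#' @export
simulate_cohort <- function(config, seed = config$seed,
                            roster = make_roster(config)) {
  patients <- generate_patients(config, seed)
  events <- generate_events(patients, roster, config, seed)
  list(patients = patients, events = events, roster = roster, config = config)
}
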