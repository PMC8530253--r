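# Pre/intra hypothesis testing: Mann-Whitney U (exact enumeration or
# tie-corrected normal approximation), the specialty-level and
# network-level test designs with Bonferroni correction, and the
# descriptive patient-outcome comparison.

#' The six NICU specialties of interest
#'
#' NICU nurses, nurse practitioners, residents, respiratory therapists,
#' cardiac ICU nurses and neonatologists — the roles central to NICU care
#' and the default specialty-level testing family.
#'
#' @export
nicu_specialties <- function() {
  c("nicu_nurse", "nurse_practitioner", "resident",
    "respiratory_therapist", "cardiac_icu_nurse", "neonatologist")
}

#' Mann-Whitney U test
#'
#' U is computed by midrank assignment: U_x = R_x - n_x(n_x+1)/2 where R_x
#' is the rank sum of `x` in the pooled sample. With `method = "auto"` the
#' p-value is obtained by full enumeration of the C(n_x+n_y, n_x) group
#' labelings when both samples have at most 8 observations and there are no
#' ties; otherwise by the normal approximation with tie-corrected variance
#' and a continuity correction of 1/2. Ties are certain for integer-valued
#' metrics such as eccentricity, where the normal path is always taken.
#'
#' @param x,y non-empty numeric vectors.
#' @param alternative `"two_sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @param method `"auto"`, `"exact"` or `"normal"`. `"exact"` errors in the
#'   presence of ties.
#' @return List with `u` (U for `x`), `p`, `n_x`, `n_y`, `method` used.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two_sided", "greater", "less"),
                           method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("mann_whitney_u: both samples must be non-empty")
  }
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))  # midranks
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (method == "auto") {
    method <- if (!ties && nx <= 8L && ny <= 8L) "exact" else "normal"
  }
  if (method == "exact") {
    if (ties) stop("exact method is not defined in the presence of ties")
    p <- mwu_exact_p(u, nx, ny, alternative)
  } else {
    p <- mwu_normal_p(u, r, nx, ny, alternative)
  }
  list(u = u, p = p, n_x = nx, n_y = ny, method = method)
}

# Exact null distribution of U by enumerating all C(N, nx) labelings.
mwu_exact_p <- function(u, nx, ny, alternative) {
  N <- nx + ny
  picks <- utils::combn(N, nx)
  us <- colSums(matrix(seq_len(N)[picks], nrow = nx)) - nx * (nx + 1) / 2
  ge <- mean(us >= u); le <- mean(us <= u)
  switch(alternative,
         greater = ge,
         less = le,
         two_sided = min(1, 2 * min(ge, le)))
}

# Normal approximation with tie-corrected variance and continuity correction.
mwu_normal_p <- function(u, r, nx, ny, alternative) {
  N <- nx + ny
  mu <- nx * ny / 2
  tie_sizes <- table(r)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(tie_sizes^3 - tie_sizes) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)  # all observations tied: no evidence of shift
  sigma <- sqrt(sigma2)
  switch(alternative,
         greater = stats::pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
         less = stats::pnorm((u - mu + 0.5) / sigma),
         two_sided = {
           z <- (u - mu - sign(u - mu) * 0.5) / sigma
           min(1, 2 * stats::pnorm(-abs(z)))
         })
}

#' Bonferroni adjustment
#'
#' @param p raw p-values.
#' @param m family size (default: `length(p)`).
#' @return `min(1, m * p)` elementwise.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, m * p)

comparison_row <- function(design, metric, specialty, x_pre, x_intra,
                           alternative, alpha) {
  res <- mann_whitney_u(x_pre, x_intra, alternative = alternative)
  data.frame(design = design, metric = metric,
             specialty = if (is.null(specialty)) NA_character_ else specialty,
             n_pre = length(x_pre), n_intra = length(x_intra),
             median_pre = stats::median(x_pre),
             median_intra = stats::median(x_intra),
             u = res$u, p_raw = res$p,
             m = NA_integer_, p_adjusted = NA_real_, alpha = alpha,
             stringsAsFactors = FALSE)
}

finalize_family <- function(rows) {
  out <- do.call(rbind, rows)
  if (!is.null(out) && nrow(out) > 0L) {
    out$m <- nrow(out)
    out$p_adjusted <- bonferroni(out$p_raw, out$m)
    rownames(out) <- NULL
  }
  out
}

#' Specialty-level pre/intra comparison
#'
#' For each (specialty, metric) pair, compares the per-clinician sociometric
#' values of that specialty in the pre-period network against the same
#' specialty in the intra-period network with a Mann-Whitney U test. The
#' Bonferroni family is the set of tests actually run (18 when all six
#' default specialties are present in both periods); a specialty absent from
#' either period is skipped with a logged reason and shrinks the family.
#'
#' @param table_pre,table_intra data frames from [sociometric_table()].
#' @param specialties specialties to test (default [nicu_specialties()]).
#' @param alternative passed to [mann_whitney_u()].
#' @param alpha significance level of the family (default 0.05).
#' @return Data frame of `ComparisonResult` rows with attribute `skipped`
#'   (data frame of skipped specialties and reasons).
#' @export
specialty_level_compare <- function(table_pre, table_intra,
                                    specialties = nicu_specialties(),
                                    alternative = "two_sided", alpha = 0.05) {
  metrics <- c("eigenvector", "betweenness", "eccentricity")
  rows <- list(); skipped <- list()
  for (sp in specialties) {
    pre <- table_pre[table_pre$specialty == sp, ]
    intra <- table_intra[table_intra$specialty == sp, ]
    if (nrow(pre) == 0L || nrow(intra) == 0L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        specialty = sp,
        reason = paste0("absent from ", if (nrow(pre) == 0L) "pre" else "intra",
                        " period"),
        stringsAsFactors = FALSE)
      next
    }
    for (m in metrics) {
      rows[[length(rows) + 1L]] <- comparison_row(
        "specialty_level", m, sp, pre[[m]], intra[[m]], alternative, alpha)
    }
  }
  out <- finalize_family(rows)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(specialty = character(), reason = character())
  out
}

#' Network-level pre/intra comparison
#'
#' For each metric, the per-specialty mean values form one array per period
#' (one cell per specialty); the two arrays are compared with a
#' Mann-Whitney U test. Family size is the number of metrics (3).
#'
#' @param table_pre,table_intra data frames from [sociometric_table()].
#' @param specialties specialties whose means enter the arrays; defaults to
#'   the specialties present in both tables.
#' @param alternative,alpha as in [specialty_level_compare()].
#' @return Data frame of `ComparisonResult` rows.
#' @export
network_level_compare <- function(table_pre, table_intra, specialties = NULL,
                                  alternative = "two_sided", alpha = 0.05) {
  if (is.null(specialties)) {
    specialties <- intersect(unique(table_pre$specialty),
                             unique(table_intra$specialty))
  }
  if (length(specialties) < 2L) {
    stop("network-level comparison needs at least 2 specialties present in each period")
  }
  metrics <- c("eigenvector", "betweenness", "eccentricity")
  rows <- lapply(metrics, function(m) {
    mean_pre <- vapply(specialties, function(sp)
      mean(table_pre[[m]][table_pre$specialty == sp]), numeric(1))
    mean_intra <- vapply(specialties, function(sp)
      mean(table_intra[[m]][table_intra$specialty == sp]), numeric(1))
    comparison_row("network_level", m, NULL, mean_pre, mean_intra,
                   alternative, alpha)
  })
  finalize_family(rows)
}

#' Patient-outcome comparison and descriptive table
#'
#' Mann-Whitney U test on length of stay between the two admission cohorts,
#' plus per-period counts and percentages for sex, race, ethnicity and
#' discharge disposition. Patients are assigned to the period of their
#' admission.
#'
#' @param patients_pre,patients_intra patient tables (with `los_days`).
#' @param alternative,alpha as in [specialty_level_compare()].
#' @return List with `tests` (a one-row `ComparisonResult` data frame for
#'   LOS, family size 1) and `descriptive` (long data frame of
#'   characteristic, level, period counts and percentages).
#' @export
outcomes_compare <- function(patients_pre, patients_intra,
                             alternative = "two_sided", alpha = 0.05) {
  tests <- finalize_family(list(comparison_row(
    "outcome", "los", NULL, patients_pre$los_days, patients_intra$los_days,
    alternative, alpha)))

  desc_one <- function(chr, levels) {
    n_pre <- nrow(patients_pre); n_intra <- nrow(patients_intra)
    cnt_pre <- table(factor(patients_pre[[chr]], levels = levels))
    cnt_intra <- table(factor(patients_intra[[chr]], levels = levels))
    data.frame(characteristic = chr, level = levels,
               n_pre = as.integer(cnt_pre),
               pct_pre = round(100 * as.integer(cnt_pre) / n_pre, 1),
               n_intra = as.integer(cnt_intra),
               pct_intra = round(100 * as.integer(cnt_intra) / n_intra, 1),
               stringsAsFactors = FALSE)
  }
  descriptive <- rbind(
    desc_one("sex", sex_levels()),
    desc_one("race", race_levels()),
    desc_one("ethnicity", ethnicity_levels()),
    desc_one("disposition", disposition_levels()))

  los_summary <- function(p) {
    q <- stats::quantile(p$los_days, c(0.25, 0.5, 0.75))
    data.frame(n = nrow(p), median = unname(q[2]),
               q25 = unname(q[1]), q75 = unname(q[3]))
  }
  list(tests = tests, descriptive = descriptive,
       los = rbind(cbind(period = "pre", los_summary(patients_pre)),
                   cbind(period = "intra", los_summary(patients_intra))))
}

#' Write comparison results to CSV
#'
#' @param results a `ComparisonResult` data frame.
#' @param path output path.
#' @export
write_comparisons <- function(results, path) {
  out <- results[c("design", "metric", "specialty", "n_pre", "n_intra",
                   "median_pre", "median_intra", "u", "p_raw", "m",
                   "p_adjusted")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
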