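# Concordance audit: compare actual management against the engine's
# recommendation at the index scan, classify each patient as concordant /
# over- / under-surveillance, and compute the imaging-burden and incidence
# metrics per patient-year.
#
# Classification is anchored at the FIRST post-index management decision;
# the burden metric walks the whole radiological follow-up window. The
# intensity ordering is imaging < EUS < surgery: doing more than
# recommended (earlier scans, escalated modality, unprompted surgery) is
# over-surveillance; doing less (late or absent scans, stopping, or
# surveillance when surgery was indicated) is under-surveillance.

#' Tolerance settings for the concordance audit
#'
#' Real-world scheduling jitters, so an actual scan counts as on-time when
#' it falls within `max(pct/100 * interval, months)` of the recommended
#' interval. Surgery counts as timely within `surgery_grace_months` of a
#' surgery recommendation. With `modality_strict = FALSE` (default), MRI
#' and EUS at the recommended time are interchangeable surveillance; with
#' `TRUE`, EUS when MRI sufficed is over-surveillance and cross-sectional
#' imaging when EUS was indicated is under-surveillance.
#'
#' @param pct Percent tolerance on the recommended interval (default 25).
#' @param months Absolute floor of the tolerance in months (default 3).
#' @param modality_strict Logical (default `FALSE`).
#' @param surgery_grace_months Months within which recommended surgery
#'   (referral or resection) is timely (default 6).
#' @return An object of class `audit_tolerance`.
#' @export
audit_tolerance <- function(pct = 25, months = 3, modality_strict = FALSE,
                            surgery_grace_months = 6) {
  stopifnot(pct >= 0, months >= 0, surgery_grace_months > 0)
  structure(
    list(pct = pct, months = months, modality_strict = modality_strict,
         surgery_grace_months = surgery_grace_months),
    class = "audit_tolerance"
  )
}

interval_tolerance <- function(interval, tol) {
  max(interval * tol$pct / 100, tol$months)
}

event_modality <- function(event_type) {
  switch(event_type,
    imaging_mri_mrcp = "mri_mrcp",
    imaging_eus = "eus",
    imaging_ct = "ct",
    NA_character_
  )
}

#' Classify one patient's management against a recommendation
#'
#' Compares the first management event after the index scan with the
#' recommendation computed at the index scan.
#'
#' * Surgery recommended: surgery (referral or resection) within the grace
#'   window is concordant; surveillance or stopping instead, or surgery
#'   later than the grace window, is under-surveillance.
#' * Surveillance recommended: surgery instead is over-surveillance;
#'   imaging earlier than the tolerated window (or, under strict modality,
#'   escalated to EUS when cross-sectional imaging sufficed) is
#'   over-surveillance; imaging later than tolerated, stopping, or no
#'   event despite sufficient follow-up is under-surveillance; imaging
#'   within tolerance with an equivalent modality is concordant.
#'
#' Patients with no post-index event whose follow-up is too short to judge
#' are `"indeterminate"` and are excluded from the audit denominator
#' (reported separately, never silently dropped).
#'
#' @param patient A [patient_record()].
#' @param recommendation The [recommend()] output at the index date.
#' @param tolerance An [audit_tolerance()].
#' @return A list with `class` (one of `"concordant"`, `"over"`,
#'   `"under"`, `"indeterminate"`), `first_event_type`,
#'   `first_event_months` and `reason`.
#' @export
classify_patient <- function(patient, recommendation,
                             tolerance = audit_tolerance()) {
  idx <- index_date(patient)
  ev <- patient$management_events
  post <- ev[ev$event_date > idx, , drop = FALSE]
  first_type <- if (nrow(post)) post$event_type[1] else NA_character_
  t_first <- if (nrow(post)) months_between(idx, post$event_date[1]) else NA_real_

  out <- function(class, reason) {
    list(class = class, first_event_type = first_type,
         first_event_months = t_first, reason = reason)
  }

  if (recommendation$action == "surgery_referral") {
    grace <- tolerance$surgery_grace_months
    if (!nrow(post)) {
      if (patient$clinical_followup_months >= grace) {
        return(out("under", "surgery recommended but none performed"))
      }
      return(out("indeterminate", "follow-up shorter than surgery grace window"))
    }
    if (first_type %in% c("surgery_referral", "surgery_performed")) {
      if (t_first <= grace) {
        return(out("concordant", "surgery within grace window"))
      }
      return(out("under", "surgery delayed beyond grace window"))
    }
    return(out("under", "surveillance despite surgery recommendation"))
  }

  interval <- recommendation$interval_months
  tol <- interval_tolerance(interval, tolerance)
  if (!nrow(post)) {
    if (patient$radiological_followup_months >= interval + tol) {
      return(out("under", "no imaging within the tolerated window"))
    }
    return(out("indeterminate", "follow-up shorter than recommended interval"))
  }
  if (first_type %in% c("surgery_referral", "surgery_performed")) {
    return(out("over", "surgery despite surveillance recommendation"))
  }
  if (first_type == "surveillance_stopped") {
    return(out("under", "surveillance stopped against recommendation"))
  }
  if (t_first < interval - tol) {
    return(out("over", "imaging earlier than tolerated"))
  }
  if (t_first > interval + tol) {
    return(out("under", "imaging later than tolerated"))
  }
  if (tolerance$modality_strict) {
    got <- event_modality(first_type)
    want <- recommendation$modality
    if (want %in% c("mri_mrcp", "ct") && got == "eus") {
      return(out("over", "modality escalated to EUS"))
    }
    if (want == "eus" && got %in% c("mri_mrcp", "ct")) {
      return(out("under", "cross-sectional imaging when EUS indicated"))
    }
  }
  out("concordant", "on-time imaging with equivalent modality")
}

#' Counterfactual guideline imaging count over the follow-up window
#'
#' Walks the patient's radiological follow-up window as the guideline
#' scheduler would have: starting at the index scan, each step re-evaluates
#' [recommend()] against the observed trajectory state at the current
#' scheduled time, advances by the then-current recommended interval, and
#' accrues one scan if the scheduled visit still falls inside the window.
#' Scheduling stops if the engine escalates to surgery referral.
#'
#' @param patient A [patient_record()].
#' @param policy A `decision_policy`.
#' @param count_modality `"mri_mrcp"` (default; the burden metric counts
#'   MRI/MRCP scans only) or `"all"` to count every scheduled scan.
#' @return Number of scheduled scans, an integer >= 0.
#' @export
expected_imaging_count <- function(patient, policy = default_policy(),
                                   count_modality = c("mri_mrcp", "all")) {
  count_modality <- match.arg(count_modality)
  window <- patient$radiological_followup_months
  if (window <= 0) return(0L)
  idx <- index_date(patient)
  t <- 0
  count <- 0L
  repeat {
    core <- .recommend_core(patient, add_months(idx, t), policy)
    if (core$action == "surgery_referral") break
    t_next <- t + core$interval_months
    if (t_next > window + 1e-9) break
    if (count_modality == "all" || core$modality == "mri_mrcp") {
      count <- count + 1L
    }
    t <- t_next
  }
  count
}

observed_imaging_count <- function(patient, count_modality = c("mri_mrcp", "all")) {
  count_modality <- match.arg(count_modality)
  idx <- index_date(patient)
  ev <- patient$management_events
  post <- ev[ev$event_date > idx, , drop = FALSE]
  types <- if (count_modality == "all") {
    c("imaging_mri_mrcp", "imaging_eus", "imaging_ct")
  } else {
    "imaging_mri_mrcp"
  }
  sum(post$event_type %in% types)
}

#' Incidence rate per patient-year, in percent
#'
#' @param events Number of events observed.
#' @param patient_years Total follow-up in patient-years; must be > 0.
#' @return `100 * events / patient_years`, rounded to two decimals.
#' @export
#' @examples
#' incidence_per_patient_year(1, 1661)  # 0.06
incidence_per_patient_year <- function(events, patient_years) {
  if (!is.numeric(patient_years) || patient_years <= 0) {
    stop("patient_years must be > 0")
  }
  round(100 * events / patient_years, 2)
}

#' Percentage of a count, rounded
#'
#' @param k Numerator count.
#' @param n Denominator count; must be > 0.
#' @param digits Decimal places (default 1, the audit's reporting
#'   convention).
#' @return `100 * k / n` rounded to `digits`.
#' @export
percent_of <- function(k, n, digits = 1) {
  if (n <= 0) stop("denominator must be > 0")
  round(100 * k / n, digits)
}

#' Audit a cohort against a decision policy
#'
#' For every patient: computes the recommendation at the index scan,
#' classifies the first post-index decision ([classify_patient()]), and
#' compares the observed MRI/MRCP count with the counterfactual guideline
#' schedule ([expected_imaging_count()]). Cohort-level excess imaging is
#' pooled: total (observed - expected) scans over total patient-years of
#' radiological follow-up among classified patients.
#'
#' @param cohort An [ipmn_cohort()].
#' @param policy A `decision_policy`.
#' @param tolerance An [audit_tolerance()].
#' @return A list of class `cohort_audit` with
#'   * `results`: tibble of per-patient rows (`patient_id`, `class`,
#'     `recommended_action`, `recommended_interval`, `first_event_type`,
#'     `first_event_months`, `observed_imaging`, `expected_imaging`,
#'     `followup_years`, `excess_per_patient_year`, `reason`);
#'   * `summary`: a `cohort_audit_summary` with counts, one-decimal
#'     percentages, pooled excess per patient-year, total patient-years,
#'     PDAC events and incidence (% per patient-year).
#' @export
audit_cohort <- function(cohort, policy = default_policy(),
                         tolerance = audit_tolerance()) {
  rows <- lapply(cohort$patients, function(p) {
    rec <- recommend(p, policy = policy)
    cls <- classify_patient(p, rec, tolerance)
    obs_n <- observed_imaging_count(p)
    exp_n <- expected_imaging_count(p, policy)
    fy <- p$radiological_followup_months / 12
    tibble(
      patient_id = p$patient_id,
      class = cls$class,
      recommended_action = rec$action,
      recommended_interval = rec$interval_months,
      first_event_type = cls$first_event_type,
      first_event_months = cls$first_event_months,
      observed_imaging = obs_n,
      expected_imaging = exp_n,
      followup_years = fy,
      excess_per_patient_year = if (fy > 0) (obs_n - exp_n) / fy else NA_real_,
      reason = cls$reason
    )
  })
  results <- if (length(rows)) do.call(rbind, rows) else tibble(
    patient_id = character(), class = character(),
    recommended_action = character(), recommended_interval = numeric(),
    first_event_type = character(), first_event_months = numeric(),
    observed_imaging = integer(), expected_imaging = integer(),
    followup_years = numeric(), excess_per_patient_year = numeric(),
    reason = character()
  )

  classified <- results[results$class != "indeterminate", , drop = FALSE]
  n_total <- nrow(classified)
  n_con <- sum(classified$class == "concordant")
  n_over <- sum(classified$class == "over")
  n_under <- sum(classified$class == "under")
  total_py <- sum(classified$followup_years)
  pdac <- sum(vapply(cohort$patients, function(p) isTRUE(p$outcome_pdac), logical(1)))

  summary <- structure(
    list(
      n_total = n_total,
      n_concordant = n_con,
      n_over = n_over,
      n_under = n_under,
      n_indeterminate = nrow(results) - n_total,
      pct_concordant = if (n_total > 0) percent_of(n_con, n_total) else NA_real_,
      pct_over = if (n_total > 0) percent_of(n_over, n_total) else NA_real_,
      pct_under = if (n_total > 0) percent_of(n_under, n_total) else NA_real_,
      mean_excess_per_patient_year = if (total_py > 0) {
        sum(classified$observed_imaging - classified$expected_imaging) / total_py
      } else {
        NA_real_
      },
      total_patient_years = total_py,
      pdac_events = pdac,
      pdac_incidence_pct_per_patient_year = if (total_py > 0) {
        incidence_per_patient_year(pdac, total_py)
      } else {
        NA_real_
      }
    ),
    class = "cohort_audit_summary"
  )
  structure(list(results = results, summary = summary), class = "cohort_audit")
}

#' @export
print.cohort_audit_summary <- function(x, ...) {
  cat("<cohort_audit_summary>\n")
  cat(sprintf(
    "  %d patients classified (+%d indeterminate)\n",
    x$n_total, x$n_indeterminate
  ))
  cat(sprintf(
    "  concordant %d (%.1f%%), over %d (%.1f%%), under %d (%.1f%%)\n",
    x$n_concordant, x$pct_concordant, x$n_over, x$pct_over,
    x$n_under, x$pct_under
  ))
  cat(sprintf(
    "  excess MRI/MRCP per patient-year: %.2f over %.0f patient-years\n",
    x$mean_excess_per_patient_year, x$total_patient_years
  ))
  cat(sprintf(
    "  PDAC: %d event(s), incidence %.2f%% per patient-year\n",
    x$pdac_events, x$pdac_incidence_pct_per_patient_year
  ))
  invisible(x)
}

#' @export
print.cohort_audit <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
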