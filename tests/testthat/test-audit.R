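pol <- default_policy()
tol <- audit_tolerance()   # +/- max(25%, 3 months), surgery grace 6 months

patient_with_events <- function(event_months, event_types,
                                rad_fu = 60, clin_fu = 60, size = 10, ...) {
  d0 <- as.Date("2018-01-01")
  ev <- if (length(event_months)) {
    data.frame(event_date = add_months(d0, event_months),
               event_type = event_types, stringsAsFactors = FALSE)
  } else {
    empty_events_df()
  }
  mk_patient(size = size, date = d0, rad_fu = rad_fu, clin_fu = clin_fu,
             events = ev, ...)
}

test_that("surveillance timing classifies by the tolerance window", {
  rec18 <- mk_recommendation("imaging_surveillance", "mri_mrcp", 18)
  # 18-month recommendation, scan at 17.5 months: within +/-4.5 -> concordant
  p <- patient_with_events(17.5, "imaging_mri_mrcp")
  expect_identical(classify_patient(p, rec18, tol)$class, "concordant")
  # scan at 6 months: earlier than tolerated -> over
  p2 <- patient_with_events(6, "imaging_mri_mrcp")
  expect_identical(classify_patient(p2, rec18, tol)$class, "over")
  # scan at 30 months: later than tolerated -> under
  p3 <- patient_with_events(30, "imaging_mri_mrcp")
  expect_identical(classify_patient(p3, rec18, tol)$class, "under")
  # EUS q6 recommended, nothing for 30 months of follow-up -> under
  rec6 <- mk_recommendation("eus_surveillance", "eus", 6)
  p4 <- patient_with_events(numeric(), character(), rad_fu = 30)
  expect_identical(classify_patient(p4, rec6, tol)$class, "under")
  # no event and follow-up shorter than the interval -> indeterminate
  p5 <- patient_with_events(numeric(), character(), rad_fu = 4)
  expect_identical(classify_patient(p5, rec6, tol)$class, "indeterminate")
})

test_that("surgery crossing surveillance recommendations orders the classes", {
  rec_surv <- mk_recommendation("imaging_surveillance", "mri_mrcp", 6)
  p <- patient_with_events(2, "surgery_performed")
  expect_identical(classify_patient(p, rec_surv, tol)$class, "over")

  rec_surg <- mk_recommendation("surgery_referral", "none", NA_real_)
  p2 <- patient_with_events(2, "surgery_performed")
  expect_identical(classify_patient(p2, rec_surg, tol)$class, "concordant")
  p3 <- patient_with_events(9, "surgery_performed")
  expect_identical(classify_patient(p3, rec_surg, tol)$class, "under")
  p4 <- patient_with_events(3, "imaging_mri_mrcp")
  expect_identical(classify_patient(p4, rec_surg, tol)$class, "under")
  p5 <- patient_with_events(numeric(), character(), clin_fu = 24)
  expect_identical(classify_patient(p5, rec_surg, tol)$class, "under")
  p6 <- patient_with_events(numeric(), character(), clin_fu = 2, rad_fu = 2)
  expect_identical(classify_patient(p6, rec_surg, tol)$class, "indeterminate")
  # stopping surveillance against an active recommendation is under
  p7 <- patient_with_events(5, "surveillance_stopped")
  expect_identical(classify_patient(p7, rec_surv, tol)$class, "under")
})

test_that("the three-class partition is exhaustive over action x event x timing", {
  recs <- list(
    mk_recommendation("surgery_referral", "none", NA_real_),
    mk_recommendation("eus_surveillance", "eus", 6),
    mk_recommendation("imaging_surveillance", "mri_mrcp", 18)
  )
  event_types <- c("imaging_mri_mrcp", "imaging_eus", "imaging_ct",
                   "surgery_referral", "surgery_performed",
                   "surveillance_stopped", "none")
  timings <- c(1, 5, 17, 30)
  for (rec in recs) {
    for (ety in event_types) {
      for (tt in timings) {
        p <- if (ety == "none") {
          patient_with_events(numeric(), character(), rad_fu = tt, clin_fu = tt)
        } else {
          patient_with_events(tt, ety)
        }
        cls <- classify_patient(p, rec, tol)$class
        expect_true(cls %in% c("concordant", "over", "under", "indeterminate"))
        # indeterminate arises only when there is nothing to judge
        if (cls == "indeterminate") expect_identical(ety, "none")
      }
    }
  }
})

test_that("modality strictness is a switch, lenient by default", {
  rec <- mk_recommendation("imaging_surveillance", "mri_mrcp", 6)
  p <- patient_with_events(6, "imaging_eus")
  expect_identical(classify_patient(p, rec, tol)$class, "concordant")
  strict <- audit_tolerance(modality_strict = TRUE)
  expect_identical(classify_patient(p, rec, strict)$class, "over")
  rec_eus <- mk_recommendation("eus_surveillance", "eus", 6)
  p2 <- patient_with_events(6, "imaging_mri_mrcp")
  expect_identical(classify_patient(p2, rec_eus, strict)$class, "under")
})

test_that("the counterfactual scheduler reproduces the hand-walked visit plan", {
  # stable 10 mm cyst, 60-month window, default schedule (6 then every 18):
  # visits at months 6, 24, 42, 60 -> 4 scans
  d0 <- as.Date("2018-01-01")
  p <- patient_record(
    "w", 70, "male",
    observations = rbind(mk_obs(d0, 10), mk_obs(add_months(d0, 6), 10.1),
                         mk_obs(add_months(d0, 24), 10.2)),
    radiological_followup_months = 60, clinical_followup_months = 60
  )
  expect_identical(expected_imaging_count(p, pol), 4L)
  # window shorter than the first interval -> no scheduled scan
  p2 <- mk_patient(rad_fu = 5)
  expect_identical(expected_imaging_count(p2, pol), 0L)
  p3 <- mk_patient(rad_fu = 0)
  expect_identical(expected_imaging_count(p3, pol), 0L)
  # a WF patient is scheduled on EUS: zero MRI/MRCP scans, but scans counted
  # under the all-modality variant
  p4 <- mk_patient(size = 32, rad_fu = 13)
  expect_identical(expected_imaging_count(p4, pol), 0L)
  expect_identical(expected_imaging_count(p4, pol, "all"), 2L)
  # HRS at index: no surveillance is scheduled at all
  p5 <- mk_patient(size = 12, obstructive_jaundice = TRUE, rad_fu = 60)
  expect_identical(expected_imaging_count(p5, pol), 0L)
})

test_that("incidence arithmetic follows the percent-per-patient-year definition", {
  expect_identical(incidence_per_patient_year(1, 1661), 0.06)
  expect_identical(incidence_per_patient_year(0, 123), 0)
  expect_identical(incidence_per_patient_year(5, 1000), 0.5)
  expect_error(incidence_per_patient_year(1, 0), "patient_years")
  expect_error(incidence_per_patient_year(1, -3), "patient_years")
})

test_that("audit summary partitions the cohort and pools the excess metric", {
  g <- generate_cohort_with_truth(cohort_spec(n_patients = 120, seed = 11))
  aud <- audit_cohort(g$cohort, pol, tol)
  s <- aud$summary
  expect_identical(s$n_total, s$n_concordant + s$n_over + s$n_under)
  expect_identical(s$n_total + s$n_indeterminate, length(g$cohort))
  expect_equal(s$pct_concordant + s$pct_over + s$pct_under, 100, tolerance = 0.002)
  # per-patient excess rows satisfy the defining identity
  r <- aud$results[aud$results$followup_years > 0, ]
  expect_equal(r$excess_per_patient_year,
               (r$observed_imaging - r$expected_imaging) / r$followup_years)
  # indeterminate patients are reported, never silently dropped
  expect_identical(nrow(aud$results), length(g$cohort))
})

test_that("an exactly policy-following cohort audits as fully concordant", {
  spec <- cohort_spec(
    n_patients = 80, seed = 3,
    behavior = behavior_spec(1, 0, 0, concordant_frac = c(1, 1)),
    wf_hazard = 0, hrs_hazard = 0, p_jaundice = 0, p_nodule = 0,
    baseline_feature_prob = 0, pdac_hazard = 0
  )
  aud <- audit_cohort(generate_cohort(spec), pol, tol)
  expect_identical(aud$summary$n_over, 0L)
  expect_identical(aud$summary$n_under, 0L)
  expect_equal(aud$summary$pct_concordant, 100)
  expect_equal(aud$summary$mean_excess_per_patient_year, 0)
})

test_that("widening the tolerance never moves a patient off concordant", {
  g <- generate_cohort(cohort_spec(n_patients = 150, seed = 21))
  narrow <- audit_cohort(g, pol, audit_tolerance(pct = 15, months = 2))
  wide <- audit_cohort(g, pol, audit_tolerance(pct = 40, months = 5))
  con_narrow <- narrow$results$patient_id[narrow$results$class == "concordant"]
  con_wide <- wide$results$patient_id[wide$results$class == "concordant"]
  expect_true(all(con_narrow %in% con_wide))
})

test_that("an empty cohort yields a zero summary with undefined rates flagged", {
  aud <- audit_cohort(ipmn_cohort(list()), pol, tol)
  expect_identical(aud$summary$n_total, 0L)
  expect_true(is.na(aud$summary$pct_concordant))
  expect_true(is.na(aud$summary$mean_excess_per_patient_year))
})
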