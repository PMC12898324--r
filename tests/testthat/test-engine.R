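pol <- default_policy()

test_that("growth rate matches hand arithmetic and the least-squares oracle", {
  d0 <- as.Date("2018-01-01")
  obs <- rbind(mk_obs(d0, 10), mk_obs(d0 + 731, 16))  # 731 d = 24.02 months
  expect_equal(compute_growth_rate(obs), 6, tolerance = 0.01)

  flat <- rbind(mk_obs("2018-01-01", 10), mk_obs("2019-04-09", 10))
  expect_equal(compute_growth_rate(flat), 0)

  tri <- rbind(
    mk_obs(d0, 10),
    mk_obs(add_months(d0, 12), 12.5),
    mk_obs(add_months(d0, 24), 15)
  )
  expect_equal(compute_growth_rate(tri), 5, tolerance = 0.01)
  # on a collinear series the first-vs-last rule equals the regression slope
  expect_equal(
    compute_growth_rate(tri),
    ls_growth_oracle(tri$observation_date, tri$leading_cyst_size),
    tolerance = 1e-6
  )
})

test_that("growth is undefined (NA, never 0) without two sizes in the window", {
  single <- mk_obs("2018-01-01", 10)
  expect_true(is.na(compute_growth_rate(single)))
  # earlier scans outside the trailing 24-month window do not anchor growth
  d0 <- as.Date("2012-01-01")
  far <- rbind(mk_obs(d0, 10), mk_obs(add_months(d0, 60), 18))
  expect_true(is.na(compute_growth_rate(far)))
  # but a scan inside the window does, measured from the window-interior scan
  d1 <- as.Date("2014-01-01")
  mixed <- rbind(
    mk_obs(d1, 10),
    mk_obs(add_months(d1, 40), 11),
    mk_obs(add_months(d1, 58), 14)
  )
  expect_equal(compute_growth_rate(mixed), (14 - 11) / 18 * 24, tolerance = 0.01)
  unordered <- rbind(mk_obs("2018-06-01", 10), mk_obs("2018-01-01", 12))
  expect_error(compute_growth_rate(unordered), "strictly increasing")
})

test_that("threshold boundaries follow the printed definitions", {
  # main duct exactly 10 mm is a high-risk stigma (inclusive)
  fa <- assess_features(mk_patient(size = 12, mpd_diameter = 10), policy = pol)
  expect_true("mpd_ge_10mm" %in% fa$high_risk_stigmata)
  # 30 mm cyst + 7 mm duct + 4 mm non-enhancing nodule = exactly 3 WFs
  fa2 <- assess_features(
    mk_patient(size = 30, mpd_diameter = 7, mural_nodule_size = 4,
               mural_nodule_enhancing = FALSE),
    policy = pol
  )
  expect_setequal(fa2$worrisome_features,
                  c("cyst_ge_30mm", "mpd_5_to_9mm", "nodule_lt_5mm"))
  expect_identical(fa2$wf_count, 3L)
  expect_length(fa2$high_risk_stigmata, 0)
  # all quiet
  fa3 <- assess_features(mk_patient(size = 10, mpd_diameter = 3, ca19_9 = 12),
                         policy = pol)
  expect_length(fa3$high_risk_stigmata, 0)
  expect_identical(fa3$wf_count, 0L)
  # growth of exactly 5 mm / 2 years does NOT trigger the strict > rule
  d0 <- as.Date("2018-01-01")
  p5 <- patient_record(
    "g", 70, "male",
    observations = rbind(mk_obs(d0, 10), mk_obs(d0 + 731, 15)),
    radiological_followup_months = 36, clinical_followup_months = 36
  )
  fa4 <- assess_features(p5, at = d0 + 731, policy = pol)
  expect_false("growth_gt_5mm_per_2y" %in% fa4$worrisome_features)
  p6 <- patient_record(
    "g2", 70, "male",
    observations = rbind(mk_obs(d0, 10), mk_obs(d0 + 731, 15.2)),
    radiological_followup_months = 36, clinical_followup_months = 36
  )
  fa5 <- assess_features(p6, at = d0 + 731, policy = pol)
  expect_true("growth_gt_5mm_per_2y" %in% fa5$worrisome_features)
})

test_that("missing optional measurements mean feature absent, with a note", {
  p <- mk_patient(size = 12)   # no MPD, no CA 19-9
  fa <- assess_features(p, policy = pol)
  expect_length(fa$high_risk_stigmata, 0)
  expect_identical(fa$wf_count, 0L)
  expect_true(any(grepl("mpd_diameter missing", fa$notes)))
  expect_true(any(grepl("ca19_9 missing", fa$notes)))
})

test_that("mutual-exclusion invariants hold across random feature states", {
  set.seed(101)
  for (i in 1:150) {
    p <- mk_patient(
      size = runif(1, 3, 45),
      mpd_diameter = if (runif(1) < 0.8) runif(1, 0, 14) else NA,
      mural_nodule_size = if (runif(1) < 0.5) runif(1, 1, 9) else NA,
      mural_nodule_enhancing = runif(1) < 0.5,
      ca19_9 = if (runif(1) < 0.7) runif(1, 1, 120) else NA,
      wall_thickened = runif(1) < 0.2,
      lymphadenopathy = runif(1) < 0.2
    )
    fa <- assess_features(p, policy = pol)
    expect_identical(fa$wf_count, length(fa$worrisome_features))
    expect_false(all(c("mpd_ge_10mm", "mpd_5_to_9mm") %in%
                     c(fa$high_risk_stigmata, fa$worrisome_features)))
    expect_false("enhancing_nodule_ge_5mm" %in% fa$high_risk_stigmata &&
                 "nodule_lt_5mm" %in% fa$worrisome_features)
    expect_false(anyDuplicated(fa$worrisome_features) > 0)
  }
})

test_that("recommendation precedence is HRS > WF > size band", {
  # enhancing 6 mm nodule, fit patient -> surgery referral
  r1 <- recommend(mk_patient(size = 15, mural_nodule_size = 6,
                             mural_nodule_enhancing = TRUE), policy = pol)
  expect_identical(r1$action, "surgery_referral")
  expect_true(is.na(r1$interval_months))
  # same stigma, unfit patient -> EUS surveillance at the unfit interval
  r2 <- recommend(mk_patient(size = 15, mural_nodule_size = 6,
                             mural_nodule_enhancing = TRUE, fit = FALSE),
                  policy = pol)
  expect_identical(r2$action, "eus_surveillance")
  expect_equal(r2$interval_months, pol$unfit_rule$interval_months)
  # a single WF -> EUS at the WF-tier interval
  r3 <- recommend(mk_patient(size = 15, wall_thickened = TRUE), policy = pol)
  expect_identical(r3$action, "eus_surveillance")
  expect_equal(r3$interval_months, pol$wf_rules$interval_months[1])
  # no WF/HRS, 10 mm cyst at index -> first-visit MRI interval of the <20 band
  r4 <- recommend(mk_patient(size = 10), policy = pol)
  expect_identical(r4$action, "imaging_surveillance")
  expect_identical(r4$modality, "mri_mrcp")
  expect_equal(r4$interval_months, pol$size_bands$interval_months[1])
  # obstructive jaundice alone is an HRS
  r5 <- recommend(mk_patient(size = 8, obstructive_jaundice = TRUE), policy = pol)
  expect_identical(r5$action, "surgery_referral")
})

test_that("a stable cyst graduates to the band's stable interval", {
  d0 <- as.Date("2018-01-01")
  p <- patient_record(
    "s", 70, "male",
    observations = rbind(mk_obs(d0, 10), mk_obs(add_months(d0, 6), 10.2)),
    radiological_followup_months = 60, clinical_followup_months = 60
  )
  r_idx <- recommend(p, at = d0, policy = pol)
  expect_equal(r_idx$interval_months, 6)
  r_later <- recommend(p, at = add_months(d0, 6), policy = pol)
  expect_equal(r_later$interval_months, 18)
  # the 20-29 mm band has its own stable interval
  p2 <- patient_record(
    "s2", 70, "male",
    observations = rbind(mk_obs(d0, 24), mk_obs(add_months(d0, 6), 24.3)),
    radiological_followup_months = 60, clinical_followup_months = 60
  )
  expect_equal(recommend(p2, at = add_months(d0, 6), policy = pol)$interval_months, 12)
})

test_that("recommendations are deterministic with a bitwise-stable rationale", {
  p <- mk_patient(size = 24, mpd_diameter = 6, ca19_9 = 80)
  r1 <- recommend(p, policy = pol)
  r2 <- recommend(p, policy = pol)
  expect_identical(r1, r2)
  expect_match(r1$rationale[1], "^policy:")
})

test_that("boolean findings count regardless of which cyst carried them", {
  p <- mk_patient(size = 12, n_cysts = 3, lymphadenopathy = TRUE)
  fa <- assess_features(p, policy = pol)
  expect_true("lymphadenopathy" %in% fa$worrisome_features)
  r <- recommend(p, policy = pol)
  expect_identical(r$action, "eus_surveillance")
})

test_that("asking for a recommendation before any observation is an error", {
  p <- mk_patient(date = "2019-06-01")
  expect_error(recommend(p, at = "2019-01-01", policy = pol), "no observation")
})
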