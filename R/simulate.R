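# Synthetic retrospective cohorts: longitudinal SB-IPMN surveillance data
# with the marginal structure of the study population (age, sex, cyst
# size, follow-up, comorbidity prevalences) and a configurable behavior
# model that realizes actual management as concordant with, more intensive
# than, or less intensive than the policy recommendation. Because no
# patient-level data are deposited, these cohorts are the test bed for the
# engine, the auditor and the statistics.
#
# Right-skewed quantities (cyst size, follow-up durations) are log-normal
# with parameters matched to the target median and IQR: meanlog =
# log(median), sdlog = (log(q3) - log(q1)) / (2 * qnorm(0.75)). Age is
# normal matched the same way, truncated to adulthood, with an adjustable
# point mass below 50 to exercise the under-50 subgroup.

lnorm_from_quartiles <- function(median, q1, q3) {
  list(meanlog = log(median), sdlog = (log(q3) - log(q1)) / (2 * qnorm(0.75)))
}

#' Behavior model for actual management
#'
#' Each patient draws a latent management class from the base
#' probabilities, shifted on the log-odds scale by covariate modifiers
#' (younger patients toward over-surveillance, larger cysts toward
#' concordance). The realized surveillance schedule then multiplies every
#' recommended interval by a class-specific factor: well inside the audit
#' tolerance for concordant patients, well below it for over-surveilled,
#' well above for under-surveilled.
#'
#' @param p_concordant,p_over,p_under Base class probabilities; must sum
#'   to 1.
#' @param age_lt50_to_over Log-odds shift toward `over` for patients under
#'   50 (default `log(1.61)`).
#' @param cyst_gt20_to_concordant Log-odds shift toward `concordant` for
#'   cysts over 20 mm (default `log(2.1)`).
#' @param concordant_frac,over_frac,under_frac Ranges (length-2) of the
#'   per-visit interval multiplier for each class.
#' @param p_under_no_event Probability that an under-surveilled patient has
#'   no follow-up imaging at all.
#' @return An object of class `behavior_spec`.
#' @export
behavior_spec <- function(p_concordant = 0.158,
                          p_over = 0.603,
                          p_under = 0.239,
                          age_lt50_to_over = log(1.61),
                          cyst_gt20_to_concordant = log(2.1),
                          concordant_frac = c(0.95, 1.05),
                          over_frac = c(0.25, 0.45),
                          under_frac = c(1.6, 2.6),
                          p_under_no_event = 0.15) {
  p <- c(concordant = p_concordant, over = p_over, under = p_under)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("base class probabilities must be non-negative and sum to 1")
  }
  structure(
    list(
      base = p,
      age_lt50_to_over = age_lt50_to_over,
      cyst_gt20_to_concordant = cyst_gt20_to_concordant,
      frac = list(concordant = concordant_frac, over = over_frac,
                  under = under_frac),
      p_under_no_event = p_under_no_event
    ),
    class = "behavior_spec"
  )
}

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the study conditions: 368 patients, median age 69.5
#' (IQR 63.2-75.2) with 69% male and a 19/368 point mass under 50;
#' leading cyst size median 10 mm (IQR 6-14), 10.5% with multiple cysts;
#' radiological follow-up median 48.5 months (IQR 28-75), clinical median
#' 64 (IQR 46-88); comorbidity prevalences pooled from the published
#' per-group percentages; PDAC hazard 0.0006 per patient-year (the
#' 0.06%-per-patient-year regime). Worrisome-feature onset hazards are
#' deliberately low so the cohort is dominated by stable low-risk cysts.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; the generator derives one substream per
#'   patient from it, so cohorts are bitwise-reproducible and extending
#'   `n_patients` does not perturb earlier patients.
#' @param age Target list (median, q1, q3, min).
#' @param p_male Male fraction.
#' @param p_age_lt50 Point mass of patients aged under 50.
#' @param cyst_size,followup_rad,followup_clin Target (median, q1, q3)
#'   lists for the log-normal families.
#' @param p_multiple_cysts Probability of >1 cyst at baseline.
#' @param comorbidity_prev Named prevalence vector over the comorbidity
#'   set.
#' @param baseline_feature_prob Per-feature probability of a boolean
#'   worrisome finding at the index scan.
#' @param p_nodule,p_nodule_enhancing Baseline mural-nodule parameters.
#' @param p_jaundice Baseline obstructive-jaundice probability.
#' @param p_ca19_9_measured Probability CA 19-9 was measured.
#' @param wf_hazard,hrs_hazard Onset hazards per patient-year for new
#'   worrisome features / high-risk stigmata during follow-up.
#' @param growth Growth model list: per-patient `drift_mean`/`drift_sd`
#'   (mm/year) and measurement `noise_sd` (mm).
#' @param behavior A [behavior_spec()].
#' @param pdac_hazard PDAC hazard per patient-year.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 368,
                        seed = 1,
                        age = list(median = 69.5, q1 = 63.2, q3 = 75.2, min = 18),
                        p_male = 0.69,
                        p_age_lt50 = 19 / 368,
                        cyst_size = list(median = 10, q1 = 6, q3 = 14),
                        p_multiple_cysts = 0.105,
                        followup_rad = list(median = 48.5, q1 = 28, q3 = 75),
                        followup_clin = list(median = 64, q1 = 46, q3 = 88),
                        comorbidity_prev = c(
                          diabetes_or_ifg = 0.296, smoker = 0.158,
                          alcohol = 0.011, pancreatitis_history = 0.054,
                          liver_biliary_disease = 0.252,
                          family_history_pancreatitis = 0.044,
                          non_gi_malignancy = 0.288, gi_malignancy = 0.041,
                          cholelithiasis_ccy = 0.255, psc = 0.013,
                          pancreas_divisum = 0.071, chronic_pancreatitis = 0.011
                        ),
                        baseline_feature_prob = 0.005,
                        p_nodule = 0.02,
                        p_nodule_enhancing = 0.3,
                        p_jaundice = 0.002,
                        p_ca19_9_measured = 0.7,
                        wf_hazard = 0.005,
                        hrs_hazard = 0.001,
                        growth = list(drift_mean = 0.2, drift_sd = 0.4, noise_sd = 0.5),
                        behavior = behavior_spec(),
                        pdac_hazard = 0.0006) {
  probs <- c(p_male, p_age_lt50, p_multiple_cysts, baseline_feature_prob,
             p_nodule, p_nodule_enhancing, p_jaundice, p_ca19_9_measured,
             unname(comorbidity_prev))
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (wf_hazard < 0 || hrs_hazard < 0 || pdac_hazard < 0) {
    stop("hazards must be >= 0")
  }
  missing_cm <- setdiff(COMORBIDITIES, names(comorbidity_prev))
  if (length(missing_cm)) {
    stop("comorbidity_prev missing: ", paste(missing_cm, collapse = ", "))
  }
  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      age = age, p_male = p_male, p_age_lt50 = p_age_lt50,
      cyst_size = cyst_size, p_multiple_cysts = p_multiple_cysts,
      followup_rad = followup_rad, followup_clin = followup_clin,
      comorbidity_prev = comorbidity_prev,
      baseline_feature_prob = baseline_feature_prob,
      p_nodule = p_nodule, p_nodule_enhancing = p_nodule_enhancing,
      p_jaundice = p_jaundice, p_ca19_9_measured = p_ca19_9_measured,
      wf_hazard = wf_hazard, hrs_hazard = hrs_hazard,
      growth = growth, behavior = behavior, pdac_hazard = pdac_hazard
    ),
    class = "cohort_spec"
  )
}

# One RNG substream per patient: deterministic in (seed, i) and independent
# of n_patients, so extending a cohort never perturbs earlier patients.
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483629 + 1)
}

sample_class <- function(behavior, age, cyst_size) {
  logits <- log(behavior$base)
  if (age < 50) logits["over"] <- logits["over"] + behavior$age_lt50_to_over
  if (cyst_size > 20) {
    logits["concordant"] <- logits["concordant"] + behavior$cyst_gt20_to_concordant
  }
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  sample(names(p), 1, prob = p)
}

runif_range <- function(range) runif(1, range[1], range[2])

# Advance the boolean feature state of the previous observation by dt
# months: each worrisome finding switches on (and stays on) with the
# per-patient-year hazard; high-risk stigmata onset realizes as
# obstructive jaundice.
advance_features <- function(prev, dt_months, wf_hazard, hrs_hazard) {
  p_wf <- 1 - exp(-wf_hazard * dt_months / 12)
  p_hrs <- 1 - exp(-hrs_hazard * dt_months / 12)
  flip <- function(x, p) isTRUE(x) || runif(1) < p
  list(
    wall_thickened = flip(prev$wall_thickened, p_wf),
    abrupt_duct_change = flip(prev$abrupt_duct_change, p_wf),
    lymphadenopathy = flip(prev$lymphadenopathy, p_wf),
    acute_pancreatitis_episode = flip(prev$acute_pancreatitis_episode, p_wf),
    new_onset_diabetes = flip(prev$new_onset_diabetes, p_wf),
    obstructive_jaundice = flip(prev$obstructive_jaundice, p_hrs)
  )
}

.sim_patient <- function(i, spec, policy) {
  set.seed(patient_seed(spec$seed, i))
  beh <- spec$behavior

  sex <- if (runif(1) < spec$p_male) "male" else "female"
  age <- if (runif(1) < spec$p_age_lt50) {
    runif(1, 40, 49.9)
  } else {
    sd_age <- (spec$age$q3 - spec$age$q1) / (2 * qnorm(0.75))
    repeat {
      a <- rnorm(1, spec$age$median, sd_age)
      if (a >= max(50, spec$age$min)) break
    }
    a
  }
  limited <- runif(1) < 0.03
  fit <- !limited && runif(1) > 0.02
  comorb <- names(spec$comorbidity_prev)[
    runif(length(spec$comorbidity_prev)) < spec$comorbidity_prev
  ]

  idx_date <- as.Date("2007-01-01") + floor(runif(1, 0, 4748))
  sz <- lnorm_from_quartiles(spec$cyst_size$median, spec$cyst_size$q1,
                             spec$cyst_size$q3)
  size0 <- min(max(rlnorm(1, sz$meanlog, sz$sdlog), 2), 80)
  n_cysts <- if (runif(1) < spec$p_multiple_cysts) sample(2:4, 1) else 1L

  fr <- lnorm_from_quartiles(spec$followup_rad$median, spec$followup_rad$q1,
                             spec$followup_rad$q3)
  rad_fu <- min(max(rlnorm(1, fr$meanlog, fr$sdlog), 3), 204)
  fc <- lnorm_from_quartiles(spec$followup_clin$median, spec$followup_clin$q1,
                             spec$followup_clin$q3)
  clin_fu <- max(rad_fu, min(max(rlnorm(1, fc$meanlog, fc$sdlog), 3), 240))

  bp <- spec$baseline_feature_prob
  has_nodule <- runif(1) < spec$p_nodule
  feat <- list(
    wall_thickened = runif(1) < bp,
    abrupt_duct_change = runif(1) < bp,
    lymphadenopathy = runif(1) < bp,
    acute_pancreatitis_episode = runif(1) < bp,
    new_onset_diabetes = runif(1) < bp,
    obstructive_jaundice = runif(1) < spec$p_jaundice
  )
  mpd <- rlnorm(1, log(2.5), 0.35)
  ca <- if (runif(1) < spec$p_ca19_9_measured) rlnorm(1, log(12), 0.6) else NA_real_
  drift <- rnorm(1, spec$growth$drift_mean, spec$growth$drift_sd)

  nodule_size <- if (has_nodule) min(max(rlnorm(1, log(3), 0.5), 1), 12) else NA_real_
  nodule_enh <- if (has_nodule) runif(1) < spec$p_nodule_enhancing else NA

  # observation columns accumulated as plain vectors (hot loop)
  ob <- list(
    observation_date = add_months(idx_date, 0),
    leading_cyst_size = size0,
    n_cysts = n_cysts,
    mpd_diameter = mpd,
    mural_nodule_size = nodule_size,
    mural_nodule_enhancing = nodule_enh,
    wall_thickened = feat$wall_thickened,
    abrupt_duct_change = feat$abrupt_duct_change,
    lymphadenopathy = feat$lymphadenopathy,
    obstructive_jaundice = feat$obstructive_jaundice,
    ca19_9 = ca,
    acute_pancreatitis_episode = feat$acute_pancreatitis_episode,
    new_onset_diabetes = feat$new_onset_diabetes,
    modality = "mri_mrcp"
  )
  append_obs <- function(t_months, size, feat, modality) {
    d <- add_months(idx_date, t_months)
    if (d <= ob$observation_date[length(ob$observation_date)]) {
      return(FALSE)  # guard against same-day duplicates from tiny intervals
    }
    ob$observation_date <<- c(ob$observation_date, d)
    ob$leading_cyst_size <<- c(ob$leading_cyst_size, size)
    ob$n_cysts <<- c(ob$n_cysts, n_cysts)
    ob$mpd_diameter <<- c(ob$mpd_diameter, mpd)
    ob$mural_nodule_size <<- c(ob$mural_nodule_size, nodule_size)
    ob$mural_nodule_enhancing <<- c(ob$mural_nodule_enhancing, nodule_enh)
    ob$wall_thickened <<- c(ob$wall_thickened, feat$wall_thickened)
    ob$abrupt_duct_change <<- c(ob$abrupt_duct_change, feat$abrupt_duct_change)
    ob$lymphadenopathy <<- c(ob$lymphadenopathy, feat$lymphadenopathy)
    ob$obstructive_jaundice <<- c(ob$obstructive_jaundice, feat$obstructive_jaundice)
    ob$ca19_9 <<- c(ob$ca19_9, ca)
    ob$acute_pancreatitis_episode <<- c(ob$acute_pancreatitis_episode,
                                        feat$acute_pancreatitis_episode)
    ob$new_onset_diabetes <<- c(ob$new_onset_diabetes, feat$new_onset_diabetes)
    ob$modality <<- c(ob$modality, modality)
    TRUE
  }

  true_class <- sample_class(beh, age, size0)
  pid <- sprintf("sim%05d", i)
  patient_so_far <- function() {
    list(patient_id = pid, observations = ob,
         surgically_fit = fit, limited_life_expectancy = limited)
  }
  rec0 <- .recommend_core(patient_so_far(), idx_date, policy)

  ev_t <- numeric()
  ev_type <- character()
  add_event <- function(t_months, type) {
    ev_t <<- c(ev_t, t_months)
    ev_type <<- c(ev_type, type)
  }

  if (rec0$action == "surgery_referral") {
    # more-intensive-than-surgery does not exist; an over draw realizes as
    # timely surgery and the truth label records the realized class
    if (true_class == "over") true_class <- "concordant"
    if (true_class == "concordant") {
      t_ref <- runif(1, 0.5, 2)
      add_event(t_ref, "surgery_referral")
      add_event(t_ref + runif(1, 1, 3), "surgery_performed")
    } else {
      add_event(runif(1, 6, 18), "imaging_mri_mrcp")
    }
  } else {
    skip_all <- true_class == "under" && runif(1) < beh$p_under_no_event
    if (!skip_all) {
      t <- 0
      for (visit in 1:100) {
        core <- .recommend_core(patient_so_far(), add_months(idx_date, t), policy)
        if (core$action == "surgery_referral") {
          if (true_class == "concordant") add_event(t + 1, "surgery_referral")
          break
        }
        m <- runif_range(beh$frac[[true_class]])
        t_next <- t + core$interval_months * m
        if (t_next > rad_fu + 1e-9) break
        add_event(t_next, paste0("imaging_", core$modality))
        feat <- advance_features(feat, t_next - t, spec$wf_hazard, spec$hrs_hazard)
        size_t <- max(1, size0 + drift * t_next / 12 +
                        rnorm(1, 0, spec$growth$noise_sd))
        append_obs(t_next, size_t, feat, core$modality)
        t <- t_next
      }
    }
  }

  events <- if (length(ev_t)) {
    data.frame(event_date = add_months(idx_date, 0) + round(ev_t * DAYS_PER_MONTH),
               event_type = ev_type, stringsAsFactors = FALSE)
  } else {
    empty_events()
  }

  t_pdac <- rexp(1, max(spec$pdac_hazard, 1e-12)) * 12
  pdac <- spec$pdac_hazard > 0 && t_pdac <= rad_fu
  obs <- as.data.frame(ob, stringsAsFactors = FALSE)
  p <- structure(
    list(
      patient_id = pid,
      age_at_index = age,
      sex = sex,
      surgically_fit = fit,
      limited_life_expectancy = limited,
      comorbidities = comorb,
      observations = obs,
      management_events = events,
      outcome_pdac = pdac,
      outcome_pdac_date = if (pdac) add_months(idx_date, t_pdac) else as.Date(NA),
      clinical_followup_months = clin_fu,
      radiological_followup_months = rad_fu
    ),
    class = "patient_record"
  )
  list(patient = p, true_class = true_class)
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @param policy The `decision_policy` the behavior model follows (or
#'   deviates from); default [default_policy()].
#' @return A validated [ipmn_cohort()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 20, seed = 7))
#' cohort
generate_cohort <- function(spec = cohort_spec(), policy = default_policy()) {
  generate_cohort_with_truth(spec, policy)$cohort
}

#' Generate a synthetic cohort together with its latent truth
#'
#' Identical to [generate_cohort()] but also returns, per patient, the
#' management class the behavior model actually realized, so the auditor's
#' classification can be scored against ground truth.
#'
#' @inheritParams generate_cohort
#' @return A list with `cohort` (an [ipmn_cohort()]) and `truth` (tibble
#'   of `patient_id`, `true_class`).
#' @export
generate_cohort_with_truth <- function(spec = cohort_spec(),
                                       policy = default_policy()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  sims <- lapply(seq_len(spec$n_patients), .sim_patient, spec = spec,
                 policy = policy)
  patients <- lapply(sims, `[[`, "patient")
  truth <- tibble(
    patient_id = vapply(patients, `[[`, character(1), "patient_id"),
    true_class = vapply(sims, `[[`, character(1), "true_class")
  )
  cohort <- ipmn_cohort(
    patients,
    provenance = sprintf("synthetic cohort (n=%d, seed=%d)",
                         spec$n_patients, spec$seed)
  )
  problems <- validate_cohort(cohort)
  if (nrow(problems)) {
    stop("generated cohort failed validation: ",
         paste(unique(problems$problem), collapse = "; "))
  }
  list(cohort = cohort, truth = truth)
}
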