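# Builders for small hand-made patients used across test files.

mk_obs <- function(date, size, ...) {
  cyst_observation(observation_date = date, leading_cyst_size = size, ...)
}

# single-observation patient with sensible defaults
mk_patient <- function(id = "p1", size = 10, date = "2018-01-01",
                       age = 70, sex = "male", fit = TRUE,
                       rad_fu = 60, clin_fu = 60, events = empty_events_df(),
                       ...) {
  patient_record(
    id, age, sex,
    observations = mk_obs(date, size, ...),
    management_events = events,
    surgically_fit = fit,
    radiological_followup_months = rad_fu,
    clinical_followup_months = clin_fu
  )
}

empty_events_df <- function() {
  data.frame(
    event_date = as.Date(character()),
    event_type = character(),
    stringsAsFactors = FALSE
  )
}

# a patient whose index state is described by explicit feature arguments,
# with a baseline scan `window` months earlier so growth is defined:
# delta mm of growth over the window (rate = delta / window * 24)
mk_grid_patient <- function(size, mpd = NA, nodule_size = NA, nodule_enh = NA,
                            wall = FALSE, abrupt = FALSE, lymph = FALSE,
                            jaundice = FALSE, ca = NA, delta = 0,
                            pancreatitis = FALSE, diabetes = FALSE,
                            fit = TRUE, window = 12) {
  d0 <- as.Date("2018-01-01")
  d1 <- add_months(d0, window)
  obs <- rbind(
    cyst_observation(d0, max(size - delta, 1)),
    cyst_observation(
      d1, size,
      mpd_diameter = mpd,
      mural_nodule_size = nodule_size,
      mural_nodule_enhancing = nodule_enh,
      wall_thickened = wall,
      abrupt_duct_change = abrupt,
      lymphadenopathy = lymph,
      obstructive_jaundice = jaundice,
      ca19_9 = ca,
      acute_pancreatitis_episode = pancreatitis,
      new_onset_diabetes = diabetes
    )
  )
  list(
    patient = patient_record(
      "grid", 70, "male", observations = obs, surgically_fit = fit,
      radiological_followup_months = 60, clinical_followup_months = 60
    ),
    at = d1
  )
}

# a recommendation object built directly (classification takes the
# recommendation as an argument, so tests can pin its interval)
mk_recommendation <- function(action, modality = "mri_mrcp",
                              interval = NA_real_) {
  structure(
    list(action = action, modality = modality, interval_months = interval,
         rationale = "test", assessment = NULL),
    class = "recommendation"
  )
}

# an audit-shaped object carrying externally assigned classes, for testing
# the statistics layer against known group structure
mk_audit_classes <- function(patient_ids, classes) {
  list(results = tibble::tibble(patient_id = patient_ids, class = classes))
}
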