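# Domain types: cyst observations, management events, patient records, and
# cohorts. All enums are lower_snake_case strings; dates are `Date`.

OBS_MODALITIES <- c("mri_mrcp", "eus", "ct")

EVENT_TYPES <- c(
  "imaging_mri_mrcp", "imaging_eus", "imaging_ct",
  "surgery_referral", "surgery_performed", "surveillance_stopped"
)

COMORBIDITIES <- c(
  "diabetes_or_ifg", "smoker", "alcohol", "pancreatitis_history",
  "liver_biliary_disease", "family_history_pancreatitis",
  "non_gi_malignancy", "gi_malignancy", "cholelithiasis_ccy",
  "psc", "pancreas_divisum", "chronic_pancreatitis"
)

# Column order for observation tables; also the serialization order.
OBS_COLUMNS <- c(
  "observation_date", "leading_cyst_size", "n_cysts", "mpd_diameter",
  "mural_nodule_size", "mural_nodule_enhancing", "wall_thickened",
  "abrupt_duct_change", "lymphadenopathy", "obstructive_jaundice",
  "ca19_9", "acute_pancreatitis_episode", "new_onset_diabetes", "modality"
)

#' One dated imaging assessment of cyst and duct features
#'
#' Builds a single-row observation data frame holding the feature values
#' extracted from one imaging report. Optional measurements
#' (`mpd_diameter`, `mural_nodule_size`, `mural_nodule_enhancing`,
#' `ca19_9`) may be `NA`, which downstream feature detection interprets as
#' "feature not demonstrated".
#'
#' @param observation_date Calendar date of the scan (`Date` or ISO-8601
#'   string).
#' @param leading_cyst_size Diameter of the leading (largest) cyst, mm; > 0.
#' @param n_cysts Number of cysts seen; >= 1.
#' @param mpd_diameter Main pancreatic duct diameter, mm, or `NA`.
#' @param mural_nodule_size Mural nodule diameter, mm; `NA` means no nodule.
#' @param mural_nodule_enhancing Logical; whether the nodule enhances with
#'   contrast (`NA` when no nodule or not reported).
#' @param wall_thickened,abrupt_duct_change,lymphadenopathy,obstructive_jaundice
#'   Logical report findings.
#' @param ca19_9 Serum CA 19-9, U/mL, or `NA`.
#' @param acute_pancreatitis_episode,new_onset_diabetes Logical clinical
#'   findings attributed to the cyst.
#' @param modality One of `"mri_mrcp"`, `"eus"`, `"ct"`.
#' @return A one-row data frame with the canonical observation columns.
#' @export
#' @examples
#' cyst_observation("2020-03-01", leading_cyst_size = 12)
cyst_observation <- function(observation_date,
                             leading_cyst_size,
                             n_cysts = 1L,
                             mpd_diameter = NA_real_,
                             mural_nodule_size = NA_real_,
                             mural_nodule_enhancing = NA,
                             wall_thickened = FALSE,
                             abrupt_duct_change = FALSE,
                             lymphadenopathy = FALSE,
                             obstructive_jaundice = FALSE,
                             ca19_9 = NA_real_,
                             acute_pancreatitis_episode = FALSE,
                             new_onset_diabetes = FALSE,
                             modality = "mri_mrcp") {
  obs <- data.frame(
    observation_date = as.Date(observation_date),
    leading_cyst_size = as.numeric(leading_cyst_size),
    n_cysts = as.integer(n_cysts),
    mpd_diameter = as.numeric(mpd_diameter),
    mural_nodule_size = as.numeric(mural_nodule_size),
    mural_nodule_enhancing = as.logical(mural_nodule_enhancing),
    wall_thickened = as.logical(wall_thickened),
    abrupt_duct_change = as.logical(abrupt_duct_change),
    lymphadenopathy = as.logical(lymphadenopathy),
    obstructive_jaundice = as.logical(obstructive_jaundice),
    ca19_9 = as.numeric(ca19_9),
    acute_pancreatitis_episode = as.logical(acute_pancreatitis_episode),
    new_onset_diabetes = as.logical(new_onset_diabetes),
    modality = as.character(modality),
    stringsAsFactors = FALSE
  )
  problems <- validate_observations(obs)
  if (length(problems)) {
    stop("invalid observation: ", paste(problems, collapse = "; "))
  }
  obs
}

#' One management event
#'
#' @param event_date Calendar date (`Date` or ISO-8601 string).
#' @param event_type One of `"imaging_mri_mrcp"`, `"imaging_eus"`,
#'   `"imaging_ct"`, `"surgery_referral"`, `"surgery_performed"`,
#'   `"surveillance_stopped"`.
#' @return A one-row data frame.
#' @export
management_event <- function(event_date, event_type) {
  event_type <- as.character(event_type)
  if (!all(event_type %in% EVENT_TYPES)) {
    stop("invalid event_type: ", paste(setdiff(event_type, EVENT_TYPES), collapse = ", "))
  }
  data.frame(
    event_date = as.Date(event_date),
    event_type = event_type,
    stringsAsFactors = FALSE
  )
}

empty_events <- function() {
  data.frame(
    event_date = as.Date(character()),
    event_type = character(),
    stringsAsFactors = FALSE
  )
}

#' A patient record: demographics, observation series, management events
#'
#' @param patient_id Opaque identifier string.
#' @param age_at_index Age in years at the index scan; >= 18.
#' @param sex `"male"` or `"female"`.
#' @param observations Data frame of observations (rows built with
#'   [cyst_observation()] and combined with `rbind`), strictly increasing
#'   dates; the first row must have modality `"mri_mrcp"` (the index scan).
#' @param management_events Data frame of events ([management_event()]),
#'   non-decreasing dates. May be empty.
#' @param surgically_fit Logical; surgical candidate.
#' @param limited_life_expectancy Logical.
#' @param comorbidities Character vector drawn from the recognised
#'   comorbidity set (see `ipmnaudit:::COMORBIDITIES`).
#' @param outcome_pdac Logical; pancreatic ductal adenocarcinoma during
#'   follow-up.
#' @param outcome_pdac_date Diagnosis date or `NA`.
#' @param clinical_followup_months,radiological_followup_months Follow-up
#'   durations in months; independent clocks, both >= 0.
#' @return An object of class `patient_record`.
#' @export
#' @examples
#' p <- patient_record(
#'   "p1", age_at_index = 70, sex = "male",
#'   observations = cyst_observation("2018-01-01", 12),
#'   radiological_followup_months = 36, clinical_followup_months = 48
#' )
patient_record <- function(patient_id,
                           age_at_index,
                           sex,
                           observations,
                           management_events = empty_events(),
                           surgically_fit = TRUE,
                           limited_life_expectancy = FALSE,
                           comorbidities = character(),
                           outcome_pdac = FALSE,
                           outcome_pdac_date = as.Date(NA),
                           clinical_followup_months = 0,
                           radiological_followup_months = 0) {
  p <- structure(
    list(
      patient_id = as.character(patient_id),
      age_at_index = as.numeric(age_at_index),
      sex = as.character(sex),
      surgically_fit = as.logical(surgically_fit),
      limited_life_expectancy = as.logical(limited_life_expectancy),
      comorbidities = as.character(comorbidities),
      observations = observations,
      management_events = management_events,
      outcome_pdac = as.logical(outcome_pdac),
      outcome_pdac_date = as.Date(outcome_pdac_date),
      clinical_followup_months = as.numeric(clinical_followup_months),
      radiological_followup_months = as.numeric(radiological_followup_months)
    ),
    class = "patient_record"
  )
  problems <- validate_patient(p)
  if (length(problems)) {
    stop(
      "invalid patient record '", patient_id, "': ",
      paste(problems, collapse = "; ")
    )
  }
  p
}

#' @export
print.patient_record <- function(x, ...) {
  cat(
    "<patient_record ", x$patient_id, "> ", x$sex, ", age ",
    format(x$age_at_index, digits = 4), "; ",
    nrow(x$observations), " observation(s), ",
    nrow(x$management_events), " event(s); radiological follow-up ",
    format(x$radiological_followup_months, digits = 4), " months\n",
    sep = ""
  )
  invisible(x)
}

validate_observations <- function(obs) {
  problems <- character()
  if (!nrow(obs)) {
    return("at least one observation is required")
  }
  if (anyNA(obs$observation_date)) {
    problems <- c(problems, "observation_date missing or unparseable")
  }
  bad_size <- !is.na(obs$leading_cyst_size) & obs$leading_cyst_size <= 0
  if (anyNA(obs$leading_cyst_size) || any(bad_size)) {
    problems <- c(problems, "leading_cyst_size must be present and > 0")
  }
  if (anyNA(obs$n_cysts) || any(obs$n_cysts < 1)) {
    problems <- c(problems, "n_cysts must be >= 1")
  }
  if (any(!is.na(obs$mpd_diameter) & obs$mpd_diameter < 0)) {
    problems <- c(problems, "mpd_diameter must be >= 0 when present")
  }
  if (any(!is.na(obs$mural_nodule_size) & obs$mural_nodule_size <= 0)) {
    problems <- c(problems, "mural_nodule_size must be > 0 when present")
  }
  if (!all(obs$modality %in% OBS_MODALITIES)) {
    problems <- c(problems, paste0(
      "modality must be one of ", paste(OBS_MODALITIES, collapse = "/")
    ))
  }
  if (nrow(obs) > 1 && !anyNA(obs$observation_date) &&
      any(diff(as.numeric(obs$observation_date)) <= 0)) {
    problems <- c(problems, "observation dates must be strictly increasing")
  }
  problems
}

#' Validate a patient record
#'
#' Checks every stated invariant of the record: adult age, valid enums,
#' strictly increasing observation dates, index scan by MRI/MRCP,
#' non-decreasing event dates, non-negative follow-up clocks.
#'
#' @param p A `patient_record` (or a bare list with the same fields).
#' @return Character vector of problems; empty when valid.
#' @export
validate_patient <- function(p) {
  problems <- character()
  if (is.na(p$age_at_index) || p$age_at_index < 18) {
    problems <- c(problems, "age_at_index must be >= 18")
  }
  if (!p$sex %in% c("male", "female")) {
    problems <- c(problems, "sex must be 'male' or 'female'")
  }
  unknown <- setdiff(p$comorbidities, COMORBIDITIES)
  if (length(unknown)) {
    problems <- c(problems, paste0(
      "unknown comorbidities: ", paste(unknown, collapse = ", ")
    ))
  }
  problems <- c(problems, validate_observations(p$observations))
  if (nrow(p$observations) && !anyNA(p$observations$modality) &&
      p$observations$modality[1] != "mri_mrcp") {
    problems <- c(problems, "first observation must be an MRI/MRCP index scan")
  }
  ev <- p$management_events
  if (nrow(ev)) {
    if (!all(ev$event_type %in% EVENT_TYPES)) {
      problems <- c(problems, "invalid event_type in management_events")
    }
    if (anyNA(ev$event_date)) {
      problems <- c(problems, "event_date missing or unparseable")
    } else if (nrow(ev) > 1 && any(diff(as.numeric(ev$event_date)) < 0)) {
      problems <- c(problems, "event dates must be non-decreasing")
    }
  }
  if (is.na(p$clinical_followup_months) || p$clinical_followup_months < 0) {
    problems <- c(problems, "clinical_followup_months must be >= 0")
  }
  if (is.na(p$radiological_followup_months) || p$radiological_followup_months < 0) {
    problems <- c(problems, "radiological_followup_months must be >= 0")
  }
  problems
}

#' A cohort of patient records
#'
#' @param patients List of [patient_record()] objects with unique ids.
#' @param provenance Free-text description of where the cohort came from.
#' @return An object of class `ipmn_cohort`.
#' @export
ipmn_cohort <- function(patients, provenance = "unspecified") {
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop(
      "duplicate patient ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  structure(
    list(patients = patients, provenance = provenance),
    class = "ipmn_cohort"
  )
}

#' @export
print.ipmn_cohort <- function(x, ...) {
  n_obs <- sum(vapply(x$patients, function(p) nrow(p$observations), integer(1)))
  cat(
    "<ipmn_cohort> ", length(x$patients), " patients, ", n_obs,
    " observations (", x$provenance, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
length.ipmn_cohort <- function(x) length(x$patients)

#' Validate every patient in a cohort
#'
#' @param cohort An `ipmn_cohort`.
#' @return A tibble with columns `patient_id` and `problem`; zero rows when
#'   the whole cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  rows <- lapply(cohort$patients, function(p) {
    problems <- validate_patient(p)
    if (!length(problems)) return(NULL)
    tibble(patient_id = p$patient_id, problem = problems)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(tibble(patient_id = character(), problem = character()))
  }
  do.call(rbind, rows)
}

index_date <- function(patient) patient$observations$observation_date[1]
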