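# Readers and writers for cohort tables.
#
# CSV layout is "long": one row per (patient_id, record_kind, date) with
# record_kind in {patient, observation, event}. Patient rows carry the
# demographic/outcome fields, observation rows the imaging fields, event
# rows the event_type; cells not applicable to a row kind are empty.
# JSON nests observations and events inside each patient object. Dates are
# ISO-8601; logicals are "true"/"false"; missing optionals are empty cells
# (never the strings "NA"/"NaN"/"None").

PATIENT_FIELDS <- c(
  "age_at_index", "sex", "surgically_fit", "limited_life_expectancy",
  "comorbidities", "outcome_pdac", "outcome_pdac_date",
  "clinical_followup_months", "radiological_followup_months"
)

CSV_COLUMNS <- c(
  "patient_id", "record_kind", "date", PATIENT_FIELDS,
  setdiff(OBS_COLUMNS, "observation_date"), "event_type"
)

fmt_cell <- function(x) {
  if (length(x) == 0 || is.na(x)) return("")
  if (is.logical(x)) return(if (x) "true" else "false")
  if (inherits(x, "Date")) return(format(x, "%Y-%m-%d"))
  as.character(x)
}

parse_logical_cell <- function(x) {
  if (x == "") return(NA)
  if (x %in% c("true", "TRUE", "True")) return(TRUE)
  if (x %in% c("false", "FALSE", "False")) return(FALSE)
  stop("not a logical: '", x, "'")
}

parse_numeric_cell <- function(x) {
  if (x == "") return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("not a number: '", x, "'")
  v
}

parse_date_cell <- function(x) {
  if (x == "") return(as.Date(NA))
  v <- as.Date(x, format = "%Y-%m-%d")
  if (is.na(v)) stop("not an ISO-8601 date: '", x, "'")
  v
}

#' Write a cohort to disk
#'
#' @param cohort An [ipmn_cohort()].
#' @param path Output file path.
#' @param format `"csv"` (long layout, one row per record) or `"json"`
#'   (nested patient objects).
#' @return `path`, invisibly.
#' @seealso [read_cohort()] for the inverse; the two are lossless on valid
#'   cohorts.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      cohort_to_list(cohort), path,
      auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = TRUE
    )
    return(invisible(path))
  }
  rows <- lapply(cohort$patients, patient_csv_rows)
  mat <- if (length(rows)) do.call(rbind, rows) else {
    matrix(character(), ncol = length(CSV_COLUMNS),
           dimnames = list(NULL, CSV_COLUMNS))
  }
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  colnames(df) <- CSV_COLUMNS
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

patient_csv_rows <- function(p) {
  blank <- setNames(rep("", length(CSV_COLUMNS)), CSV_COLUMNS)
  prow <- blank
  prow["patient_id"] <- p$patient_id
  prow["record_kind"] <- "patient"
  prow["age_at_index"] <- fmt_cell(p$age_at_index)
  prow["sex"] <- p$sex
  prow["surgically_fit"] <- fmt_cell(p$surgically_fit)
  prow["limited_life_expectancy"] <- fmt_cell(p$limited_life_expectancy)
  prow["comorbidities"] <- paste(p$comorbidities, collapse = ";")
  prow["outcome_pdac"] <- fmt_cell(p$outcome_pdac)
  prow["outcome_pdac_date"] <- fmt_cell(p$outcome_pdac_date)
  prow["clinical_followup_months"] <- fmt_cell(p$clinical_followup_months)
  prow["radiological_followup_months"] <- fmt_cell(p$radiological_followup_months)

  obs <- p$observations
  orows <- t(vapply(seq_len(nrow(obs)), function(i) {
    r <- blank
    r["patient_id"] <- p$patient_id
    r["record_kind"] <- "observation"
    r["date"] <- fmt_cell(obs$observation_date[i])
    for (col in setdiff(OBS_COLUMNS, "observation_date")) {
      r[col] <- fmt_cell(obs[[col]][i])
    }
    r
  }, blank))

  ev <- p$management_events
  erows <- if (nrow(ev)) {
    t(vapply(seq_len(nrow(ev)), function(i) {
      r <- blank
      r["patient_id"] <- p$patient_id
      r["record_kind"] <- "event"
      r["date"] <- fmt_cell(ev$event_date[i])
      r["event_type"] <- ev$event_type[i]
      r
    }, blank))
  } else {
    matrix(character(), ncol = length(CSV_COLUMNS))
  }
  rbind(matrix(prow, nrow = 1, dimnames = list(NULL, CSV_COLUMNS)), orows, erows)
}

cohort_to_list <- function(cohort) {
  list(
    provenance = cohort$provenance,
    patients = lapply(cohort$patients, function(p) {
      obs <- p$observations
      list(
        patient_id = p$patient_id,
        age_at_index = p$age_at_index,
        sex = p$sex,
        surgically_fit = p$surgically_fit,
        limited_life_expectancy = p$limited_life_expectancy,
        comorbidities = as.list(p$comorbidities),
        outcome_pdac = p$outcome_pdac,
        outcome_pdac_date = if (is.na(p$outcome_pdac_date)) NULL else
          format(p$outcome_pdac_date, "%Y-%m-%d"),
        clinical_followup_months = p$clinical_followup_months,
        radiological_followup_months = p$radiological_followup_months,
        observations = lapply(seq_len(nrow(obs)), function(i) {
          row <- lapply(OBS_COLUMNS, function(col) {
            v <- obs[[col]][i]
            if (is.na(v)) NULL
            else if (inherits(v, "Date")) format(v, "%Y-%m-%d")
            else v
          })
          names(row) <- OBS_COLUMNS
          row[!vapply(row, is.null, logical(1))]
        }),
        management_events = lapply(seq_len(nrow(p$management_events)), function(i) {
          list(
            event_date = format(p$management_events$event_date[i], "%Y-%m-%d"),
            event_type = p$management_events$event_type[i]
          )
        })
      )
    })
  )
}

#' Read a cohort from disk
#'
#' Reads and validates a cohort written by [write_cohort()]. Validation
#' failures are collected across rows and reported together, each citing
#' the file row (CSV) or patient id (JSON) and the violated invariant.
#'
#' @param path Input file path.
#' @param format `"csv"` or `"json"`; default guesses from the extension.
#' @return A validated [ipmn_cohort()].
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") read_cohort_json(path) else read_cohort_csv(path)
}

read_cohort_csv <- function(path) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(c("patient_id", "record_kind", "date"), colnames(df))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df[is.na(df)] <- ""
  errors <- character()
  note <- function(row, msg) {
    # +1 for the header line so the number matches the file
    errors[[length(errors) + 1]] <<- sprintf("row %d: %s", row + 1L, msg)
  }
  cell <- function(row, col) if (col %in% colnames(df)) df[[col]][row] else ""
  typed <- function(row, col, parser) {
    tryCatch(parser(cell(row, col)),
             error = function(e) {
               note(row, sprintf("field '%s': %s", col, conditionMessage(e)))
               NA
             })
  }

  patients <- list()
  for (pid in unique(df$patient_id)) {
    rows <- which(df$patient_id == pid)
    kinds <- df$record_kind[rows]
    bad_kind <- rows[!kinds %in% c("patient", "observation", "event")]
    for (r in bad_kind) {
      note(r, sprintf("field 'record_kind': invalid value '%s'", df$record_kind[r]))
    }
    prow <- rows[kinds == "patient"]
    if (length(prow) != 1) {
      note(rows[1], sprintf(
        "patient '%s' must have exactly one 'patient' row (found %d)",
        pid, length(prow)
      ))
      next
    }
    orows <- rows[kinds == "observation"]
    erows <- rows[kinds == "event"]

    obs_list <- lapply(orows, function(r) {
      mod <- cell(r, "modality")
      if (!mod %in% OBS_MODALITIES) {
        note(r, sprintf("field 'modality': invalid value '%s'", mod))
      }
      data.frame(
        observation_date = typed(r, "date", parse_date_cell),
        leading_cyst_size = typed(r, "leading_cyst_size", parse_numeric_cell),
        n_cysts = as.integer(typed(r, "n_cysts", parse_numeric_cell)),
        mpd_diameter = typed(r, "mpd_diameter", parse_numeric_cell),
        mural_nodule_size = typed(r, "mural_nodule_size", parse_numeric_cell),
        mural_nodule_enhancing = typed(r, "mural_nodule_enhancing", parse_logical_cell),
        wall_thickened = isTRUE(typed(r, "wall_thickened", parse_logical_cell)),
        abrupt_duct_change = isTRUE(typed(r, "abrupt_duct_change", parse_logical_cell)),
        lymphadenopathy = isTRUE(typed(r, "lymphadenopathy", parse_logical_cell)),
        obstructive_jaundice = isTRUE(typed(r, "obstructive_jaundice", parse_logical_cell)),
        ca19_9 = typed(r, "ca19_9", parse_numeric_cell),
        acute_pancreatitis_episode = isTRUE(typed(r, "acute_pancreatitis_episode", parse_logical_cell)),
        new_onset_diabetes = isTRUE(typed(r, "new_onset_diabetes", parse_logical_cell)),
        modality = cell(r, "modality"),
        stringsAsFactors = FALSE
      )
    })
    obs <- if (length(obs_list)) do.call(rbind, obs_list) else
      cyst_observation(Sys.Date(), 1)[0, ]

    for (r in erows) {
      ety <- cell(r, "event_type")
      if (!ety %in% EVENT_TYPES) {
        note(r, sprintf("field 'event_type': invalid value '%s'", ety))
      }
    }
    ev <- if (length(erows)) {
      data.frame(
        event_date = as.Date(vapply(erows, function(r) {
          as.character(typed(r, "date", parse_date_cell))
        }, character(1))),
        event_type = df$event_type[erows],
        stringsAsFactors = FALSE
      )
    } else {
      empty_events()
    }

    comorb <- cell(prow, "comorbidities")
    comorb <- if (comorb == "") character() else strsplit(comorb, ";", fixed = TRUE)[[1]]

    p <- structure(
      list(
        patient_id = pid,
        age_at_index = typed(prow, "age_at_index", parse_numeric_cell),
        sex = cell(prow, "sex"),
        surgically_fit = isTRUE(typed(prow, "surgically_fit", parse_logical_cell)),
        limited_life_expectancy = isTRUE(typed(prow, "limited_life_expectancy", parse_logical_cell)),
        comorbidities = comorb,
        observations = obs,
        management_events = ev,
        outcome_pdac = isTRUE(typed(prow, "outcome_pdac", parse_logical_cell)),
        outcome_pdac_date = typed(prow, "outcome_pdac_date", parse_date_cell),
        clinical_followup_months = typed(prow, "clinical_followup_months", parse_numeric_cell),
        radiological_followup_months = typed(prow, "radiological_followup_months", parse_numeric_cell)
      ),
      class = "patient_record"
    )
    problems <- validate_patient(p)
    for (msg in problems) note(prow, sprintf("patient '%s': %s", pid, msg))
    patients[[length(patients) + 1]] <- p
  }
  if (length(errors)) {
    stop("cohort validation failed:\n  ", paste(errors, collapse = "\n  "))
  }
  ipmn_cohort(patients, provenance = paste0("read from ", basename(path)))
}

read_cohort_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  errors <- character()
  patients <- lapply(raw$patients, function(pr) {
    scal <- function(x, default = NA) if (is.null(x)) default else x
    obs_list <- lapply(pr$observations, function(o) {
      cyst_observation(
        observation_date = o$observation_date,
        leading_cyst_size = o$leading_cyst_size,
        n_cysts = scal(o$n_cysts, 1L),
        mpd_diameter = scal(o$mpd_diameter, NA_real_),
        mural_nodule_size = scal(o$mural_nodule_size, NA_real_),
        mural_nodule_enhancing = scal(o$mural_nodule_enhancing, NA),
        wall_thickened = isTRUE(o$wall_thickened),
        abrupt_duct_change = isTRUE(o$abrupt_duct_change),
        lymphadenopathy = isTRUE(o$lymphadenopathy),
        obstructive_jaundice = isTRUE(o$obstructive_jaundice),
        ca19_9 = scal(o$ca19_9, NA_real_),
        acute_pancreatitis_episode = isTRUE(o$acute_pancreatitis_episode),
        new_onset_diabetes = isTRUE(o$new_onset_diabetes),
        modality = scal(o$modality, "mri_mrcp")
      )
    })
    ev <- if (length(pr$management_events)) {
      do.call(rbind, lapply(pr$management_events, function(e) {
        management_event(e$event_date, e$event_type)
      }))
    } else {
      empty_events()
    }
    p <- structure(
      list(
        patient_id = pr$patient_id,
        age_at_index = as.numeric(pr$age_at_index),
        sex = pr$sex,
        surgically_fit = isTRUE(pr$surgically_fit),
        limited_life_expectancy = isTRUE(pr$limited_life_expectancy),
        comorbidities = as.character(unlist(pr$comorbidities)),
        observations = do.call(rbind, obs_list),
        management_events = ev,
        outcome_pdac = isTRUE(pr$outcome_pdac),
        outcome_pdac_date = as.Date(scal(pr$outcome_pdac_date, NA)),
        clinical_followup_months = as.numeric(pr$clinical_followup_months),
        radiological_followup_months = as.numeric(pr$radiological_followup_months)
      ),
      class = "patient_record"
    )
    problems <- validate_patient(p)
    if (length(problems)) {
      errors[[length(errors) + 1]] <<- sprintf(
        "patient '%s': %s", pr$patient_id, paste(problems, collapse = "; ")
      )
    }
    p
  })
  if (length(errors)) {
    stop("cohort validation failed:\n  ", paste(errors, collapse = "\n  "))
  }
  ipmn_cohort(patients, provenance = scal_or(raw$provenance, paste0("read from ", basename(path))))
}

scal_or <- function(x, default) if (is.null(x)) default else x
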