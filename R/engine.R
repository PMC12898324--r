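# The rule engine: detectors for high-risk stigmata (HRS) and worrisome
# features (WF), and the recommendation logic with precedence
# HRS > WF > size band.
#
# Feature definitions (thresholds live in the policy, defaults shown):
#   HRS: main pancreatic duct >= 10 mm; obstructive jaundice; enhancing
#        mural nodule >= 5 mm.
#   WF:  cyst >= 30 mm; mural nodule not qualifying as HRS (< 5 mm, or
#        non-enhancing); thickened cyst wall; main duct 5-9 mm (closed
#        band below the HRS cutoff); abrupt duct-calibre change;
#        lymphadenopathy; CA 19-9 above the assay upper limit of normal;
#        growth strictly > 5 mm per 2 years; plus the switchable additions
#        acute pancreatitis and new-onset diabetes.
# Boundary conventions follow the printed definitions exactly: ">=" for the
# size/duct cutoffs, strict ">" for growth and CA 19-9 elevation.

HRS_FEATURES <- c("mpd_ge_10mm", "obstructive_jaundice", "enhancing_nodule_ge_5mm")

WF_FEATURES <- c(
  "cyst_ge_30mm", "nodule_lt_5mm", "wall_thickened", "mpd_5_to_9mm",
  "abrupt_duct_change", "lymphadenopathy", "ca19_9_elevated",
  "growth_gt_5mm_per_2y", "acute_pancreatitis", "new_onset_diabetes"
)

#' Cyst growth rate over the trailing two-year window
#'
#' Growth is the size difference between the latest observation and the
#' earliest observation inside the trailing 24-month window ending at the
#' latest observation, rescaled to mm per 24 months. With fewer than two
#' observations in the window (or zero elapsed time) growth is undefined
#' and `NA` is returned — never 0, so an undefined rate can not
#' accidentally clear the rapid-growth feature threshold.
#'
#' @param observations A data frame of observations (strictly increasing
#'   `observation_date`, `leading_cyst_size` in mm).
#' @param window_months Width of the trailing window (default 24).
#' @return Growth in mm per 24 months, or `NA_real_` when undefined.
#' @export
#' @examples
#' obs <- rbind(
#'   cyst_observation("2020-01-01", 10),
#'   cyst_observation("2022-01-01", 16, modality = "eus")
#' )
#' compute_growth_rate(obs)  # 6 mm / 2 years
compute_growth_rate <- function(observations, window_months = 24) {
  d <- observations$observation_date
  if (length(d) > 1 && any(diff(as.numeric(d)) <= 0)) {
    stop("observation dates must be strictly increasing")
  }
  .growth_rate(d, observations$leading_cyst_size, window_months)
}

# vector core shared with the scheduler fast path (no re-validation)
.growth_rate <- function(d, s, window_months = 24) {
  keep <- !is.na(s)
  d <- d[keep]; s <- s[keep]
  n <- length(d)
  if (n < 2) return(NA_real_)
  days <- as.numeric(d)
  elapsed <- (days[n] - days) / DAYS_PER_MONTH  # months before the last scan
  # dates are whole days, so admit half a day (~0.02 months) of rounding
  # slack at the window edge
  first <- which(elapsed <= window_months + 0.02)[1]
  if (first == n) return(NA_real_)
  span <- elapsed[first]
  if (span <= 0) return(NA_real_)
  (s[n] - s[first]) / span * 24
}

# Fast internal feature detection on pre-extracted vectors. `obs` is the
# patient's observation data frame, `i` the row index of the observation in
# effect, `growth` the growth rate (mm/2y or NA).
.detect_features <- function(obs, i, growth, policy) {
  th <- policy$thresholds
  notes <- character()

  size <- obs$leading_cyst_size[i]
  mpd <- obs$mpd_diameter[i]
  nod <- obs$mural_nodule_size[i]
  nod_enh <- obs$mural_nodule_enhancing[i]
  ca <- obs$ca19_9[i]

  hrs <- character()
  if (!is.na(mpd)) {
    if (mpd >= th$mpd_hrs_mm) hrs <- c(hrs, "mpd_ge_10mm")
  } else {
    notes <- c(notes, "mpd_diameter missing: duct features not assessed")
  }
  if (isTRUE(obs$obstructive_jaundice[i])) hrs <- c(hrs, "obstructive_jaundice")
  nodule_hrs <- !is.na(nod) && isTRUE(nod_enh) && nod >= th$nodule_hrs_mm
  if (nodule_hrs) hrs <- c(hrs, "enhancing_nodule_ge_5mm")

  wf <- character()
  if (size >= th$cyst_wf_mm) wf <- c(wf, "cyst_ge_30mm")
  if (!is.na(nod) && !nodule_hrs) wf <- c(wf, "nodule_lt_5mm")
  if (isTRUE(obs$wall_thickened[i])) wf <- c(wf, "wall_thickened")
  if (!is.na(mpd) && mpd >= th$mpd_wf_low_mm && mpd < th$mpd_hrs_mm) {
    wf <- c(wf, "mpd_5_to_9mm")
  }
  if (isTRUE(obs$abrupt_duct_change[i])) wf <- c(wf, "abrupt_duct_change")
  if (isTRUE(obs$lymphadenopathy[i])) wf <- c(wf, "lymphadenopathy")
  if (!is.na(ca)) {
    if (ca > th$ca19_9_u_ml) wf <- c(wf, "ca19_9_elevated")
  } else {
    notes <- c(notes, "ca19_9 missing: marker not assessed")
  }
  if (!is.na(growth) && growth > th$growth_wf_mm_per_2y) {
    wf <- c(wf, "growth_gt_5mm_per_2y")
  }
  if (policy$wf_toggles$acute_pancreatitis &&
      isTRUE(obs$acute_pancreatitis_episode[i])) {
    wf <- c(wf, "acute_pancreatitis")
  }
  if (policy$wf_toggles$new_onset_diabetes &&
      isTRUE(obs$new_onset_diabetes[i])) {
    wf <- c(wf, "new_onset_diabetes")
  }
  list(hrs = hrs, wf = wf, notes = notes, size = size)
}

#' Assess high-risk stigmata and worrisome features at a date
#'
#' Evaluates the policy thresholds on the patient's most recent observation
#' at or before `at`. The growth feature uses [compute_growth_rate()] over
#' all observations up to `at`. When the patient has multiple cysts,
#' size-derived features use the leading cyst while boolean findings are as
#' reported for the patient as a whole (every cyst is reviewed at each
#' scan, so a finding on any cyst appears in the record). Missing optional
#' measurements mean the feature is not demonstrated; each such gap is
#' listed in the assessment's `notes`.
#'
#' @param patient A [patient_record()].
#' @param at Assessment date; default the index (first) observation date.
#' @param policy A `decision_policy` (default [default_policy()]).
#' @return An object of class `feature_assessment` with elements
#'   `high_risk_stigmata`, `worrisome_features`, `wf_count`, `growth_rate`,
#'   `observation_date`, `at`, `notes`.
#' @export
assess_features <- function(patient, at = NULL, policy = default_policy()) {
  obs <- patient$observations
  if (is.null(at)) at <- obs$observation_date[1]
  at <- as.Date(at)
  idx <- which(obs$observation_date <= at)
  if (!length(idx)) {
    stop("patient '", patient$patient_id, "' has no observation on or before ", at)
  }
  i <- idx[length(idx)]
  growth <- compute_growth_rate(obs[idx, , drop = FALSE])
  det <- .detect_features(obs, i, growth, policy)
  structure(
    list(
      high_risk_stigmata = det$hrs,
      worrisome_features = det$wf,
      wf_count = length(det$wf),
      growth_rate = growth,
      observation_date = obs$observation_date[i],
      at = at,
      notes = det$notes
    ),
    class = "feature_assessment"
  )
}

#' @export
print.feature_assessment <- function(x, ...) {
  cat("<feature_assessment at ", format(x$at), ">\n", sep = "")
  cat("  HRS:", if (length(x$high_risk_stigmata))
    paste(x$high_risk_stigmata, collapse = ", ") else "none", "\n")
  cat("  WF :", if (length(x$worrisome_features))
    paste(x$worrisome_features, collapse = ", ") else "none",
    sprintf("(count %d)\n", x$wf_count))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# Core recommendation logic shared by the public recommend() and the
# counterfactual scheduler. Returns action/modality/interval plus the
# ordered list of fired-rule identifiers.
.recommend_core <- function(patient, at, policy) {
  obs <- patient$observations
  i <- findInterval(as.numeric(at), as.numeric(obs$observation_date))
  if (i < 1) {
    stop("patient '", patient$patient_id, "' has no observation on or before ", at)
  }
  growth <- .growth_rate(obs$observation_date[seq_len(i)],
                         obs$leading_cyst_size[seq_len(i)])
  det <- .detect_features(obs, i, growth, policy)
  rationale <- character()

  if (length(det$hrs)) {
    rationale <- c(rationale, paste0("hrs:", det$hrs))
    if (isTRUE(patient$surgically_fit) && !isTRUE(patient$limited_life_expectancy)) {
      rationale <- c(rationale, "rule:hrs_fit->surgery_referral")
      return(list(action = "surgery_referral", modality = "none",
                  interval_months = NA_real_, rationale = rationale, det = det))
    }
    rationale <- c(rationale, "rule:hrs_unfit->surveillance")
    return(list(action = "eus_surveillance",
                modality = policy$unfit_rule$modality,
                interval_months = policy$unfit_rule$interval_months,
                rationale = rationale, det = det))
  }

  nwf <- length(det$wf)
  if (nwf >= 1) {
    rationale <- c(rationale, paste0("wf:", det$wf),
                   paste0("wf_count:", nwf))
    tier <- policy$wf_rules[policy$wf_rules$min_count <= nwf, , drop = FALSE]
    tier <- tier[nrow(tier), , drop = FALSE]
    rationale <- c(rationale,
                   sprintf("rule:wf_tier_min_count_%d", tier$min_count))
    return(list(action = "eus_surveillance", modality = tier$modality,
                interval_months = tier$interval_months,
                rationale = rationale, det = det))
  }

  size <- det$size
  bands <- policy$size_bands
  b <- which(size >= bands$lower_mm & size < bands$upper_mm)
  if (!length(b)) {
    # sizes at/above the cyst-WF cutoff always carry the size WF, so this
    # is unreachable with a valid policy; guard for malformed inputs
    stop("cyst size ", size, " mm falls outside every policy size band")
  }
  b <- b[1]
  elapsed <- months_between(obs$observation_date[1], at)
  stable <- elapsed >= bands$interval_months[b] - 1e-9
  interval <- if (stable) bands$stable_interval_months[b] else bands$interval_months[b]
  rationale <- c(
    rationale,
    sprintf("band:%g-%gmm", bands$lower_mm[b], bands$upper_mm[b]),
    if (stable) "rule:band_stable_interval" else "rule:band_first_interval"
  )
  list(action = "imaging_surveillance", modality = bands$modality[b],
       interval_months = interval, rationale = rationale, det = det)
}

#' Recommend management for a patient at a date
#'
#' Applies the decision precedence HRS > WF > size band to the feature
#' state at `at`:
#' * any high-risk stigma: surgery referral for a surgically fit patient
#'   without limited life expectancy; otherwise the policy's unfit rule
#'   (EUS-based surveillance).
#' * one or more worrisome features: the highest matching WF tier
#'   (EUS-based surveillance; the default policy has a single tier at
#'   6 months).
#' * otherwise the size band of the leading cyst. A band's first interval
#'   applies until elapsed follow-up since the index scan reaches that
#'   interval; thereafter the band's stable interval applies (a no-WF cyst
#'   that has completed its first-interval check has demonstrated
#'   stability, because any rapid growth would have raised the growth WF).
#'
#' The rationale lists every fired rule in order, prefixed by the policy
#' version and checksum, so a recommendation is traceable to the policy
#' file that produced it.
#'
#' @inheritParams assess_features
#' @return An object of class `recommendation` with elements `action`
#'   (`"surgery_referral"`, `"eus_surveillance"`,
#'   `"imaging_surveillance"`), `modality`, `interval_months` (`NA` for
#'   surgery referral), `rationale`, and the `feature_assessment`.
#' @export
#' @examples
#' p <- patient_record(
#'   "p1", 70, "male",
#'   observations = cyst_observation("2018-01-01", 12),
#'   radiological_followup_months = 36, clinical_followup_months = 36
#' )
#' recommend(p)
recommend <- function(patient, at = NULL, policy = default_policy()) {
  obs <- patient$observations
  if (is.null(at)) at <- obs$observation_date[1]
  at <- as.Date(at)
  core <- .recommend_core(patient, at, policy)
  i <- findInterval(as.numeric(at), as.numeric(obs$observation_date))
  assessment <- structure(
    list(
      high_risk_stigmata = core$det$hrs,
      worrisome_features = core$det$wf,
      wf_count = length(core$det$wf),
      growth_rate = .growth_rate(obs$observation_date[seq_len(i)],
                                 obs$leading_cyst_size[seq_len(i)]),
      observation_date = obs$observation_date[i],
      at = at,
      notes = core$det$notes
    ),
    class = "feature_assessment"
  )
  structure(
    list(
      action = core$action,
      modality = core$modality,
      interval_months = core$interval_months,
      rationale = c(
        sprintf("policy:%s@%s", policy$version,
                substr(if (is.na(policy$checksum)) "memory" else policy$checksum, 1, 8)),
        core$rationale
      ),
      assessment = assessment
    ),
    class = "recommendation"
  )
}

#' @export
print.recommendation <- function(x, ...) {
  cat("<recommendation> ", x$action, sep = "")
  if (!is.na(x$interval_months)) {
    cat(sprintf(": %s every %g months", x$modality, x$interval_months))
  }
  cat("\n  rationale: ", paste(x$rationale, collapse = " | "), "\n", sep = "")
  invisible(x)
}
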