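# Decision policies: externalized threshold and interval tables driving the
# rule engine. The shipped default (inst/extdata/kyoto_policy.yaml) encodes
# the Kyoto-framework schedule; the engine itself contains no interval
# constants, so an institution can re-derive or correct the schedule by
# editing the policy file alone.

#' Load a decision policy from a YAML file
#'
#' A policy bundles the feature thresholds (mm, U/mL), the no-WF size-band
#' schedule, the worrisome-feature rule tiers, the high-risk-stigmata
#' action, and the rule for surgically unfit patients. The file's MD5
#' checksum is stored so that every recommendation records which policy
#' produced it.
#'
#' @param path Path to a policy YAML file; default is the shipped
#'   Kyoto-framework encoding.
#' @return An object of class `decision_policy`.
#' @export
#' @examples
#' pol <- load_policy()
#' pol$size_bands
load_policy <- function(path = system.file("extdata", "kyoto_policy.yaml",
                                           package = "ipmnaudit")) {
  raw <- yaml::read_yaml(path)
  pol <- as_policy(raw)
  pol$checksum <- unname(tools::md5sum(path))
  pol$source <- path
  pol
}

#' Construct a decision policy from a list
#'
#' Programmatic equivalent of [load_policy()]; validates the same
#' invariants (size bands partition (0, 30) mm without overlap, all
#' intervals positive, WF tiers ordered).
#'
#' @param raw A list with elements `version`, `thresholds`, `wf_toggles`,
#'   `size_bands`, `wf_rules`, `hrs_rule`, `unfit_rule` (see the shipped
#'   YAML for the layout).
#' @return An object of class `decision_policy`.
#' @export
as_policy <- function(raw) {
  required <- c("thresholds", "size_bands", "wf_rules", "hrs_rule", "unfit_rule")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("policy is missing element(s): ", paste(missing, collapse = ", "))
  }
  th_required <- c("mpd_hrs_mm", "nodule_hrs_mm", "cyst_wf_mm",
                   "mpd_wf_low_mm", "ca19_9_u_ml", "growth_wf_mm_per_2y")
  th_missing <- setdiff(th_required, names(raw$thresholds))
  if (length(th_missing)) {
    stop("policy thresholds missing: ", paste(th_missing, collapse = ", "))
  }

  bands <- do.call(rbind, lapply(raw$size_bands, function(b) {
    data.frame(
      lower_mm = as.numeric(b$lower_mm),
      upper_mm = as.numeric(b$upper_mm),
      modality = as.character(b$modality),
      interval_months = as.numeric(b$interval_months),
      stable_interval_months = as.numeric(b$stable_interval_months),
      stringsAsFactors = FALSE
    )
  }))
  bands <- bands[order(bands$lower_mm), , drop = FALSE]
  if (any(bands$upper_mm <= bands$lower_mm)) {
    stop("policy size bands must have upper_mm > lower_mm")
  }
  cyst_wf <- as.numeric(raw$thresholds$cyst_wf_mm)
  if (bands$lower_mm[1] != 0 ||
      abs(bands$upper_mm[nrow(bands)] - cyst_wf) > 1e-9) {
    stop("policy size bands must cover (0, ", cyst_wf, ") mm")
  }
  if (nrow(bands) > 1) {
    gaps <- bands$lower_mm[-1] - bands$upper_mm[-nrow(bands)]
    if (any(gaps < -1e-9)) stop("policy size bands overlap")
    if (any(gaps > 1e-9)) stop("policy size bands leave a gap")
  }
  if (any(bands$interval_months <= 0) || any(bands$stable_interval_months <= 0)) {
    stop("all policy intervals must be > 0")
  }
  if (!all(bands$modality %in% OBS_MODALITIES)) {
    stop("unknown modality in size bands")
  }

  wf_rules <- do.call(rbind, lapply(raw$wf_rules, function(w) {
    data.frame(
      min_count = as.integer(w$min_count),
      modality = as.character(w$modality),
      interval_months = as.numeric(w$interval_months),
      stringsAsFactors = FALSE
    )
  }))
  wf_rules <- wf_rules[order(wf_rules$min_count), , drop = FALSE]
  if (!nrow(wf_rules) || wf_rules$min_count[1] != 1L) {
    stop("policy wf_rules must include a tier with min_count = 1")
  }
  if (any(wf_rules$interval_months <= 0)) {
    stop("all policy intervals must be > 0")
  }
  if (is.null(raw$unfit_rule$interval_months) ||
      as.numeric(raw$unfit_rule$interval_months) <= 0) {
    stop("unfit_rule interval must be > 0")
  }

  toggles <- list(
    acute_pancreatitis = !isFALSE(raw$wf_toggles$acute_pancreatitis),
    new_onset_diabetes = !isFALSE(raw$wf_toggles$new_onset_diabetes)
  )

  structure(
    list(
      version = scal_or(raw$version, "unversioned"),
      thresholds = lapply(raw$thresholds, as.numeric),
      wf_toggles = toggles,
      size_bands = bands,
      wf_rules = wf_rules,
      hrs_rule = list(action = scal_or(raw$hrs_rule$action, "surgery_referral")),
      unfit_rule = list(
        modality = as.character(raw$unfit_rule$modality),
        interval_months = as.numeric(raw$unfit_rule$interval_months)
      ),
      checksum = NA_character_,
      source = "in-memory"
    ),
    class = "decision_policy"
  )
}

#' The shipped default policy
#'
#' @return The validated `decision_policy` read from the package's default
#'   YAML encoding of the Kyoto-framework schedule.
#' @export
default_policy <- function() load_policy()

#' @export
print.decision_policy <- function(x, ...) {
  cat("<decision_policy ", x$version, ">\n", sep = "")
  cat("  size bands (mm -> first/stable interval, months):\n")
  for (i in seq_len(nrow(x$size_bands))) {
    b <- x$size_bands[i, ]
    cat(sprintf(
      "    [%g, %g): %s %g / %g\n",
      b$lower_mm, b$upper_mm, b$modality, b$interval_months,
      b$stable_interval_months
    ))
  }
  cat(sprintf(
    "  WF tiers: %s; HRS: %s; unfit: %s q%gmo\n",
    paste(sprintf("count>=%d -> %s q%gmo", x$wf_rules$min_count,
                  x$wf_rules$modality, x$wf_rules$interval_months),
          collapse = ", "),
    x$hrs_rule$action, x$unfit_rule$modality, x$unfit_rule$interval_months
  ))
  invisible(x)
}

#' Sample a random (but valid) decision policy
#'
#' Used by property tests: the audit's excess-imaging metric must vanish on
#' cohorts generated to follow the policy exactly, whatever the policy.
#' Thresholds stay at their defaults; the band split point and every
#' interval are randomized.
#'
#' @param seed Integer seed.
#' @return A `decision_policy`.
#' @export
random_policy <- function(seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  split <- sample(8:25, 1)
  iv <- function() sample(c(3, 6, 9, 12), 1)
  stable_iv <- function(first) first + sample(c(0, 6, 12, 18), 1)
  i1 <- iv(); i2 <- iv()
  raw <- list(
    version = paste0("random-", seed),
    thresholds = list(
      mpd_hrs_mm = 10, nodule_hrs_mm = 5, cyst_wf_mm = 30,
      mpd_wf_low_mm = 5, ca19_9_u_ml = 37, growth_wf_mm_per_2y = 5
    ),
    wf_toggles = list(acute_pancreatitis = TRUE, new_onset_diabetes = TRUE),
    size_bands = list(
      list(lower_mm = 0, upper_mm = split, modality = "mri_mrcp",
           interval_months = i1, stable_interval_months = stable_iv(i1)),
      list(lower_mm = split, upper_mm = 30, modality = "mri_mrcp",
           interval_months = i2, stable_interval_months = stable_iv(i2))
    ),
    wf_rules = list(list(min_count = 1, modality = "eus",
                         interval_months = sample(c(3, 6), 1))),
    hrs_rule = list(action = "surgery_referral"),
    unfit_rule = list(modality = "eus", interval_months = sample(c(3, 6), 1))
  )
  as_policy(raw)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
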