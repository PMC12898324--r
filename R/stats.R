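# Cohort statistics: descriptive summaries (median/IQR, n/%), the
# univariable test battery relating covariates to concordance class, and
# multivariable logistic regression with the p < 0.2 variable-selection
# rule (age and sex always forced into the model).

#' Per-patient covariate table
#'
#' Flattens a cohort (optionally joined with audit classes) into one row
#' per patient: demographics, index cyst measurements, follow-up clocks,
#' and one logical column per comorbidity.
#'
#' @param cohort An [ipmn_cohort()].
#' @param audit Optional [audit_cohort()] result; adds a `class` column.
#' @return A tibble.
#' @export
covariate_table <- function(cohort, audit = NULL) {
  ps <- cohort$patients
  chr <- function(f) vapply(ps, f, character(1))
  num <- function(f) vapply(ps, f, numeric(1))
  age <- num(function(p) p$age_at_index)
  size <- num(function(p) p$observations$leading_cyst_size[1])
  tab <- tibble(
    patient_id = chr(function(p) p$patient_id),
    age = age,
    male = chr(function(p) p$sex) == "male",
    under_50 = age < 50,
    cyst_size = size,
    cyst_gt_20mm = size > 20,
    multiple_cysts = num(function(p) p$observations$n_cysts[1]) > 1,
    radiological_followup_months = num(function(p) p$radiological_followup_months),
    clinical_followup_months = num(function(p) p$clinical_followup_months),
    outcome_pdac = vapply(ps, function(p) isTRUE(p$outcome_pdac), logical(1))
  )
  for (cm in COMORBIDITIES) {
    tab[[cm]] <- vapply(ps, function(p) cm %in% p$comorbidities, logical(1))
  }
  if (!is.null(audit)) {
    res <- audit$results
    tab$class <- res$class[match(tab$patient_id, res$patient_id)]
  }
  tab
}

CONTINUOUS_COVARIATES <- c(
  "age", "cyst_size", "radiological_followup_months",
  "clinical_followup_months"
)

CATEGORICAL_COVARIATES <- function() {
  c("male", "under_50", "cyst_gt_20mm", "multiple_cysts", COMORBIDITIES)
}

#' Descriptive summary of a cohort
#'
#' Continuous variables as median (IQR), categorical as n (%), in the
#' layout of a baseline-characteristics table.
#'
#' @param cohort An [ipmn_cohort()].
#' @return A tibble with columns `variable`, `type`, `n`, `pct`, `median`,
#'   `q1`, `q3`, `summary` (formatted string).
#' @export
describe_cohort <- function(cohort) {
  if (!length(cohort$patients)) stop("cohort is empty")
  tab <- covariate_table(cohort)
  n <- nrow(tab)
  cont_row <- function(var) {
    x <- tab[[var]]
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7))
    tibble(
      variable = var, type = "continuous", n = n, pct = NA_real_,
      median = q[2], q1 = q[1], q3 = q[3],
      summary = sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
    )
  }
  cat_row <- function(var) {
    k <- sum(tab[[var]], na.rm = TRUE)
    pct <- percent_of(k, n)
    tibble(
      variable = var, type = "categorical", n = k, pct = pct,
      median = NA_real_, q1 = NA_real_, q3 = NA_real_,
      summary = sprintf("%d (%.1f%%)", k, pct)
    )
  }
  rbind(
    do.call(rbind, lapply(CONTINUOUS_COVARIATES, cont_row)),
    do.call(rbind, lapply(CATEGORICAL_COVARIATES(), cat_row))
  )
}

group_labels <- function(tab, grouping) {
  switch(grouping,
    concordant_vs_not = {
      keep <- tab$class %in% c("concordant", "over", "under")
      list(
        keep = keep,
        g = ifelse(tab$class[keep] == "concordant", "concordant", "non_concordant")
      )
    },
    over_vs_under = {
      keep <- tab$class %in% c("over", "under")
      list(keep = keep, g = tab$class[keep])
    },
    stop("unknown grouping: ", grouping)
  )
}

#' Univariable screen of covariates against concordance class
#'
#' One test per covariate: categorical variables with the chi-square test
#' (no continuity correction), falling back to Fisher's exact test when any
#' expected cell count is below 5; continuous variables with the
#' Mann-Whitney test for two groups (exact when combined n <= 20 and
#' tie-free) or Kruskal-Wallis for more.
#'
#' @param cohort An [ipmn_cohort()].
#' @param audit The [audit_cohort()] result for the same cohort.
#' @param grouping `"concordant_vs_not"` (default) or `"over_vs_under"`
#'   (the conservative-vs-liberal comparison within the non-concordant
#'   subgroup).
#' @return A tibble with columns `variable`, `test`, `statistic`,
#'   `p_value`, and per-group summary strings.
#' @export
univariable_screen <- function(cohort, audit,
                               grouping = c("concordant_vs_not", "over_vs_under")) {
  grouping <- match.arg(grouping)
  tab <- covariate_table(cohort, audit)
  gl <- group_labels(tab, grouping)
  tab <- tab[gl$keep, , drop = FALSE]
  g <- factor(gl$g)
  if (nlevels(droplevels(g)) < 2) {
    stop("grouping '", grouping, "' has all patients in one class")
  }
  lev <- levels(g)

  cat_result <- function(var) {
    x <- factor(tab[[var]], levels = c(FALSE, TRUE))
    tb <- table(x, g)
    summaries <- vapply(lev, function(l) {
      n_l <- sum(g == l)
      sprintf("%d/%d (%.1f%%)", tb["TRUE", l], n_l,
              if (n_l > 0) percent_of(tb["TRUE", l], n_l) else NA_real_)
    }, character(1))
    if (any(rowSums(tb) == 0)) {
      return(tibble(variable = var, test = "none", statistic = NA_real_,
                    p_value = NA_real_, group1 = summaries[1], group2 = summaries[2]))
    }
    expected <- suppressWarnings(chisq.test(tb, correct = FALSE)$expected)
    if (any(expected < 5)) {
      ft <- fisher.test(tb)
      tibble(variable = var, test = "fisher_exact", statistic = NA_real_,
             p_value = ft$p.value, group1 = summaries[1], group2 = summaries[2])
    } else {
      ct <- chisq.test(tb, correct = FALSE)
      tibble(variable = var, test = "chi_square",
             statistic = unname(ct$statistic), p_value = ct$p.value,
             group1 = summaries[1], group2 = summaries[2])
    }
  }

  cont_result <- function(var) {
    x <- tab[[var]]
    summaries <- vapply(lev, function(l) {
      q <- quantile(x[g == l], c(0.25, 0.5, 0.75), na.rm = TRUE)
      sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
    }, character(1))
    if (nlevels(g) == 2) {
      x1 <- x[g == lev[1]]; x2 <- x[g == lev[2]]
      use_exact <- (length(x1) + length(x2) <= 20) && !anyDuplicated(c(x1, x2))
      wt <- suppressWarnings(wilcox.test(x1, x2, exact = use_exact))
      tibble(variable = var, test = "mann_whitney",
             statistic = unname(wt$statistic), p_value = wt$p.value,
             group1 = summaries[1], group2 = summaries[2])
    } else {
      kt <- kruskal.test(x, g)
      tibble(variable = var, test = "kruskal_wallis",
             statistic = unname(kt$statistic), p_value = kt$p.value,
             group1 = summaries[1], group2 = summaries[2])
    }
  }

  out <- rbind(
    do.call(rbind, lapply(CONTINUOUS_COVARIATES, cont_result)),
    do.call(rbind, lapply(CATEGORICAL_COVARIATES(), cat_result))
  )
  names(out)[names(out) == "group1"] <- lev[1]
  names(out)[names(out) == "group2"] <- lev[2]
  out
}

#' Variable selection and multivariable logistic regression
#'
#' Builds the covariate set as the forced variables (age and sex) plus
#' every screened candidate with univariable p < `p_threshold`, then fits
#' maximum-likelihood logistic regression and reports odds ratios with
#' Wald 95% confidence intervals. Candidates are the categorical
#' covariates (the >20 mm size dichotomy, multiple cysts, and each
#' comorbidity); the continuous cyst size enters only through its
#' dichotomy, matching the multivariable design.
#'
#' @param cohort An [ipmn_cohort()].
#' @param audit The [audit_cohort()] result.
#' @param outcome `"concordant"` (guideline-concordant vs not, on all
#'   classified patients) or `"conservative_vs_liberal"`
#'   (over- vs under-surveillance within the non-concordant subgroup).
#' @param p_threshold Univariable screening threshold (default 0.2).
#' @param age_form `"continuous"` (default) or `"under50"` (dichotomized
#'   below 50 years).
#' @return An object of class `logistic_model_result`: a list with
#'   `outcome`, `n`, `selected` (screened-in variables), and `terms`, a
#'   tibble of (term, odds_ratio, ci_lower, ci_upper, p_value).
#' @export
select_and_fit <- function(cohort, audit,
                           outcome = c("concordant", "conservative_vs_liberal"),
                           p_threshold = 0.2,
                           age_form = c("continuous", "under50")) {
  outcome <- match.arg(outcome)
  age_form <- match.arg(age_form)
  grouping <- if (outcome == "concordant") "concordant_vs_not" else "over_vs_under"

  tab <- covariate_table(cohort, audit)
  gl <- group_labels(tab, grouping)
  tab <- tab[gl$keep, , drop = FALSE]
  y <- if (outcome == "concordant") {
    as.integer(gl$g == "concordant")
  } else {
    as.integer(gl$g == "over")  # conservative = more intensive than advised
  }
  if (length(unique(y)) < 2) {
    stop("outcome '", outcome, "' has a single class; cannot fit")
  }

  screen <- univariable_screen(cohort, audit, grouping)
  candidates <- setdiff(CATEGORICAL_COVARIATES(), c("male", "under_50"))
  sel <- screen$variable[screen$variable %in% candidates &
                         !is.na(screen$p_value) &
                         screen$p_value < p_threshold]

  age_var <- if (age_form == "continuous") "age" else "under_50"
  covars <- unique(c(age_var, "male", sel))
  df <- tab[, covars, drop = FALSE]
  df <- as.data.frame(lapply(df, function(x) if (is.logical(x)) as.integer(x) else x))
  # drop constant columns (non-identifiable), but never the forced ones silently
  keep <- vapply(df, function(x) length(unique(x)) > 1, logical(1))
  dropped <- names(df)[!keep]
  df <- df[, keep, drop = FALSE]
  df$.y <- y

  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (any(abs(cf[-1]) > 15 | se[-1] > 100)) {
    bad <- names(cf[-1])[which.max(abs(cf[-1]))]
    stop("complete separation detected for variable '", bad,
         "': logistic fit did not converge to finite estimates")
  }
  z <- cf / se
  p <- 2 * pnorm(-abs(z))
  ci_l <- exp(cf - qnorm(0.975) * se)
  ci_u <- exp(cf + qnorm(0.975) * se)
  terms <- tibble(
    term = names(cf),
    log_or = unname(cf),
    odds_ratio = exp(unname(cf)),
    ci_lower = unname(ci_l),
    ci_upper = unname(ci_u),
    p_value = unname(p)
  )
  structure(
    list(
      outcome = outcome,
      n = nrow(df),
      selected = sel,
      dropped_constant = dropped,
      terms = terms,
      fit = fit
    ),
    class = "logistic_model_result"
  )
}

#' @export
print.logistic_model_result <- function(x, ...) {
  cat("<logistic_model_result> outcome:", x$outcome, " n =", x$n, "\n")
  cat("  screened in (p < 0.2):",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "none", "\n")
  t <- x$terms[x$terms$term != "(Intercept)", ]
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-22s OR %.2f (95%% CI %.2f-%.2f), p = %.3f\n",
                t$term[i], t$odds_ratio[i], t$ci_lower[i], t$ci_upper[i],
                t$p_value[i]))
  }
  invisible(x)
}
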