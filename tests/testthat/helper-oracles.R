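# Independent oracles. Each re-derives an expected result by a route
# disjoint from the implementation it checks: a straight-line decision
# tree for the rule engine, combinatorial enumeration for the exact tests,
# least squares for the growth rate.

# Straight-line decision tree hard-coding the default policy's thresholds
# and schedule. Deliberately written as one if/else chain, no tables.
kyoto_tree_oracle <- function(size, mpd = NA, nodule_size = NA,
                              nodule_enh = NA, wall = FALSE, abrupt = FALSE,
                              lymph = FALSE, jaundice = FALSE, ca = NA,
                              growth = NA, pancreatitis = FALSE,
                              diabetes = FALSE, fit = TRUE, elapsed = 0) {
  nodule_is_hrs <- !is.na(nodule_size) && isTRUE(nodule_enh) && nodule_size >= 5
  if ((!is.na(mpd) && mpd >= 10) || jaundice || nodule_is_hrs) {
    if (fit) {
      return(list(action = "surgery_referral", modality = "none",
                  interval = NA_real_))
    }
    return(list(action = "eus_surveillance", modality = "eus", interval = 6))
  }
  wf <- 0L
  if (size >= 30) wf <- wf + 1L
  if (!is.na(nodule_size) && !nodule_is_hrs) wf <- wf + 1L
  if (wall) wf <- wf + 1L
  if (!is.na(mpd) && mpd >= 5 && mpd < 10) wf <- wf + 1L
  if (abrupt) wf <- wf + 1L
  if (lymph) wf <- wf + 1L
  if (!is.na(ca) && ca > 37) wf <- wf + 1L
  if (!is.na(growth) && growth > 5) wf <- wf + 1L
  if (pancreatitis) wf <- wf + 1L
  if (diabetes) wf <- wf + 1L
  if (wf >= 1L) {
    return(list(action = "eus_surveillance", modality = "eus", interval = 6))
  }
  if (size < 20) {
    interval <- if (elapsed >= 6) 18 else 6
  } else {
    interval <- if (elapsed >= 6) 12 else 6
  }
  list(action = "imaging_surveillance", modality = "mri_mrcp",
       interval = interval)
}

# Two-sided Fisher exact p for a 2x2 table by summing the probabilities of
# every table with the same margins that is no more probable than the
# observed one (probabilities from binomial coefficients directly).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  x <- max(0, k - n2):min(k, m)
  probs <- choose(m, x) * choose(n2, k - x) / choose(m + n2, k)
  p_obs <- probs[x == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# assignments of the pooled ranks to group 1.
mw_perm_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(n, n1), 2,
              function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  p1 <- if (u_obs > mu) mean(us >= u_obs) else mean(us <= u_obs)
  min(2 * p1, 1)
}

# Least-squares growth slope in mm per 24 months (alternative oracle for
# collinear size series).
ls_growth_oracle <- function(dates, sizes) {
  t_months <- months_between(dates[1], dates)
  unname(coef(lm(sizes ~ t_months))[2]) * 24
}
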