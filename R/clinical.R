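# Clinical validation arm: IHC score aggregation and dichotomization,
# site-positivity tables, contingency tests, rank correlation, and
# Kaplan-Meier / log-rank survival comparisons.

#' Dichotomize an IHC score
#'
#' Scores 0 (no staining) and 1 (faint staining in >10% of epithelial cells)
#' are low expression; 2 (moderate) and 3 (strong) are high.
#'
#' @param score integer vector of IHC scores in `{0,1,2,3}` (NA allowed and
#'   propagated).
#' @return character vector of `"low"` / `"high"`.
#' @export
dichotomize_site <- function(score) {
  ok <- is.na(score) | (score %in% 0:3)
  if (!all(ok))
    ct_validation_error("IHC score outside {0,1,2,3}: %s",
                        paste(unique(score[!ok]), collapse = ", "))
  ifelse(is.na(score), NA_character_, ifelse(score >= 2, "high", "low"))
}

#' Per-patient IHC summaries
#'
#' Averages usable site scores per patient within three compartments (bone,
#' soft tissue, all sites) and dichotomizes each compartment mean with the
#' midpoint rule: mean >= `high_cutoff` (default 1.5, the midpoint of the
#' low/high site boundary) is high. Patients with no usable site in a
#' compartment get an NA mean and class; they are flagged, never dropped.
#'
#' @param ct a `ClinicalTable`.
#' @param high_cutoff compartment-mean cutoff for the high class.
#' @return data frame with one row per patient: compartment means, classes,
#'   treatment flag, and all survival columns.
#' @export
summarize_patients <- function(ct, high_cutoff = 1.5) {
  stopifnot(inherits(ct, "ClinicalTable"))
  s <- ct$sites[ct$sites$usable & !is.na(ct$sites$ihc_score), ]
  mean_by <- function(sub) {
    v <- tapply(sub$ihc_score, sub$patient_id, mean)
    v[match(ct$patients$patient_id, names(v))]
  }
  out <- data.frame(patient_id = ct$patients$patient_id,
                    mean_bone = unname(mean_by(s[s$site_type == "bone", ])),
                    mean_soft = unname(mean_by(s[s$site_type == "soft", ])),
                    mean_all = unname(mean_by(s)),
                    stringsAsFactors = FALSE)
  for (comp in c("bone", "soft", "all")) {
    m <- out[[paste0("mean_", comp)]]
    out[[paste0("class_", comp)]] <-
      ifelse(is.na(m), NA_character_, ifelse(m >= high_cutoff, "high", "low"))
  }
  cbind(out, ct$patients[match(out$patient_id, ct$patients$patient_id),
                         setdiff(names(ct$patients), "patient_id"),
                         drop = FALSE], row.names = NULL)
}

#' Site-level positivity counts and percentages
#'
#' Counts high- and low-scoring usable sites overall and split by
#' compartment (bone vs soft tissue), with percentages rounded to the
#' nearest integer (half away from zero), restricted by default to
#' docetaxel-treated patients.
#'
#' @param ct a `ClinicalTable`.
#' @param treated_only restrict to docetaxel-treated patients (default TRUE).
#' @return data frame with rows `overall`, `bone`, `soft`: `n_sites`,
#'   `n_positive`, `n_negative`, `pct_positive`, `pct_negative`.
#' @export
site_positivity_table <- function(ct, treated_only = TRUE) {
  stopifnot(inherits(ct, "ClinicalTable"))
  s <- ct$sites[ct$sites$usable & !is.na(ct$sites$ihc_score), ]
  if (treated_only) {
    treated <- ct$patients$patient_id[ct$patients$docetaxel_treated]
    s <- s[s$patient_id %in% treated, ]
  }
  if (!nrow(s)) ct_validation_error("no usable sites in the selected cohort")
  n_dropped <- sum(!ct$sites$usable | is.na(ct$sites$ihc_score))
  if (n_dropped > 0)
    message(sprintf("site_positivity_table: %d unusable site(s) excluded", n_dropped))
  cls <- dichotomize_site(s$ihc_score)
  one <- function(sub, lab) {
    n <- nrow(sub)
    pos <- sum(dichotomize_site(sub$ihc_score) == "high")
    data.frame(compartment = lab, n_sites = n, n_positive = pos,
               n_negative = n - pos,
               pct_positive = round_half_away(100 * pos / n),
               pct_negative = round_half_away(100 * (n - pos) / n),
               stringsAsFactors = FALSE)
  }
  rbind(one(s, "overall"),
        one(s[s$site_type == "bone", ], "bone"),
        one(s[s$site_type == "soft", ], "soft"))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)))
    ct_validation_error("fisher_exact needs a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    ct_validation_error("counts must be non-negative integers")
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - r2):min(k, r1)
  probs <- stats::dhyper(support, r1, r2, k)
  pobs <- stats::dhyper(a, r1, r2, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Pearson chi-square test for a 2x2 table
#'
#' `sum((O - E)^2 / E)` on 1 degree of freedom; Yates continuity correction
#' is off by default.
#'
#' @param tab 2x2 matrix of non-negative counts with all margins positive.
#' @param correct apply the continuity correction.
#' @return list with `statistic` and `p.value`.
#' @export
chi_square <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)))
    ct_validation_error("chi_square needs a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    ct_validation_error("chi-square requires all margins > 0")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive their average rank).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return the correlation rho.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) ct_validation_error("x and y lengths differ")
  if (length(x) < 3) ct_validation_error("spearman needs >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ct_validation_error("zero variance in x or y")
  stats::cor(x, y, method = "spearman")
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator via [survival::survfit()]; at tied times events
#' precede censorings (the standard convention). The median survival per
#' group is the first time the curve crosses 0.5, NA when it never does.
#'
#' @param time non-negative durations.
#' @param event logical (or 0/1) event indicators.
#' @param group group label per subject.
#' @return object of class `SurvivalCurve`: a per-group data frame of event
#'   times, at-risk counts, event counts and survival estimates, plus the
#'   per-group medians.
#' @export
km_estimate <- function(time, event, group = rep("all", length(time))) {
  if (any(time < 0)) ct_validation_error("durations must be >= 0")
  group <- as.factor(group)
  if (any(table(group) == 0))
    ct_validation_error("group with zero subjects: '%s'",
                        names(which(table(group) == 0))[1])
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ group)
  st <- summary(fit, censored = TRUE)
  grp <- if (is.null(st$strata)) rep(levels(group)[1], length(st$time))
         else sub("^group=", "", as.character(st$strata))
  curves <- data.frame(group = grp, time = st$time, n_risk = st$n.risk,
                       n_event = st$n.event, n_censor = st$n.censor,
                       surv = st$surv, stringsAsFactors = FALSE)
  smed <- summary(fit)$table
  medians <- if (is.null(dim(smed))) {
    stats::setNames(unname(smed["median"]), levels(group)[1])
  } else {
    stats::setNames(unname(smed[, "median"]), sub("^group=", "", rownames(smed)))
  }
  obj <- list(curves = curves, medians = medians, fit = fit)
  class(obj) <- "SurvivalCurve"
  obj
}

#' Log-rank test between survival groups
#'
#' Score test `(sum(O - E))^2 / Var` with the hypergeometric variance at each
#' event time, via [survival::survdiff()].
#'
#' @inheritParams km_estimate
#' @return list with `statistic`, `df`, `p.value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2) ct_validation_error("log-rank needs >= 2 groups")
  if (any(table(group) == 0))
    ct_validation_error("group with zero subjects: '%s'",
                        names(which(table(group) == 0))[1])
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p.value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Clinical validation statistics for a cohort
#'
#' Runs the full validation arm on a `ClinicalTable`: positivity table,
#' bone-vs-soft Fisher and chi-square association of site positivity,
#' Spearman correlation of the per-patient mean bone score with each
#' survival duration, and Kaplan-Meier / log-rank comparisons of the
#' bone-compartment high vs low classes from each baseline.
#'
#' @param ct a `ClinicalTable`.
#' @param treated_only restrict to docetaxel-treated patients.
#' @return list with `positivity`, `site_association`, `summaries`,
#'   `correlations`, `survival` (per baseline: log-rank result, medians, KM
#'   curves), and a flat `stats` data frame ready for writing.
#' @export
clinical_validation <- function(ct, treated_only = TRUE) {
  stopifnot(inherits(ct, "ClinicalTable"))
  pos <- site_positivity_table(ct, treated_only = treated_only)
  tab2 <- matrix(c(pos$n_positive[pos$compartment == "bone"],
                   pos$n_negative[pos$compartment == "bone"],
                   pos$n_positive[pos$compartment == "soft"],
                   pos$n_negative[pos$compartment == "soft"]),
                 2, 2, byrow = TRUE,
                 dimnames = list(c("bone", "soft"), c("high", "low")))
  assoc <- list(fisher_p = fisher_exact(tab2),
                chisq = tryCatch(chi_square(tab2),
                                 cointf_validation_error = function(e) NULL))
  sm <- summarize_patients(ct)
  if (treated_only) sm <- sm[sm$docetaxel_treated, ]

  rows <- list()
  corr <- list(); surv <- list()
  for (b in ct$baselines) {
    tcol <- paste0("time_", b); ecol <- paste0("event_", b)
    keep <- !is.na(sm$mean_bone)
    rho <- if (sum(keep) >= 3 && stats::sd(sm$mean_bone[keep]) > 0 &&
               stats::sd(sm[[tcol]][keep]) > 0)
      spearman(sm$mean_bone[keep], sm[[tcol]][keep]) else NA_real_
    corr[[b]] <- rho
    cls <- sm$class_bone[keep]
    lr <- if (length(unique(cls)) >= 2)
      logrank_test(sm[[tcol]][keep], sm[[ecol]][keep], cls) else NULL
    km <- if (length(unique(cls)) >= 2)
      km_estimate(sm[[tcol]][keep], sm[[ecol]][keep], cls) else NULL
    surv[[b]] <- list(logrank = lr, km = km)
    rows[[b]] <- data.frame(
      baseline = b, spearman_rho = rho,
      logrank_chisq = if (is.null(lr)) NA_real_ else lr$statistic,
      logrank_p = if (is.null(lr)) NA_real_ else lr$p.value,
      median_high = if (is.null(km)) NA_real_ else unname(km$medians["high"]),
      median_low = if (is.null(km)) NA_real_ else unname(km$medians["low"]),
      stringsAsFactors = FALSE)
  }
  stats_df <- do.call(rbind, rows)
  rownames(stats_df) <- NULL
  list(positivity = pos, site_association = assoc, summaries = sm,
       correlations = corr, survival = surv, stats = stats_df)
}
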