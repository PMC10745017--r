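#' Outcome indicators evaluated by the validation pipeline
#'
#' Derives the four binary outcomes from a cohort: hospital admission; any
#' oxygen therapy (low-flow cannula or above); respiratory support in the
#' strict sense (high-flow cannula or above, excluding low-flow cannula);
#' and the top tier, nCPAP/nBiPAP/invasive ventilation — the rule-out target
#' of the score.
#'
#' @param cohort validated cohort data frame.
#' @return Data frame of logical columns \code{admission},
#'   \code{oxygen_therapy}, \code{respiratory_support}, \code{ncpap_bipap_mv}.
#' @export
cohort_outcomes <- function(cohort) {
  data.frame(
    admission = cohort$admitted %in% c(1, TRUE),
    oxygen_therapy = cohort$oxygen_therapy %in% c(1, TRUE),
    respiratory_support = cohort$support_tier %in% c("hfnc", "ncpap_bipap_mv"),
    ncpap_bipap_mv = cohort$support_tier == "ncpap_bipap_mv"
  )
}

.survival_outcomes <- c("respiratory_support", "ncpap_bipap_mv")

#' Run the full score-validation analysis on a cohort
#'
#' Scores every infant, then produces the complete validation report:
#' cohort descriptives; per-support-group comparisons (no support /
#' LFNC-HFNC / nCPAP-nBiPAP-MV, Kruskal-Wallis for quantitative and
#' chi-square or Fisher for categorical variables); for each of the four
#' outcomes a confusion matrix at the cutoff, sensitivity, specificity,
#' predictive values and the empirical ROC with DeLong interval; and, for
#' the two respiratory-support outcomes, Kaplan-Meier event-free survival of
#' the high- and low-score groups within the horizon, compared by the
#' log-rank test.  An outcome with no positives or no negatives is reported
#' as not evaluable, not an error.
#'
#' Event-free infants are right-censored at \code{min(followup_h,
#' horizon_h)}; an event beyond the horizon counts as censored at the
#' horizon.  Times are clocked from the record's time origin (the emergency-
#' department assessment in the packaged simulator).
#'
#' @param cohort cohort data frame (validated on the way in).
#' @param cutoff high-risk threshold in score points (default 3.5).
#' @param horizon_h survival horizon in hours (default 24).
#' @param consolidation_policy passed to \code{\link{score_cohort}}.
#' @param provenance list describing where the cohort came from.
#' @return An object of class \code{"validation_report"}; all proportions at
#'   full precision (percentages are rounded only by
#'   \code{\link{write_report}}).
#' @seealso [write_report()], [check_report()], [run_all()]
#' @export
run_validation <- function(cohort, cutoff = 3.5, horizon_h = 24,
                           consolidation_policy = "additive",
                           provenance = list(input = "unspecified")) {
  validate_cohort(cohort)
  check_number(cutoff, "cutoff", 0, Inf)
  check_number(horizon_h, "horizon_h", 1e-12, Inf)
  scored <- score_cohort(cohort, consolidation_policy, cutoff)
  outcomes <- cohort_outcomes(scored)

  summary <- .cohort_summary(scored, outcomes)
  comparisons <- .group_comparisons(scored)

  accuracy <- lapply(names(outcomes), function(nm) {
    y <- outcomes[[nm]]
    if (!any(y) || all(y)) {
      return(list(outcome = nm, evaluable = FALSE,
                  reason = sprintf("no outcome-%s observations",
                                   if (any(y)) "negative" else "positive")))
    }
    cm <- confusion_at_cutoff(scored$luscab_total, y, cutoff)
    roc <- roc_auc(scored$luscab_total, y)
    list(outcome = nm, evaluable = TRUE,
         n_pos = sum(y), n_neg = sum(!y),
         confusion = cm, stats = diagnostic_stats(cm),
         auc = roc$auc, auc_ci_low = roc$auc_ci_low,
         auc_ci_high = roc$auc_ci_high)
  })
  names(accuracy) <- names(outcomes)

  surv <- lapply(.survival_outcomes, function(nm) {
    .survival_comparison(scored, outcomes[[nm]], horizon_h)
  })
  names(surv) <- .survival_outcomes

  provenance$cutoff <- cutoff
  provenance$horizon_h <- horizon_h
  provenance$consolidation_policy <- consolidation_policy
  provenance$package_version <-
    as.character(utils::packageVersion("luscab"))

  structure(list(cohort_summary = summary, group_comparisons = comparisons,
                 accuracy_by_outcome = accuracy, survival = surv,
                 provenance = provenance),
            class = "validation_report")
}

.cohort_summary <- function(scored, outcomes) {
  # a degenerate cohort (constant saturation or score) yields rho = NA; the
  # warning is already encoded in the missing value
  corr <- suppressWarnings(
    spearman_correlation(scored$sao2_room_air, scored$luscab_total)
  )
  tiers <- table(factor(scored$support_tier, levels = .support_tiers))
  list(
    n = nrow(scored),
    age_months = summarize_numeric(scored$age_months),
    p_age_lt_1mo = mean(scored$age_months < 1),
    p_male = mean(scored$sex == "male"),
    wdf = summarize_numeric(scored$wdf_total),
    luscab = summarize_numeric(scored$luscab_total),
    sao2 = summarize_numeric(scored$sao2_room_air, "mean_sd"),
    p_admitted = mean(outcomes$admission),
    p_oxygen_therapy = mean(outcomes$oxygen_therapy),
    p_respiratory_support = mean(outcomes$respiratory_support),
    p_ncpap_bipap_mv = mean(outcomes$ncpap_bipap_mv),
    tier_counts = as.list(tiers),
    sao2_luscab_spearman = corr
  )
}

# Table-4 analogue: three columns, low-flow and high-flow cannula merged.
.support_group <- function(tier) {
  factor(ifelse(tier == "none", "no_support",
                ifelse(tier == "ncpap_bipap_mv", "ncpap_bipap_mv", "lfnc_hfnc")),
         levels = c("no_support", "lfnc_hfnc", "ncpap_bipap_mv"))
}

.group_comparisons <- function(scored) {
  g <- droplevels(.support_group(scored$support_tier))
  cat_table <- function(flag) {
    t <- table(factor(flag, levels = c(TRUE, FALSE)), g)
    matrix(as.integer(t), nrow = 2, dimnames = dimnames(t))
  }
  # a degenerate cohort (single support group, constant variable) makes a
  # comparison unevaluable, not an error
  safely <- function(variable_name, expr) {
    tryCatch(suppressWarnings(expr), error = function(e) {
      list(variable_name = variable_name, evaluable = FALSE,
           reason = conditionMessage(e))
    })
  }
  list(
    sex_male = safely("sex_male",
                      compare_categorical(cat_table(scored$sex == "male"),
                                          "sex_male")),
    age_lt_1mo = safely("age_lt_1mo",
                        compare_categorical(cat_table(scored$age_months < 1),
                                            "age_lt_1mo")),
    admitted = safely("admitted",
                      compare_categorical(cat_table(scored$admitted %in% c(1, TRUE)),
                                          "admitted")),
    sao2_room_air = safely("sao2_room_air",
                           compare_groups(scored$sao2_room_air, g, "sao2_room_air")),
    wdf_total = safely("wdf_total",
                       compare_groups(scored$wdf_total, g, "wdf_total")),
    luscab_total = safely("luscab_total",
                          compare_groups(scored$luscab_total, g, "luscab_total"))
  )
}

# Per-outcome Kaplan-Meier comparison between cutoff-defined groups.
.survival_comparison <- function(scored, outcome, horizon_h) {
  event_time <- ifelse(outcome & !is.na(scored$time_to_support_h),
                       scored$time_to_support_h, Inf)
  censor_time <- pmin(scored$followup_h, horizon_h)
  event <- is.finite(event_time) & event_time <= horizon_h
  time_h <- ifelse(event, event_time, censor_time)

  one_group <- function(sel) {
    if (!any(sel)) return(NULL)
    est <- km_fit(time_h[sel], event[sel])
    list(n = sum(sel), n_events = sum(event[sel]), km = est,
         survival_at_horizon = km_survival_at(est, horizon_h))
  }
  high <- one_group(scored$high_risk)
  low <- one_group(!scored$high_risk)
  evaluable <- !is.null(high) && !is.null(low) && sum(event) > 0
  logrank <- if (evaluable) {
    logrank_test(time_h[scored$high_risk], event[scored$high_risk],
                 time_h[!scored$high_risk], event[!scored$high_risk])
  } else NULL
  list(horizon_h = horizon_h, evaluable = evaluable,
       high_risk = high, low_risk = low, logrank = logrank)
}

#' @export
print.validation_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("Validation report: n = %d, cutoff %.1f points\n",
              cs$n, x$provenance$cutoff))
  cat(sprintf("  LUSCAB median %.2f (IQR %.2f-%.2f)\n",
              cs$luscab$median, cs$luscab$q1, cs$luscab$q3))
  for (a in x$accuracy_by_outcome) {
    if (!isTRUE(a$evaluable)) {
      cat(sprintf("  %s: not evaluable (%s)\n", a$outcome, a$reason))
    } else {
      cat(sprintf(
        "  %s: AUC %.2f (%.2f-%.2f), Se %.1f%%, Sp %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
        a$outcome, a$auc, a$auc_ci_low, a$auc_ci_high,
        100 * a$stats$sensitivity, 100 * a$stats$specificity,
        100 * a$stats$ppv, 100 * a$stats$npv))
    }
  }
  for (nm in names(x$survival)) {
    s <- x$survival[[nm]]
    if (isTRUE(s$evaluable)) {
      cat(sprintf(
        "  %s within %gh: event-free %.1f%% (>=cutoff) vs %.1f%%, log-rank p = %.3f\n",
        nm, s$horizon_h, 100 * s$high_risk$survival_at_horizon,
        100 * s$low_risk$survival_at_horizon, s$logrank$p_value))
    }
  }
  invisible(x)
}

# --- serialization ---------------------------------------------------------

pct <- function(p) if (is.null(p) || is.na(p)) NA_real_ else round_half_away(100 * p, 1)

.serialize_comparison <- function(gc) {
  if (!inherits(gc, "group_comparison")) {
    return(list(variable = gc$variable_name, evaluable = FALSE,
                reason = gc$reason))
  }
  list(variable = gc$variable_name, groups = as.list(gc$groups),
       summaries = gc$summaries, test = gc$test_name,
       statistic = gc$statistic, p_value = gc$p_value)
}

.serialize_accuracy <- function(a) {
  if (!isTRUE(a$evaluable)) {
    return(list(outcome = a$outcome, evaluable = FALSE, reason = a$reason))
  }
  list(outcome = a$outcome, evaluable = TRUE,
       n_pos = a$n_pos, n_neg = a$n_neg,
       confusion = list(tp = a$confusion$tp, fp = a$confusion$fp,
                        tn = a$confusion$tn, fn = a$confusion$fn),
       sensitivity_pct = pct(a$stats$sensitivity),
       specificity_pct = pct(a$stats$specificity),
       ppv_pct = pct(a$stats$ppv),
       npv_pct = pct(a$stats$npv),
       auc = a$auc, auc_ci_low = a$auc_ci_low, auc_ci_high = a$auc_ci_high)
}

.serialize_survival <- function(s) {
  grp <- function(g) {
    if (is.null(g)) return(NULL)
    list(n = g$n, n_events = g$n_events,
         event_times_h = g$km$event_times,
         survival = g$km$survival,
         at_risk = g$km$at_risk,
         n_events_at = g$km$n_events,
         event_free_at_horizon_pct = pct(g$survival_at_horizon))
  }
  out <- list(horizon_h = s$horizon_h, evaluable = s$evaluable,
              high_risk = grp(s$high_risk), low_risk = grp(s$low_risk))
  if (!is.null(s$logrank)) {
    out$logrank <- list(chi_square = s$logrank$chi_square, df = s$logrank$df,
                        p_value = s$logrank$p_value)
  }
  out
}

#' Serialize and write a validation report as JSON
#'
#' \code{serialize_report} converts a \code{\link{run_validation}} result to
#' plain lists ready for JSON: every percentage is put on the 0-100 scale
#' and rounded half away from zero to one decimal (matching the presentation
#' of published accuracy tables); AUCs, p-values and statistics keep full
#' precision; provenance is always carried along.  \code{write_report}
#' writes it to \code{path} (or standard output when \code{path} is
#' \code{NULL}).
#'
#' @param report a \code{"validation_report"}.
#' @param path output file path, or \code{NULL} for standard output.
#' @return \code{serialize_report}: a nested list.  \code{write_report}:
#'   \code{path}, invisibly.
#' @export
serialize_report <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  cs <- report$cohort_summary
  list(
    cohort_summary = list(
      n = cs$n,
      age_months = cs$age_months,
      age_lt_1mo_pct = pct(cs$p_age_lt_1mo),
      male_pct = pct(cs$p_male),
      wdf = cs$wdf,
      luscab = cs$luscab,
      sao2 = cs$sao2,
      admitted_pct = pct(cs$p_admitted),
      oxygen_therapy_pct = pct(cs$p_oxygen_therapy),
      respiratory_support_pct = pct(cs$p_respiratory_support),
      ncpap_bipap_mv_pct = pct(cs$p_ncpap_bipap_mv),
      tier_counts = cs$tier_counts,
      sao2_luscab_spearman = cs$sao2_luscab_spearman
    ),
    group_comparisons = lapply(report$group_comparisons, .serialize_comparison),
    accuracy_by_outcome = lapply(report$accuracy_by_outcome, .serialize_accuracy),
    survival = lapply(report$survival, .serialize_survival),
    provenance = report$provenance
  )
}

#' @rdname serialize_report
#' @export
write_report <- function(report, path = NULL) {
  json <- jsonlite::toJSON(serialize_report(report), auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  if (is.null(path)) {
    cat(json, "\n")
  } else {
    writeLines(json, path)
  }
  invisible(path)
}

#' Check the internal consistency of a validation report
#'
#' Verifies the count and probability identities a correct report must
#' satisfy: for every evaluable outcome, \code{tp + fn} equals the number of
#' outcome-positive infants and \code{fp + tn} the number of negatives; the
#' reported Se/Sp/PPV/NPV equal the ratios recomputed from the counts (to
#' 1e-12); PPV and NPV satisfy the Bayes identities implied by Se, Sp and
#' the group sizes; the AUC lies inside its confidence interval and in
#' \code{[0, 1]}; survival curves are proportions, non-increasing; and
#' provenance is present.
#'
#' @param report a \code{"validation_report"}.
#' @return \code{TRUE}, invisibly; any violated identity raises an error.
#' @export
check_report <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  tol <- 1e-12
  for (a in report$accuracy_by_outcome) {
    if (!isTRUE(a$evaluable)) next
    cm <- a$confusion
    stopifnot(cm$tp + cm$fn == a$n_pos, cm$fp + cm$tn == a$n_neg)
    st <- a$stats
    ratio_ok <- function(v, num, den) {
      if (den == 0) is.na(v) else abs(v - num / den) <= tol
    }
    stopifnot(ratio_ok(st$sensitivity, cm$tp, cm$tp + cm$fn),
              ratio_ok(st$specificity, cm$tn, cm$tn + cm$fp),
              ratio_ok(st$ppv, cm$tp, cm$tp + cm$fp),
              ratio_ok(st$npv, cm$tn, cm$tn + cm$fn))
    # Bayes identities linking predictive values to Se/Sp and group sizes
    if (!anyNA(c(st$sensitivity, st$specificity, st$ppv, st$npv))) {
      P <- a$n_pos; N <- a$n_neg
      ppv_b <- st$sensitivity * P / (st$sensitivity * P + (1 - st$specificity) * N)
      npv_b <- st$specificity * N / (st$specificity * N + (1 - st$sensitivity) * P)
      stopifnot(abs(st$ppv - ppv_b) <= tol, abs(st$npv - npv_b) <= tol)
    }
    stopifnot(a$auc >= 0, a$auc <= 1,
              a$auc_ci_low <= a$auc + tol, a$auc_ci_high >= a$auc - tol)
  }
  for (s in report$survival) {
    for (g in list(s$high_risk, s$low_risk)) {
      if (is.null(g)) next
      surv <- g$km$survival
      stopifnot(all(surv >= 0), all(surv <= 1),
                !is.unsorted(rev(surv)),
                g$survival_at_horizon >= 0, g$survival_at_horizon <= 1)
    }
  }
  stopifnot(!is.null(report$provenance),
            !is.null(report$provenance$package_version))
  invisible(TRUE)
}

#' Simulate a cohort and run the full validation end to end
#'
#' Generates a synthetic cohort from the calibrated latent-severity model,
#' scores it, runs the complete validation analysis, and optionally writes
#' the cohort CSV and the JSON report.  This is the one-call (and
#' command-line \code{run-all}) entry point for the fully synthetic demo.
#'
#' @param n cohort size (default 50).
#' @param seed simulation seed (default 1).
#' @param config cohort model configuration.
#' @param cutoff,horizon_h,consolidation_policy passed to
#'   \code{\link{run_validation}}.
#' @param cohort_csv optional path for the simulated cohort CSV.
#' @param report_path optional path for the JSON report.
#' @return The \code{"validation_report"}, invisibly.
#' @export
#' @examples
#' report <- run_all(n = 50, seed = 1)
#' report$accuracy_by_outcome$ncpap_bipap_mv$auc
run_all <- function(n = 50, seed = 1, config = default_study_config(),
                    cutoff = 3.5, horizon_h = 24,
                    consolidation_policy = "additive",
                    cohort_csv = NULL, report_path = NULL) {
  cohort <- generate_cohort(config, n = n, seed = seed)
  if (!is.null(cohort_csv)) write_cohort_csv(cohort, cohort_csv)
  report <- run_validation(
    cohort, cutoff = cutoff, horizon_h = horizon_h,
    consolidation_policy = consolidation_policy,
    provenance = list(input = "simulated", n = n, seed = seed)
  )
  check_report(report)
  if (!is.null(report_path)) write_report(report, report_path)
  invisible(report)
}
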