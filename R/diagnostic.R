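#' Confusion matrix at a score cutoff
#'
#' Cross-tabulates test positivity (score at or above the cutoff) against a
#' binary outcome.
#'
#' @param scores numeric score values.
#' @param outcomes logical (or 0/1) outcome indicator, same length.
#' @param cutoff decision threshold; test-positive means \code{score >= cutoff}.
#' @return An object of class \code{"confusion_matrix"}: a list with integer
#'   counts \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @export
#' @examples
#' confusion_at_cutoff(c(5, 4, 3, 1), c(TRUE, TRUE, FALSE, FALSE), 3.5)
confusion_at_cutoff <- function(scores, outcomes, cutoff) {
  if (length(scores) == 0) stop_invalid("'scores' must be non-empty")
  outcomes <- as_flag(outcomes, "outcomes")
  if (length(scores) != length(outcomes)) {
    stop_invalid("'scores' and 'outcomes' must have the same length")
  }
  check_number(scores, "scores")
  check_number(cutoff, "cutoff")
  pos <- scores >= cutoff
  confusion_matrix(tp = sum(pos & outcomes), fp = sum(pos & !outcomes),
                   tn = sum(!pos & !outcomes), fn = sum(!pos & outcomes))
}

#' @rdname confusion_at_cutoff
#' @param tp,fp,tn,fn non-negative integer counts (at least one positive).
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  for (nm in c("tp", "fp", "tn", "fn")) {
    check_number(get(nm), nm, 0, Inf, integer = TRUE)
  }
  if (tp + fp + tn + fn < 1) stop_invalid("confusion matrix is empty")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test+", "test-"), c("event", "no event")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and predictive values
#'
#' Computes Se = tp/(tp+fn), Sp = tn/(tn+fp), PPV = tp/(tp+fp) and
#' NPV = tn/(tn+fn) from a confusion matrix.  A ratio with a zero denominator
#' is reported as \code{NA} (missing), never as 0.
#'
#' @param cm a \code{\link{confusion_matrix}}.
#' @return An object of class \code{"diagnostic_stats"}: a list with
#'   \code{sensitivity}, \code{specificity}, \code{ppv}, \code{npv}, all
#'   proportions in \code{[0, 1]} or \code{NA}.
#' @export
#' @examples
#' diagnostic_stats(confusion_matrix(tp = 7, fp = 15, tn = 27, fn = 1))
diagnostic_stats <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn)
  ), class = "diagnostic_stats")
}

#' Reconstruct a 2x2 table from printed summary statistics
#'
#' Recovers the integer confusion matrix behind a published sensitivity /
#' specificity pair and the two outcome group sizes:
#' \code{tp = round(se * n_pos)}, \code{fn = n_pos - tp},
#' \code{tn = round(sp * n_neg)}, \code{fp = n_neg - tn}, rounding half away
#' from zero.  Used to check the internal consistency of published accuracy
#' tables.  If a printed proportion is farther than half a count from every
#' integer cell, a warning is emitted; the counts are never adjusted
#' silently.
#'
#' @param sensitivity,specificity proportions in \code{[0, 1]}.
#' @param n_pos,n_neg outcome-positive and outcome-negative group sizes.
#' @return A \code{\link{confusion_matrix}}.
#' @export
#' @examples
#' reconstruct_confusion(0.875, 0.643, n_pos = 8, n_neg = 42)
reconstruct_confusion <- function(sensitivity, specificity, n_pos, n_neg) {
  check_number(sensitivity, "sensitivity", 0, 1)
  check_number(specificity, "specificity", 0, 1)
  check_number(n_pos, "n_pos", 0, Inf, integer = TRUE)
  check_number(n_neg, "n_neg", 0, Inf, integer = TRUE)
  tp <- round_half_away(sensitivity * n_pos)
  tn <- round_half_away(specificity * n_neg)
  if (abs(tp - sensitivity * n_pos) > 0.5 + 1e-9 ||
      abs(tn - specificity * n_neg) > 0.5 + 1e-9) {
    warning("printed statistics are inconsistent with any integer table")
  }
  confusion_matrix(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' Empirical ROC curve and AUC with DeLong confidence interval
#'
#' Enumerates the empirical ROC curve of a score against a binary outcome and
#' computes the area under it.  The AUC equals the Mann-Whitney probability:
#' over all (positive, negative) pairs, the fraction with the positive scored
#' higher, counting ties as 1/2.  The 95\% confidence interval uses DeLong's
#' nonparametric variance with a normal approximation, truncated to
#' \code{[0, 1]}.  Curve points are evaluated at thresholds midway between
#' consecutive distinct observed scores, plus sentinels beyond the extremes,
#' so the curve runs from (0, 0) to (1, 1).
#'
#' @inheritParams confusion_at_cutoff
#' @param conf_level confidence level for the AUC interval (default 0.95).
#' @return An object of class \code{"roc_result"}: a list with
#'   \code{thresholds} (decreasing), \code{tpr}, \code{fpr} (both
#'   non-decreasing), \code{auc}, \code{auc_ci_low}, \code{auc_ci_high},
#'   \code{conf_level}, \code{n_pos}, \code{n_neg}.
#' @export
#' @examples
#' roc_auc(c(3, 5, 1, 2, 4), c(TRUE, TRUE, FALSE, FALSE, FALSE))$auc  # 5/6
roc_auc <- function(scores, outcomes, conf_level = 0.95) {
  if (length(scores) == 0) stop_invalid("'scores' must be non-empty")
  outcomes <- as_flag(outcomes, "outcomes")
  if (length(scores) != length(outcomes)) {
    stop_invalid("'scores' and 'outcomes' must have the same length")
  }
  check_number(scores, "scores")
  if (!any(outcomes)) stop_invalid("no outcome-positive observations")
  if (all(outcomes)) stop_invalid("no outcome-negative observations")

  r <- pROC::roc(response = outcomes, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(r, conf.level = conf_level, method = "delong"))
  )

  s <- sort(unique(scores))
  mid <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  thresholds <- c(Inf, rev(mid), -Inf)  # decreasing; curve (0,0) -> (1,1)
  n_pos <- sum(outcomes)
  n_neg <- sum(!outcomes)
  tpr <- vapply(thresholds, function(th) sum(scores >= th & outcomes) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(th) sum(scores >= th & !outcomes) / n_neg,
                numeric(1))

  structure(list(
    thresholds = thresholds, tpr = tpr, fpr = fpr,
    auc = auc,
    auc_ci_low = max(0, min(ci[1], auc)),
    auc_ci_high = min(1, max(ci[3], auc)),
    conf_level = conf_level, n_pos = n_pos, n_neg = n_neg
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d positives, %d negatives\n", x$n_pos, x$n_neg))
  cat(sprintf("AUC %.3f (%g%% CI %.3f-%.3f, DeLong)\n", x$auc,
              100 * x$conf_level, x$auc_ci_low, x$auc_ci_high))
  invisible(x)
}
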