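test_that("confusion_at_cutoff cross-tabulates with an inclusive cutoff", {
  cm <- confusion_at_cutoff(c(5, 4, 3, 1), c(TRUE, TRUE, FALSE, FALSE), 3.5)
  expect_identical(unclass(cm)[c("tp", "fn", "fp", "tn")],
                   list(tp = 2L, fn = 0L, fp = 0L, tn = 2L))
  cm <- confusion_at_cutoff(c(4, 1), c(FALSE, TRUE), 3.5)
  expect_identical(unclass(cm)[c("tp", "fn", "fp", "tn")],
                   list(tp = 0L, fn = 1L, fp = 1L, tn = 0L))
  # boundary: scores equal to the cutoff are test-positive
  cm <- confusion_at_cutoff(rep(3.5, 4), c(TRUE, TRUE, FALSE, FALSE), 3.5)
  expect_identical(cm$fn, 0L)
  expect_identical(cm$tn, 0L)
  expect_error(confusion_at_cutoff(numeric(0), logical(0), 1), "non-empty")
  expect_error(confusion_at_cutoff(1:3, c(TRUE, FALSE), 1), "length")
})

test_that("diagnostic statistics reproduce published accuracy rows", {
  # top-tier ventilation row: 8 events among 50
  st <- diagnostic_stats(confusion_matrix(tp = 7, fp = 15, tn = 27, fn = 1))
  expect_equal(st$sensitivity, 0.875, tolerance = 1e-3)
  expect_equal(st$specificity, 0.643, tolerance = 1e-3)
  expect_equal(st$ppv, 0.318, tolerance = 1e-3)
  expect_equal(st$npv, 0.964, tolerance = 1e-3)
  # admission row: 33 admitted, 17 not
  st <- diagnostic_stats(confusion_matrix(tp = 17, fp = 5, tn = 12, fn = 16))
  expect_equal(st$sensitivity, 0.515, tolerance = 1e-3)
  expect_equal(st$specificity, 0.706, tolerance = 1e-3)
  expect_equal(st$ppv, 0.773, tolerance = 1e-3)
  expect_equal(st$npv, 0.429, tolerance = 1e-3)
  # perfect classifier
  st <- diagnostic_stats(confusion_matrix(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_identical(unlist(unclass(st)), c(sensitivity = 1, specificity = 1,
                                          ppv = 1, npv = 1))
})

test_that("zero denominators give missing values, never zero", {
  st <- diagnostic_stats(confusion_matrix(tp = 0, fp = 3, tn = 4, fn = 0))
  expect_true(is.na(st$sensitivity))
  expect_true(is.na(st$npv) == FALSE)  # tn+fn = 4
  st <- diagnostic_stats(confusion_matrix(tp = 2, fp = 0, tn = 0, fn = 1))
  expect_true(is.na(st$specificity))
})

test_that("Bayes identities link predictive values to Se/Sp and prevalence", {
  set.seed(21)
  for (rep in 1:50) {
    cm <- confusion_matrix(tp = sample(1:40, 1), fp = sample(1:40, 1),
                           tn = sample(1:40, 1), fn = sample(1:40, 1))
    st <- diagnostic_stats(cm)
    P <- cm$tp + cm$fn
    N <- cm$tn + cm$fp
    expect_equal(st$ppv,
                 st$sensitivity * P / (st$sensitivity * P + (1 - st$specificity) * N),
                 tolerance = 1e-12)
    expect_equal(st$npv,
                 st$specificity * N / (st$specificity * N + (1 - st$sensitivity) * P),
                 tolerance = 1e-12)
  }
})

test_that("2x2 reconstruction recovers integer tables from printed stats", {
  cm <- reconstruct_confusion(0.875, 0.643, n_pos = 8, n_neg = 42)
  expect_identical(unclass(cm)[c("tp", "fn", "tn", "fp")],
                   list(tp = 7L, fn = 1L, tn = 27L, fp = 15L))
  cm <- reconstruct_confusion(1, 1, n_pos = 3, n_neg = 5)
  expect_identical(unclass(cm)[c("tp", "fn", "tn", "fp")],
                   list(tp = 3L, fn = 0L, tn = 5L, fp = 0L))
  cm <- reconstruct_confusion(0.667, 0.688, n_pos = 18, n_neg = 32)
  expect_identical(unclass(cm)[c("tp", "fn", "tn", "fp")],
                   list(tp = 12L, fn = 6L, tn = 22L, fp = 10L))
})

test_that("reconstruction round-trips all published accuracy rows to 1e-3", {
  rows <- list(  # se, sp, ppv, npv, n_pos (of 50)
    admission = c(0.515, 0.706, 0.773, 0.429, 33),
    oxygen_therapy = c(0.619, 0.690, 0.590, 0.714, 21),
    respiratory_support = c(0.667, 0.688, 0.546, 0.786, 18),
    ncpap_bipap_mv = c(0.875, 0.643, 0.318, 0.964, 8)
  )
  for (r in rows) {
    cm <- reconstruct_confusion(r[1], r[2], n_pos = r[5], n_neg = 50 - r[5])
    st <- diagnostic_stats(cm)
    expect_lte(abs(st$sensitivity - r[[1]]), 1e-3)
    expect_lte(abs(st$specificity - r[[2]]), 1e-3)
    expect_lte(abs(st$ppv - r[[3]]), 1e-3)
    expect_lte(abs(st$npv - r[[4]]), 1e-3)
    # every published row reconstructs to 22 test-positives
    expect_identical(cm$tp + cm$fp, 22L)
  }
})

test_that("empirical AUC equals the pairwise Mann-Whitney probability", {
  r <- roc_auc(c(3, 5, 1, 2, 4), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$auc, 5 / 6, tolerance = 1e-12)
  # identical score multisets in both classes
  r <- roc_auc(c(1, 2, 3, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(r$auc, 0.5, tolerance = 1e-12)
  # perfect separation
  r <- roc_auc(c(4, 5, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1, tolerance = 1e-12)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "negative")
  expect_error(roc_auc(1:3, c(FALSE, FALSE, FALSE)), "positive")
})

test_that("AUC agrees with brute-force pairs and with the trapezoidal area", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    scores <- round(rnorm(n, 0, 2), sample(0:1, 1))  # induces ties
    outcomes <- runif(n) < 0.5
    if (!any(outcomes) || all(outcomes)) next
    r <- roc_auc(scores, outcomes)
    expect_equal(r$auc, auc_oracle(scores, outcomes), tolerance = 1e-12)
    expect_equal(trapezoid_area(r$fpr, r$tpr), r$auc, tolerance = 1e-12)
    expect_false(is.unsorted(r$tpr))
    expect_false(is.unsorted(r$fpr))
    expect_identical(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_identical(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
    expect_true(r$auc_ci_low <= r$auc && r$auc <= r$auc_ci_high)
  }
})

test_that("the AUC interval matches a hand-coded DeLong computation", {
  set.seed(41)
  scores <- c(rnorm(40, 1), rnorm(60))
  outcomes <- rep(c(TRUE, FALSE), c(40, 60))
  r <- roc_auc(scores, outcomes)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  pos <- scores[outcomes]; neg <- scores[!outcomes]
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  se <- sqrt(var(v10) / length(pos) + var(v01) / length(neg))
  expect_equal(r$auc, mean(v10), tolerance = 1e-12)
  expect_equal(r$auc_ci_low, r$auc - qnorm(0.975) * se, tolerance = 1e-8)
  expect_equal(r$auc_ci_high, r$auc + qnorm(0.975) * se, tolerance = 1e-8)
})

test_that("empirical Se/Sp at a cutoff converge to the analytic values", {
  set.seed(51)
  n <- 1e5
  outcomes <- runif(n) < 0.3
  scores <- rnorm(n, mean = ifelse(outcomes, 1, 0))
  cutoff <- 0.8
  st <- diagnostic_stats(confusion_at_cutoff(scores, outcomes, cutoff))
  expect_equal(st$sensitivity, pnorm(1 - cutoff), tolerance = 0.01)
  expect_equal(st$specificity, pnorm(cutoff), tolerance = 0.01)
})
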