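test_that("WDF totals match hand-summed item points", {
  # all items at their minimum
  expect_identical(wdf_score(wdf_items(0, 0, 25, 100, 0, FALSE)), 0L)
  # all items at their maximum: 3+3+3+1+3+1
  expect_identical(wdf_score(wdf_items(3, 3, 70, 130, 3, TRUE)), 14L)
  # mixed case: 2+1+2 (RR 50)+1 (HR 130)+0+0
  expect_identical(wdf_score(wdf_items(2, 1, 50, 130, 0, FALSE)), 6L)
})

test_that("rate bands close their gaps downward", {
  expect_identical(wdf_score(wdf_items(0, 0, 30, 120, 0, FALSE)), 0L)
  expect_identical(wdf_score(wdf_items(0, 0, 31, 121, 0, FALSE)), 2L)
  expect_identical(wdf_score(wdf_items(0, 0, 45, 100, 0, FALSE)), 1L)
  expect_identical(wdf_score(wdf_items(0, 0, 46, 100, 0, FALSE)), 2L)
  expect_identical(wdf_score(wdf_items(0, 0, 60, 100, 0, FALSE)), 2L)
  expect_identical(wdf_score(wdf_items(0, 0, 61, 100, 0, FALSE)), 3L)
})

test_that("out-of-range ordinal items fail naming the item", {
  expect_error(wdf_items(4, 0, 40, 100, 0, FALSE), "wheezing")
  expect_error(wdf_items(0, -1, 40, 100, 0, FALSE), "retractions")
  expect_error(wdf_items(0, 0, 40, 100, 5, FALSE), "inspiratory_breath_sounds")
})

test_that("WDF score is monotone non-decreasing in every ordinal item", {
  set.seed(11)
  for (rep in 1:25) {
    base <- list(wheezing = sample(0:2, 1), retractions = sample(0:2, 1),
                 respiratory_rate = sample(20:70, 1),
                 heart_rate = sample(90:140, 1),
                 inspiratory_breath_sounds = sample(0:2, 1),
                 cyanosis = FALSE)
    s0 <- wdf_score(do.call(wdf_items, base))
    for (item in c("wheezing", "retractions", "inspiratory_breath_sounds")) {
      up <- base
      up[[item]] <- up[[item]] + 1
      expect_gte(wdf_score(do.call(wdf_items, up)), s0)
    }
    up <- base; up$respiratory_rate <- up$respiratory_rate + 20
    expect_gte(wdf_score(do.call(wdf_items, up)), s0)
    up <- base; up$heart_rate <- up$heart_rate + 40
    expect_gte(wdf_score(do.call(wdf_items, up)), s0)
    up <- base; up$cyanosis <- TRUE
    expect_gte(wdf_score(do.call(wdf_items, up)), s0)
  }
})

test_that("severity bands map totals as published, with 0 folded into mild", {
  expect_equal(as.character(wdf_band(c(0, 2, 3, 4, 7, 8, 14))),
               c("mild", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
  expect_error(wdf_band(15), "total")
  expect_error(wdf_band(-1), "total")
})

test_that("LUSCAB worked examples sum the satisfied item points", {
  expect_identical(luscab_score(3, 2, lus_findings()), 0)
  all_findings <- lus_findings(TRUE, TRUE, TRUE, TRUE)
  expect_identical(luscab_score(0.8, 7, all_findings), 10.5)
  expect_identical(luscab_score(0.8, 7, all_findings, "exclusive_max"), 9.5)
  expect_identical(luscab_score(0.5, 3, lus_findings()), 1.5)
  expect_identical(
    luscab_score(2, 6, lus_findings(posterior_consolidation_large = TRUE)),
    5.5)
  expect_error(luscab_score(-0.1, 2, lus_findings()), "age_months")
})

test_that("LUSCAB totals over all 64 item combinations stay in range", {
  combos <- expand.grid(age_lt_1 = c(FALSE, TRUE), bl = c(FALSE, TRUE),
                        cf = c(FALSE, TRUE), cs = c(FALSE, TRUE),
                        cl = c(FALSE, TRUE), wdf6 = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    lus <- lus_findings(cb$bl, cb$cf, cb$cs, cb$cl)
    age <- if (cb$age_lt_1) 0.5 else 2
    wdf <- if (cb$wdf6) 8L else 2L
    add <- luscab_score(age, wdf, lus, "additive")
    exc <- luscab_score(age, wdf, lus, "exclusive_max")
    # exact half-point arithmetic
    expect_identical(add * 2, round(add * 2))
    expect_identical(exc * 2, round(exc * 2))
    expect_gte(add, 0); expect_lte(add, 10.5)
    expect_gte(exc, 0); expect_lte(exc, 9.5)
    expect_gte(add, exc)
    if (!(cb$cs && cb$cl)) expect_identical(add, exc)
    # hand recomputation from the item table
    expect_identical(add, 1.5 * cb$age_lt_1 + 1.5 * cb$bl + 1 * cb$cf +
                       1 * cb$cs + 3 * cb$cl + 2.5 * cb$wdf6)
  }
  # the two bounds are attained
  expect_identical(luscab_score(0.5, 8, lus_findings(TRUE, TRUE, TRUE, TRUE)),
                   10.5)
})

test_that("high-risk classification is inclusive at the cutoff", {
  expect_identical(classify_high_risk(c(3.5, 3, 10.5)), c(TRUE, FALSE, TRUE))
})

test_that("score_cohort appends scores and rejects inconsistent WDF input", {
  cohort <- make_cohort(2, age_months = c(0.5, 3), wdf_total = c(6, 2),
                        consol_large = c(1, 0))
  scored <- score_cohort(cohort)
  expect_identical(scored$luscab_total, c(7, 0))  # 1.5 + 3 + 2.5 vs nothing
  expect_identical(scored$high_risk, c(TRUE, FALSE))
  expect_identical(scored$wdf_band, c("moderate", "mild"))

  both <- cohort
  both$wdf_wheezing <- c(2, 0); both$wdf_retractions <- c(1, 0)
  both$resp_rate <- c(50, 25); both$heart_rate <- c(130, 100)
  both$wdf_breath_sounds <- 0; both$wdf_cyanosis <- 0
  both$wdf_total <- c(6, 1)  # second row disagrees (items give 0)
  expect_error(score_cohort(both), "row\\(s\\) 2")
})
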