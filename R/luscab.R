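#' Scoreable lung-ultrasound findings
#'
#' The four lung-ultrasound findings that carry points in the LUSCAB score,
#' recorded as pre-adjudicated booleans: more than three B-lines per
#' intercostal space bilaterally in the anterior area, confluent B-lines
#' bilaterally in the anterior area, and one or more posterior subpleural
#' consolidations with largest diameter under / of at least 1 cm.  The two
#' consolidation flags are independent: a chest can harbour both a small and
#' a large consolidation.  A consolidation of exactly 1 cm counts as large
#' (ties go to higher severity, consistent with a rule-out score).
#'
#' @param blines_gt3_bilateral_anterior logical (or 0/1).
#' @param confluent_blines_bilateral_anterior logical (or 0/1).
#' @param posterior_consolidation_small logical (or 0/1): any posterior
#'   consolidation < 1 cm.
#' @param posterior_consolidation_large logical (or 0/1): any posterior
#'   consolidation >= 1 cm.
#' @return An object of class \code{"lus_findings"}; fields may be vectors of
#'   a common length.
#' @export
#' @examples
#' lus_findings(posterior_consolidation_large = TRUE)
lus_findings <- function(blines_gt3_bilateral_anterior = FALSE,
                         confluent_blines_bilateral_anterior = FALSE,
                         posterior_consolidation_small = FALSE,
                         posterior_consolidation_large = FALSE) {
  f <- list(
    blines_gt3_bilateral_anterior =
      as_flag(blines_gt3_bilateral_anterior, "blines_gt3_bilateral_anterior"),
    confluent_blines_bilateral_anterior =
      as_flag(confluent_blines_bilateral_anterior,
              "confluent_blines_bilateral_anterior"),
    posterior_consolidation_small =
      as_flag(posterior_consolidation_small, "posterior_consolidation_small"),
    posterior_consolidation_large =
      as_flag(posterior_consolidation_large, "posterior_consolidation_large")
  )
  n <- max(lengths(f))
  f <- lapply(f, rep_len, n)
  structure(f, class = "lus_findings")
}

# LUSCAB item weights in half-point integer units, so that every total is an
# exact multiple of 0.5 with no floating-point drift.
.luscab_halves <- c(
  age_lt_1mo = 3L,   # 1.5 points
  blines = 3L,       # 1.5
  confluent = 2L,    # 1
  consol_small = 2L, # 1
  consol_large = 6L, # 3
  wdf_ge_6 = 5L      # 2.5
)

#' LUSCAB score
#'
#' Additive prognostic score for acute bronchiolitis combining Lung
#' UltraSound findings, Clinical data (the WDF score) and Age: age under one
#' month scores 1.5 points; >3 B-lines per intercostal space bilaterally
#' (anterior) 1.5; confluent B-lines bilaterally (anterior) 1; one or more
#' posterior consolidations under 1 cm 1; of at least 1 cm 3; and a WDF total
#' of 6 or more 2.5.  Every satisfied item scores, so the range is 0-10.5 in
#' half-point steps.
#'
#' The published item table does not state whether the two consolidation
#' sizes are mutually exclusive.  Under the default \code{"additive"} policy
#' both consolidation items may score together; under \code{"exclusive_max"}
#' only the 3-point item counts when both flags are set (range then 0-9.5).
#'
#' @param age_months age in months (non-negative, decimals allowed).
#' @param wdf_total WDF total score, integer in \code{[0, 14]}.
#' @param lus a \code{\link{lus_findings}} object.
#' @param consolidation_policy \code{"additive"} (default) or
#'   \code{"exclusive_max"}.
#' @return Numeric vector of totals; each an exact multiple of 0.5.
#' @seealso [classify_high_risk()], [score_cohort()]
#' @export
#' @examples
#' luscab_score(0.5, 3, lus_findings())                       # 1.5
#' luscab_score(2, 6, lus_findings(posterior_consolidation_large = TRUE))  # 5.5
luscab_score <- function(age_months, wdf_total, lus,
                         consolidation_policy = c("additive", "exclusive_max")) {
  consolidation_policy <- match.arg(consolidation_policy)
  check_number(age_months, "age_months", 0, Inf)
  check_number(wdf_total, "wdf_total", 0, 14, integer = TRUE)
  if (!inherits(lus, "lus_findings")) {
    lus <- do.call(lus_findings, as.list(lus))
  }
  w <- .luscab_halves
  halves <- w[["age_lt_1mo"]] * (age_months < 1) +
    w[["blines"]] * lus$blines_gt3_bilateral_anterior +
    w[["confluent"]] * lus$confluent_blines_bilateral_anterior +
    w[["consol_small"]] * lus$posterior_consolidation_small +
    w[["consol_large"]] * lus$posterior_consolidation_large +
    w[["wdf_ge_6"]] * (wdf_total >= 6)
  if (consolidation_policy == "exclusive_max") {
    both <- lus$posterior_consolidation_small & lus$posterior_consolidation_large
    halves <- halves - w[["consol_small"]] * both
  }
  as.integer(halves) / 2
}

#' High-risk classification at the prognostic cutoff
#'
#' A LUSCAB total of 3.5 points or more flags the infant as at higher risk of
#' needing respiratory support; below 3.5 is the rule-out side.
#'
#' @param luscab_total non-negative score points.
#' @param cutoff decision threshold in points (default 3.5).
#' @return Logical vector: \code{TRUE} iff \code{luscab_total >= cutoff}.
#' @export
#' @examples
#' classify_high_risk(c(3, 3.5, 10.5))
classify_high_risk <- function(luscab_total, cutoff = 3.5) {
  check_number(luscab_total, "luscab_total", 0, Inf)
  luscab_total >= cutoff
}

#' Score a cohort data frame
#'
#' Appends \code{wdf_total}, \code{wdf_band}, \code{luscab_total} and
#' \code{high_risk} columns to a cohort in the documented CSV schema (see
#' \code{\link{read_cohort_csv}}).  The WDF total is computed from the raw
#' item columns when present; a precomputed \code{wdf_total} column is used
#' when the items are absent.  If both are present and disagree on any row,
#' scoring fails rather than silently preferring one.
#'
#' @param cohort data frame in the cohort schema.
#' @param consolidation_policy passed to \code{\link{luscab_score}}.
#' @param cutoff passed to \code{\link{classify_high_risk}}.
#' @return The input data frame with the four score columns appended.
#' @export
score_cohort <- function(cohort, consolidation_policy = "additive",
                         cutoff = 3.5) {
  has_items <- all(.wdf_item_cols %in% names(cohort))
  has_total <- "wdf_total" %in% names(cohort)
  if (!has_items && !has_total) {
    stop_invalid("cohort has neither the WDF item columns nor 'wdf_total'")
  }
  if (has_items) {
    items <- wdf_items(cohort$wdf_wheezing, cohort$wdf_retractions,
                       cohort$resp_rate, cohort$heart_rate,
                       cohort$wdf_breath_sounds, cohort$wdf_cyanosis)
    total <- wdf_score(items)
    if (has_total) {
      bad <- which(!is.na(cohort$wdf_total) & cohort$wdf_total != total)
      if (length(bad)) {
        stop_invalid("wdf_total disagrees with the WDF item columns on row(s) ",
                     paste(bad, collapse = ", "))
      }
    }
  } else {
    total <- as.integer(check_number(cohort$wdf_total, "wdf_total", 0, 14,
                                     integer = TRUE))
  }
  lus <- lus_findings(cohort$blines_gt3_bilat_ant,
                      cohort$confluent_blines_bilat_ant,
                      cohort$post_consol_small,
                      cohort$post_consol_large)
  cohort$wdf_total <- total
  cohort$wdf_band <- as.character(wdf_band(total))
  cohort$luscab_total <- luscab_score(cohort$age_months, total, lus,
                                      consolidation_policy)
  cohort$high_risk <- classify_high_risk(cohort$luscab_total, cutoff)
  cohort
}

.wdf_item_cols <- c("wdf_wheezing", "wdf_retractions", "resp_rate",
                    "heart_rate", "wdf_breath_sounds", "wdf_cyanosis")
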