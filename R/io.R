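# Cohort CSV schema.  Flags are stored as 0/1 integers so that a write/read
# round trip is lossless.
.cohort_required_cols <- c("patient_id", "age_months", "sex", "sao2_room_air",
                           "blines_gt3_bilat_ant", "confluent_blines_bilat_ant",
                           "post_consol_small", "post_consol_large",
                           "admitted", "oxygen_therapy", "support_tier",
                           "time_to_support_h", "followup_h")
.cohort_flag_cols <- c("wdf_cyanosis", "blines_gt3_bilat_ant",
                       "confluent_blines_bilat_ant", "post_consol_small",
                       "post_consol_large", "admitted", "oxygen_therapy")
.support_tiers <- c("none", "lfnc", "hfnc", "ncpap_bipap_mv")

#' Validate patient records
#'
#' Enforces the patient-record invariants on a cohort data frame: ages,
#' saturations and times in range; sex and support tier from their
#' vocabularies; any support tier implies the oxygen-therapy flag and a
#' recorded time to support; time to support never exceeds follow-up; WDF
#' items within their ordinal ranges; and, when both the WDF item columns and
#' a precomputed \code{wdf_total} are present, agreement between the two.
#' Violations are reported with 1-based row numbers.
#'
#' @param cohort data frame in the cohort schema.
#' @return The cohort, invisibly; invalid rows raise a validation error
#'   listing every offending row and rule.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(.cohort_required_cols, names(cohort))
  if (length(missing_cols)) {
    stop_invalid("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  has_items <- all(.wdf_item_cols %in% names(cohort))
  if (!has_items && !("wdf_total" %in% names(cohort))) {
    stop_invalid("cohort needs either the WDF item columns (",
                 paste(.wdf_item_cols, collapse = ", "),
                 ") or a 'wdf_total' column")
  }

  problems <- character(0)
  flag_rows <- function(bad, msg) {
    if (any(bad, na.rm = TRUE)) {
      problems <<- c(problems,
                     sprintf("%s (row %s)", msg,
                             paste(which(bad), collapse = ", ")))
    }
  }

  flag_rows(is.na(cohort$age_months) | cohort$age_months < 0,
            "age_months must be non-negative")
  flag_rows(!cohort$sex %in% c("male", "female"), "sex must be male or female")
  flag_rows(is.na(cohort$sao2_room_air) | cohort$sao2_room_air < 0 |
              cohort$sao2_room_air > 100, "sao2_room_air must be in [0, 100]")
  flag_rows(!cohort$support_tier %in% .support_tiers,
            paste0("support_tier must be one of ",
                   paste(.support_tiers, collapse = "/")))
  for (col in intersect(.cohort_flag_cols, names(cohort))) {
    flag_rows(!cohort[[col]] %in% c(0, 1, TRUE, FALSE),
              sprintf("%s must be 0/1", col))
  }
  supported <- cohort$support_tier %in% .support_tiers[-1]
  flag_rows(supported & !cohort$oxygen_therapy %in% c(1, TRUE),
            "support_tier other than 'none' requires oxygen_therapy = 1")
  flag_rows(supported & is.na(cohort$time_to_support_h),
            "support_tier other than 'none' requires time_to_support_h")
  flag_rows(!is.na(cohort$time_to_support_h) & cohort$time_to_support_h < 0,
            "time_to_support_h must be non-negative")
  flag_rows(is.na(cohort$followup_h) | cohort$followup_h < 0,
            "followup_h must be non-negative")
  flag_rows(!is.na(cohort$time_to_support_h) &
              cohort$time_to_support_h > cohort$followup_h,
            "time_to_support_h must not exceed followup_h")
  if (has_items) {
    flag_rows(!cohort$wdf_wheezing %in% 0:3, "wdf_wheezing must be 0-3")
    flag_rows(!cohort$wdf_retractions %in% 0:3, "wdf_retractions must be 0-3")
    flag_rows(!cohort$wdf_breath_sounds %in% 0:3, "wdf_breath_sounds must be 0-3")
    flag_rows(is.na(cohort$resp_rate) | cohort$resp_rate < 0,
              "resp_rate must be non-negative")
    flag_rows(is.na(cohort$heart_rate) | cohort$heart_rate < 0,
              "heart_rate must be non-negative")
    if ("wdf_total" %in% names(cohort)) {
      items <- wdf_items(cohort$wdf_wheezing, cohort$wdf_retractions,
                         cohort$resp_rate, cohort$heart_rate,
                         cohort$wdf_breath_sounds, cohort$wdf_cyanosis)
      flag_rows(!is.na(cohort$wdf_total) & cohort$wdf_total != wdf_score(items),
                "wdf_total disagrees with the WDF item columns")
    }
  } else {
    flag_rows(is.na(cohort$wdf_total) | !cohort$wdf_total %in% 0:14,
              "wdf_total must be 0-14")
  }

  if (length(problems)) {
    stop_invalid("invalid cohort:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(cohort)
}

#' Read and write cohort CSV files
#'
#' \code{read_cohort_csv} reads a UTF-8 comma-separated cohort file with a
#' header row into a validated data frame.  The schema requires
#' \code{patient_id}, \code{age_months}, \code{sex}, \code{sao2_room_air},
#' the four ultrasound-finding flags (\code{blines_gt3_bilat_ant},
#' \code{confluent_blines_bilat_ant}, \code{post_consol_small},
#' \code{post_consol_large}), \code{admitted}, \code{oxygen_therapy},
#' \code{support_tier} (\code{none}/\code{lfnc}/\code{hfnc}/
#' \code{ncpap_bipap_mv}), \code{time_to_support_h} (empty when no support)
#' and \code{followup_h}, plus either the six raw WDF clinical columns
#' (\code{wdf_wheezing}, \code{wdf_retractions}, \code{resp_rate},
#' \code{heart_rate}, \code{wdf_breath_sounds}, \code{wdf_cyanosis}) or a
#' precomputed \code{wdf_total}.  Unknown columns are kept but flagged with
#' a warning.  \code{write_cohort_csv} writes the complementary format
#' (missing event times as empty fields), so that write-then-read is the
#' identity.
#'
#' @param path file path.
#' @param cohort validated cohort data frame.
#' @return \code{read_cohort_csv}: the validated data frame.
#'   \code{write_cohort_csv}: \code{path}, invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  known <- c(.cohort_required_cols, .wdf_item_cols, "wdf_total")
  extra <- setdiff(names(cohort), known)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  }
  validate_cohort(cohort)
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
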