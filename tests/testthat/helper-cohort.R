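# Build a minimal valid cohort data frame (wdf_total variant of the schema).
# Defaults give a low-risk, no-support infant; override per patient.
make_cohort <- function(n, age_months = 3, wdf_total = 2,
                        blines = 0, confluent = 0, consol_small = 0,
                        consol_large = 0, admitted = 0, oxygen = 0,
                        tier = "none", time_h = NA_real_, followup_h = 96,
                        sao2 = 96, sex = "male") {
  data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    age_months = rep_len(age_months, n),
    sex = rep_len(sex, n),
    sao2_room_air = rep_len(sao2, n),
    wdf_total = rep_len(wdf_total, n),
    blines_gt3_bilat_ant = rep_len(blines, n),
    confluent_blines_bilat_ant = rep_len(confluent, n),
    post_consol_small = rep_len(consol_small, n),
    post_consol_large = rep_len(consol_large, n),
    admitted = rep_len(admitted, n),
    oxygen_therapy = rep_len(oxygen, n),
    support_tier = rep_len(tier, n),
    time_to_support_h = rep_len(time_h, n),
    followup_h = rep_len(followup_h, n),
    stringsAsFactors = FALSE
  )
}

# Independent log-rank oracle: direct O/E/V tabulation over pooled distinct
# event times, written without reference to the implementation.
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  times <- sort(unique(c(time_a[event_a], time_b[event_b])))
  O <- E <- V <- 0
  for (t in times) {
    n_a <- sum(time_a >= t)
    n_b <- sum(time_b >= t)
    d_a <- sum(time_a == t & event_a)
    d_b <- sum(time_b == t & event_b)
    n <- n_a + n_b
    d <- d_a + d_b
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1) V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Independent AUC oracle: brute force over all (positive, negative) pairs,
# ties counted 1/2.
auc_oracle <- function(scores, outcomes) {
  pos <- scores[outcomes]
  neg <- scores[!outcomes]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Trapezoidal area under an (fpr, tpr) polyline ordered from (0,0) to (1,1).
trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
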