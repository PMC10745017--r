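#' Configuration of the latent-severity cohort model
#'
#' The synthetic generator emulates the marginal and ordinal structure of an
#' emergency-department bronchiolitis cohort of infants under six months.  A
#' single continuous latent severity drives everything: age enters through
#' its logarithm (younger infants are sicker), clinical items are
#' severity-monotone ordinals, ultrasound findings follow per-finding
#' logistic models, the respiratory-support tier is obtained by thresholding
#' a noisy copy of severity, and event times are exponential.
#'
#' The packaged defaults (see \code{\link{default_study_config}}) are
#' calibrated once, with \code{tools/calibrate-generator.R}, so that large
#' cohorts reproduce the study marginals: 60\% male, 22\% under one month,
#' median WDF about 4.5, 66\% admitted, 42\% on any oxygen, 36\% on HFNC or
#' higher, 16\% on nCPAP/nBiPAP/MV, and a LUSCAB score stochastically larger
#' in higher support tiers.
#'
#' @param n cohort size (default 50, the study size).
#' @param seed integer seed for the single random generator.
#' @param age_lognormal \code{c(meanlog, sdlog)} of age in months.
#' @param p_male proportion male.
#' @param severity_age_coefficient effect of centred log-age on latent
#'   severity; negative means younger infants are sicker.
#' @param wdf_severity_loading common loading of latent severity in the
#'   clinical-item models (ordinal probits and vital-sign regressions).
#' @param wdf_cutpoints list of probit cutpoints for the three ordinal items
#'   (\code{wheezing}, \code{retractions}, \code{breath_sounds}).
#' @param lus_severity_loadings list of \code{c(intercept, slope)} logistic
#'   coefficients for the four scoreable ultrasound findings (in CSV column
#'   order) and for cyanosis.
#' @param outcome_thresholds ordered latent-severity thresholds
#'   \code{c(admission, oxygen, hfnc, ncpap)}; crossing a threshold (with
#'   outcome noise) yields the corresponding outcome, so the support tier is
#'   monotone in severity.
#' @param tier_noise_sd,admission_noise_sd standard deviations of the
#'   outcome noise terms.
#' @param time_to_support_rate_per_h exponential hazard (per hour) of support
#'   initiation for infants who reach any support tier.
#' @param followup_h follow-up horizon in hours (default 96); event-free
#'   infants are censored here.
#' @return A validated object of class \code{"cohort_config"}.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n = 50,
                          seed = 1,
                          age_lognormal = c(meanlog = 0.7793, sdlog = 1.009),
                          p_male = 0.60,
                          severity_age_coefficient = -0.8,
                          wdf_severity_loading = 0.45,
                          wdf_cutpoints = list(
                            wheezing = c(-1.3, 0.45, 2.1),
                            retractions = c(-0.6, 0.95, 2.3),
                            breath_sounds = c(0.6, 1.9, 3.0)
                          ),
                          lus_severity_loadings = list(
                            blines_gt3_bilat_ant = c(0.1, 0.4),
                            confluent_blines_bilat_ant = c(-0.8, 0.4),
                            post_consol_small = c(-0.7, 0.3),
                            post_consol_large = c(-2.5, 0.75),
                            cyanosis = c(-4.0, 1.2)
                          ),
                          outcome_thresholds = c(admission = -0.52,
                                                 oxygen = 0.2784,
                                                 hfnc = 0.4943,
                                                 ncpap = 1.3712),
                          tier_noise_sd = 0.5,
                          admission_noise_sd = 0.5,
                          time_to_support_rate_per_h = 1 / 12,
                          followup_h = 96) {
  config <- structure(list(
    n = n, seed = seed, age_lognormal = age_lognormal, p_male = p_male,
    severity_age_coefficient = severity_age_coefficient,
    wdf_severity_loading = wdf_severity_loading,
    wdf_cutpoints = wdf_cutpoints,
    lus_severity_loadings = lus_severity_loadings,
    outcome_thresholds = outcome_thresholds,
    tier_noise_sd = tier_noise_sd,
    admission_noise_sd = admission_noise_sd,
    time_to_support_rate_per_h = time_to_support_rate_per_h,
    followup_h = followup_h
  ), class = "cohort_config")
  validate_cohort_config(config)
  config
}

#' @rdname cohort_config
#' @export
default_study_config <- function() cohort_config()

#' Validate a cohort model configuration
#'
#' Checks all configuration invariants: positive integer size, proportions
#' in \code{[0, 1]}, ordered outcome thresholds
#' (admission \eqn{\le} oxygen \eqn{\le} HFNC \eqn{\le} nCPAP), positive
#' hazard and follow-up, increasing probit cutpoints and complete logistic
#' coefficient pairs.  Called before any sampling.
#'
#' @param config a \code{"cohort_config"}.
#' @return The configuration, invisibly; invalid configurations raise a
#'   validation error.
#' @export
validate_cohort_config <- function(config) {
  check_number(config$n, "n", 1, Inf, integer = TRUE)
  check_number(config$seed, "seed", integer = TRUE)
  check_number(config$age_lognormal, "age_lognormal")
  if (length(config$age_lognormal) != 2 || config$age_lognormal[2] <= 0) {
    stop_invalid("'age_lognormal' must be c(meanlog, sdlog) with sdlog > 0")
  }
  check_number(config$p_male, "p_male", 0, 1)
  check_number(config$severity_age_coefficient, "severity_age_coefficient")
  check_number(config$wdf_severity_loading, "wdf_severity_loading")
  for (nm in c("wheezing", "retractions", "breath_sounds")) {
    cp <- config$wdf_cutpoints[[nm]]
    if (is.null(cp) || length(cp) != 3 || is.unsorted(cp, strictly = TRUE)) {
      stop_invalid(sprintf("'wdf_cutpoints$%s' must be 3 increasing values", nm))
    }
  }
  for (nm in names(config$lus_severity_loadings)) {
    if (length(config$lus_severity_loadings[[nm]]) != 2) {
      stop_invalid(sprintf("'lus_severity_loadings$%s' must be c(intercept, slope)",
                           nm))
    }
  }
  th <- config$outcome_thresholds
  if (length(th) != 4 || is.unsorted(th)) {
    stop_invalid("'outcome_thresholds' must be 4 ordered values ",
                 "(admission <= oxygen <= hfnc <= ncpap)")
  }
  check_number(config$tier_noise_sd, "tier_noise_sd", 0, Inf)
  check_number(config$admission_noise_sd, "admission_noise_sd", 0, Inf)
  check_number(config$time_to_support_rate_per_h, "time_to_support_rate_per_h",
               1e-12, Inf)
  check_number(config$followup_h, "followup_h", 1e-12, Inf)
  invisible(config)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort of patient records from the latent-severity model of
#' \code{\link{cohort_config}}.  Deterministic given the configuration and
#' seed: all draws come from one seeded generator, variable block by
#' variable block over the whole cohort, in this documented order: age; sex;
#' severity noise; ordinal item noises (wheezing, retractions, breath
#' sounds); vital-sign noises (respiratory rate, heart rate); cyanosis;
#' oxygen-saturation noise; the four ultrasound findings in CSV column
#' order; tier noise; admission noise; event-time uniforms.
#'
#' For infants reaching any support tier the time to support initiation is
#' exponential with the configured hazard, truncated to the follow-up window
#' (support, when it happens, happens during the observed course);
#' support-free infants carry no event time and are censored at follow-up.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param n,seed optional overrides of \code{config$n} / \code{config$seed}.
#' @return A data frame in the documented cohort CSV schema (see
#'   \code{\link{read_cohort_csv}}), one row per infant; all records satisfy
#'   the patient-record invariants.
#' @export
#' @examples
#' cohort <- generate_cohort(default_study_config(), n = 10, seed = 7)
#' cohort$support_tier
generate_cohort <- function(config = default_study_config(),
                            n = config$n, seed = config$seed) {
  validate_cohort_config(config)
  check_number(n, "n", 1, Inf, integer = TRUE)

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(seed)
  }

  meanlog <- config$age_lognormal[[1]]
  sdlog <- config$age_lognormal[[2]]
  lam <- config$wdf_severity_loading

  age <- round(stats::rlnorm(n, meanlog, sdlog), 2)
  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  z <- config$severity_age_coefficient * (log(pmax(age, 0.01)) - meanlog) +
    stats::rnorm(n)

  ordinal <- function(cutpoints) {
    lin <- lam * z + stats::rnorm(n)
    findInterval(lin, cutpoints)
  }
  wheezing <- ordinal(config$wdf_cutpoints$wheezing)
  retractions <- ordinal(config$wdf_cutpoints$retractions)
  breath_sounds <- ordinal(config$wdf_cutpoints$breath_sounds)
  resp_rate <- pmin(pmax(round(43 + 9.2 * lam * z + stats::rnorm(n, 0, 7)), 20), 90)
  heart_rate <- pmin(pmax(round(126 + 8.3 * lam * z + stats::rnorm(n, 0, 14)), 80), 220)
  logistic_draw <- function(coefs) {
    as.integer(stats::runif(n) < stats::plogis(coefs[1] + coefs[2] * z))
  }
  cyanosis <- logistic_draw(config$lus_severity_loadings$cyanosis)
  sao2 <- pmin(pmax(round(95.9 - 0.7 * z + stats::rnorm(n, 0, 2.4)), 80), 100)

  lus_cols <- c("blines_gt3_bilat_ant", "confluent_blines_bilat_ant",
                "post_consol_small", "post_consol_large")
  lus <- lapply(lus_cols, function(nm) {
    logistic_draw(config$lus_severity_loadings[[nm]])
  })
  names(lus) <- lus_cols

  th <- config$outcome_thresholds
  u_tier <- z + stats::rnorm(n, 0, config$tier_noise_sd)
  support_tier <- ifelse(u_tier >= th[["ncpap"]], "ncpap_bipap_mv",
                         ifelse(u_tier >= th[["hfnc"]], "hfnc",
                                ifelse(u_tier >= th[["oxygen"]], "lfnc", "none")))
  oxygen_therapy <- as.integer(support_tier != "none")
  v_adm <- z + stats::rnorm(n, 0, config$admission_noise_sd)
  admitted <- as.integer(oxygen_therapy == 1L | v_adm >= th[["admission"]])

  # truncated exponential: support, when required, starts inside follow-up
  rate <- config$time_to_support_rate_per_h
  u_time <- stats::runif(n)
  t_trunc <- -log(1 - u_time * (1 - exp(-rate * config$followup_h))) / rate
  time_to_support_h <- ifelse(oxygen_therapy == 1L, round(t_trunc, 1), NA_real_)

  data.frame(
    patient_id = sprintf("P%0*d", max(3L, nchar(n)), seq_len(n)),
    age_months = age,
    sex = sex,
    sao2_room_air = sao2,
    wdf_wheezing = wheezing,
    wdf_retractions = retractions,
    resp_rate = resp_rate,
    heart_rate = heart_rate,
    wdf_breath_sounds = breath_sounds,
    wdf_cyanosis = cyanosis,
    blines_gt3_bilat_ant = lus$blines_gt3_bilat_ant,
    confluent_blines_bilat_ant = lus$confluent_blines_bilat_ant,
    post_consol_small = lus$post_consol_small,
    post_consol_large = lus$post_consol_large,
    admitted = admitted,
    oxygen_therapy = oxygen_therapy,
    support_tier = support_tier,
    time_to_support_h = time_to_support_h,
    followup_h = config$followup_h,
    stringsAsFactors = FALSE
  )
}
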