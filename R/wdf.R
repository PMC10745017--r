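#' Modified Wood-Downes-Ferres (WDF) clinical items
#'
#' Bundle and validate the six items of the Wood-Downes clinical severity
#' score as modified by Ferres, widely used for respiratory distress in
#' infants.  Wheezing, retractions and inspiratory breath sounds are recorded
#' as ordinal levels 0-3; respiratory and heart rate are recorded as raw
#' measurements (their point contributions are computed by
#' \code{\link{wdf_score}}, not stored); cyanosis is present/absent.
#'
#' @param wheezing ordinal 0-3: none / end expiration / entire expiratory
#'   phase / inspiration and expiration.
#' @param retractions ordinal 0-3: none / subcostal or lower intercostal /
#'   plus supraclavicular and nasal flaring / plus suprasternal.
#' @param respiratory_rate breaths per minute (non-negative integer).
#' @param heart_rate beats per minute (non-negative integer).
#' @param inspiratory_breath_sounds ordinal 0-3: normal / regular and
#'   symmetrical / markedly silent / silent thorax.
#' @param cyanosis logical (or 0/1): cyanosis present.
#'
#' @return An object of class \code{"wdf_items"}: a list with the six
#'   validated fields.  All arguments may be vectors of a common length.
#' @seealso [wdf_score()], [wdf_band()]
#' @export
#' @examples
#' wdf_items(wheezing = 2, retractions = 1, respiratory_rate = 50,
#'           heart_rate = 130, inspiratory_breath_sounds = 0, cyanosis = FALSE)
wdf_items <- function(wheezing, retractions, respiratory_rate, heart_rate,
                      inspiratory_breath_sounds, cyanosis) {
  check_number(wheezing, "wheezing", 0, 3, integer = TRUE)
  check_number(retractions, "retractions", 0, 3, integer = TRUE)
  check_number(respiratory_rate, "respiratory_rate", 0, Inf, integer = TRUE)
  check_number(heart_rate, "heart_rate", 0, Inf, integer = TRUE)
  check_number(inspiratory_breath_sounds, "inspiratory_breath_sounds", 0, 3,
               integer = TRUE)
  cyanosis <- as_flag(cyanosis, "cyanosis")
  n <- max(length(wheezing), length(retractions), length(respiratory_rate),
           length(heart_rate), length(inspiratory_breath_sounds),
           length(cyanosis))
  out <- list(
    wheezing = rep_len(as.integer(wheezing), n),
    retractions = rep_len(as.integer(retractions), n),
    respiratory_rate = rep_len(as.integer(respiratory_rate), n),
    heart_rate = rep_len(as.integer(heart_rate), n),
    inspiratory_breath_sounds = rep_len(as.integer(inspiratory_breath_sounds), n),
    cyanosis = rep_len(cyanosis, n)
  )
  structure(out, class = "wdf_items")
}

# Point bands for raw rates.  The published bands leave exactly 30 breaths/min
# and 120 beats/min unassigned; both gaps are closed downward (<=30 -> 0,
# <=120 -> 0) so a borderline measurement never inflates the score.
wdf_respiratory_rate_points <- function(rate) {
  ifelse(rate <= 30, 0L, ifelse(rate <= 45, 1L, ifelse(rate <= 60, 2L, 3L)))
}

wdf_heart_rate_points <- function(rate) {
  ifelse(rate <= 120, 0L, 1L)
}

#' Total modified Wood-Downes-Ferres score
#'
#' Sums the point contributions of the six items.  Wheezing, retractions and
#' inspiratory breath sounds contribute their ordinal level directly (0-3
#' each); respiratory rate maps to 0-3 points (\eqn{\le}30 / 31-45 / 46-60 /
#' >60 breaths/min), heart rate to 0-1 points (\eqn{\le}120 / >120 beats/min)
#' and cyanosis to 0-1 points, giving a total between 0 and 14.
#'
#' @param items a \code{\link{wdf_items}} object (or a list with the same six
#'   fields, which is validated on the way in).
#' @return Integer vector of totals in \code{[0, 14]}.
#' @export
#' @examples
#' wdf_score(wdf_items(2, 1, 50, 130, 0, FALSE))  # 6
wdf_score <- function(items) {
  if (!inherits(items, "wdf_items")) {
    items <- do.call(wdf_items, items[c("wheezing", "retractions",
                                        "respiratory_rate", "heart_rate",
                                        "inspiratory_breath_sounds",
                                        "cyanosis")])
  }
  total <- items$wheezing + items$retractions +
    wdf_respiratory_rate_points(items$respiratory_rate) +
    wdf_heart_rate_points(items$heart_rate) +
    items$inspiratory_breath_sounds +
    as.integer(items$cyanosis)
  as.integer(total)
}

#' Severity band of a WDF total
#'
#' Maps a total score to the published severity bands: 1-3 mild, 4-7
#' moderate, 8-14 severe.  A total of 0 lies below the printed bands and is
#' mapped to mild (no lower category exists).
#'
#' @param total integer total in \code{[0, 14]}.
#' @return Factor with levels \code{mild}, \code{moderate}, \code{severe}.
#' @export
#' @examples
#' wdf_band(c(0, 2, 7, 8))
wdf_band <- function(total) {
  check_number(total, "total", 0, 14, integer = TRUE)
  bands <- ifelse(total <= 3, "mild", ifelse(total <= 7, "moderate", "severe"))
  factor(bands, levels = c("mild", "moderate", "severe"))
}
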