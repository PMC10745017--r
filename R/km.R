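#' Kaplan-Meier estimate of event-free survival
#'
#' Product-limit estimator of remaining free of respiratory support by time
#' t: \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over the distinct event
#' times, where \eqn{d_i} is the number of events and \eqn{n_i} the number at
#' risk at \eqn{t_i}.  Observations censored at an event time are still at
#' risk for that event time (events precede censorings at ties, the standard
#' convention).  The fit is delegated to \code{survival::survfit}.
#'
#' @param time_h non-negative event or censoring times, in hours.
#' @param event logical (or 0/1): \code{TRUE} if support was initiated at
#'   \code{time_h}, \code{FALSE} if the observation is right-censored there.
#' @return An object of class \code{"km_estimate"}: a list with
#'   \code{event_times} (strictly increasing), \code{survival}
#'   (non-increasing), \code{at_risk}, \code{n_events} (all aligned to
#'   \code{event_times}) and the sample size \code{n}.
#' @seealso [km_survival_at()], [logrank_test()]
#' @export
#' @examples
#' km_fit(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
km_fit <- function(time_h, event) {
  if (length(time_h) == 0) stop_invalid("'time_h' must be non-empty")
  check_number(time_h, "time_h", 0, Inf)
  event <- as_flag(event, "event")
  if (length(event) != length(time_h)) {
    stop_invalid("'time_h' and 'event' must have the same length")
  }
  fit <- survival::survfit(survival::Surv(time_h, event) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  structure(list(
    event_times = fit$time[keep],
    survival = fit$surv[keep],
    at_risk = fit$n.risk[keep],
    n_events = fit$n.event[keep],
    n = length(time_h)
  ), class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, %d event time(s)\n",
              x$n, length(x$event_times)))
  if (length(x$event_times)) {
    print(data.frame(time_h = x$event_times, at_risk = x$at_risk,
                     events = x$n_events, survival = round(x$survival, 4)))
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function evaluation: at an event time the value
#' after the jump is returned; before the first event the survival is 1.
#'
#' @param est a \code{\link{km_fit}} result.
#' @param t non-negative times, in hours.
#' @return Numeric vector of survival proportions.
#' @export
#' @examples
#' est <- km_fit(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
#' km_survival_at(est, c(0, 1.5, 2))  # 1.00 0.75 0.50
km_survival_at <- function(est, t) {
  stopifnot(inherits(est, "km_estimate"))
  check_number(t, "t", 0, Inf)
  if (length(est$event_times) == 0) return(rep(1, length(t)))
  sf <- stats::stepfun(est$event_times, c(1, est$survival), right = FALSE)
  sf(t)
}

#' Log-rank (Mantel-Cox) comparison of two survival curves
#'
#' Two-sample log-rank test: over the pooled distinct event times, the
#' observed minus expected events in the first group are summed with the
#' hypergeometric variance; the statistic \eqn{(\sum O - \sum E)^2 / \sum V}
#' is referred to a chi-square distribution with one degree of freedom.  No
#' continuity correction is applied.  The computation is delegated to
#' \code{survival::survdiff}.
#'
#' @param time_a,event_a times (hours) and event indicators of the first
#'   group, as in \code{\link{km_fit}}.
#' @param time_b,event_b the second group.
#' @return An object of class \code{"logrank_result"}: a list with
#'   \code{chi_square}, \code{df} (= 1) and \code{p_value}.
#' @export
#' @examples
#' logrank_test(c(1, 2), c(TRUE, TRUE), c(24, 24), c(FALSE, FALSE))
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0) {
    stop_invalid("both groups must be non-empty")
  }
  check_number(time_a, "time_a", 0, Inf)
  check_number(time_b, "time_b", 0, Inf)
  event_a <- as_flag(event_a, "event_a")
  event_b <- as_flag(event_b, "event_b")
  if (length(event_a) != length(time_a) || length(event_b) != length(time_b)) {
    stop_invalid("time and event vectors must have the same length")
  }
  if (sum(event_a) + sum(event_b) == 0) {
    stop_invalid("log-rank statistic is undefined with zero events")
  }
  d <- data.frame(time = c(time_a, time_b),
                  event = c(event_a, event_b),
                  group = rep(c("a", "b"), c(length(time_a), length(time_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d,
                           rho = 0)
  chi <- unname(sd$chisq)
  structure(list(chi_square = chi, df = 1L,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}
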