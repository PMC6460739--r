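#' @title Nonparametric estimators for right-censored data
#' @description Product-limit estimators of the event-free survival function,
#'   the censoring survival function and cause-specific cumulative incidence,
#'   computed from the counting processes of a [surv_data()] sample. All three
#'   share the tie convention that events are ordered before censorings at
#'   tied times, so the at-risk set of the censoring estimator at time t
#'   excludes subjects with an event at t. This is the standard convention
#'   that keeps inverse-probability-of-censoring weights well defined.
#' @name estimators
NULL

# Per-distinct-time event/censoring counts, shared by all estimators.
# Returns distinct sorted times, at-risk counts, per-cause event counts and
# censoring counts.
risk_table <- function(x) {
  stopifnot(inherits(x, "surv_data"))
  tt <- sort(unique(x$time))
  n_at_risk <- vapply(tt, function(t) sum(x$time >= t), numeric(1))
  d_cause <- vapply(seq_len(x$n_causes), function(k) {
    vapply(tt, function(t) sum(x$time == t & x$status == k), numeric(1))
  }, numeric(length(tt)))
  d_cause <- matrix(d_cause, nrow = length(tt))
  d_cens <- vapply(tt, function(t) sum(x$time == t & x$status == 0L),
                   numeric(1))
  list(time = tt, n = n_at_risk, d_cause = d_cause,
       d_event = rowSums(d_cause), d_cens = d_cens)
}

#' Kaplan-Meier estimator of event-free survival
#'
#' Product-limit estimate of P(T > t), pooling all causes as "event". On
#' uncensored data it coincides with the empirical survival function.
#'
#' @param x A [surv_data()] sample.
#' @return A [step_function()] for S(t), non-increasing from 1.
#' @examples
#' S <- kaplan_meier(surv_data(c(1, 2, 3), c(0, 1, 1)))
#' eval_step(S, c(1, 2, 3))  # 1, 1/2, 0
#' @export
kaplan_meier <- function(x) {
  rt <- risk_table(x)
  keep <- rt$d_event > 0
  surv <- cumprod(1 - rt$d_event[keep] / rt$n[keep])
  step_function(rt$time[keep], surv, initial_value = 1)
}

#' Reverse Kaplan-Meier estimator of the censoring distribution
#'
#' Kaplan-Meier estimate of G(t) = P(C > t) with the roles of event and
#' censoring exchanged. Because events precede censorings at tied times, the
#' at-risk set at t excludes subjects observed to fail at t.
#'
#' @param x A [surv_data()] sample.
#' @return A [step_function()] for G(t), non-increasing from 1.
#' @examples
#' G <- reverse_kaplan_meier(surv_data(c(1, 2, 3), c(1, 0, 1)))
#' eval_step(G, 2)  # 1/2
#' @export
reverse_kaplan_meier <- function(x) {
  rt <- risk_table(x)
  keep <- rt$d_cens > 0
  # at-risk for censoring excludes same-time events
  n_cens <- rt$n[keep] - rt$d_event[keep]
  surv <- cumprod(1 - rt$d_cens[keep] / n_cens)
  step_function(rt$time[keep], surv, initial_value = 1)
}

#' Aalen-Johansen estimator of cumulative incidence
#'
#' Nonparametric estimate of the absolute risk F_k(t) = P(T <= t, cause = k)
#' in the presence of competing causes. The increment at an event time t is
#' S(t-) d_k(t) / n(t) with S the all-cause Kaplan-Meier, so cause-specific
#' incidences and all-cause survival add exactly to one at every time.
#'
#' @param x A [surv_data()] sample.
#' @param cause Target cause, an integer in `1..x$n_causes`.
#' @return A [step_function()] for F_cause(t), non-decreasing from 0.
#' @examples
#' F1 <- aalen_johansen(surv_data(c(1, 2, 3), c(1, 2, 1)), cause = 1)
#' eval_step(F1, c(1, 3))  # 1/3, 2/3
#' @export
aalen_johansen <- function(x, cause = 1L) {
  cause <- as.integer(cause)
  if (length(cause) != 1L || is.na(cause) || cause < 1L ||
      cause > x$n_causes) {
    stop(sprintf("'cause' must be a single integer in 1..%d", x$n_causes),
         call. = FALSE)
  }
  rt <- risk_table(x)
  keep <- rt$d_event > 0
  tt <- rt$time[keep]
  n <- rt$n[keep]
  d <- rt$d_event[keep]
  dk <- rt$d_cause[keep, cause]
  s_left <- cumprod(c(1, utils::head(1 - d / n, -1L)))  # S(t-)
  inc <- cumsum(s_left * dk / n)
  step_function(tt, inc, initial_value = 0)
}
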