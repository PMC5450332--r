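#' Risk table for a covered/uncovered split
#'
#' For every distinct event time across both groups, the weighted event
#' counts (`d_c`, `d_u`) and weighted at-risk counts (`r_c`, `r_u`) of the
#' covered and uncovered groups. These are the quantities the two-sample
#' log-rank statistic is built from.
#'
#' @param time non-negative observation times.
#' @param status event indicator: 1 = event, 0 = censored.
#' @param covered logical vector: `TRUE` for records in the covered group.
#' @param weights optional positive case weights.
#' @return A data frame with columns `time`, `d_c`, `d_u`, `r_c`, `r_u`,
#'   one row per distinct event time.
#' @export
build_risk_table <- function(time, status, covered, weights = NULL) {
  n <- length(time)
  if (n == 0) stop("no records")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(status) == n, length(covered) == n, length(weights) == n)
  ev_times <- sort(unique(time[status == 1]))
  dc <- du <- rc <- ru <- numeric(length(ev_times))
  for (k in seq_along(ev_times)) {
    t <- ev_times[k]
    at <- time >= t
    ev <- time == t & status == 1
    rc[k] <- sum(weights[at & covered])
    ru[k] <- sum(weights[at & !covered])
    dc[k] <- sum(weights[ev & covered])
    du[k] <- sum(weights[ev & !covered])
  }
  data.frame(time = ev_times, d_c = dc, d_u = du, r_c = rc, r_u = ru)
}

#' Two-sample log-rank statistic
#'
#' The rule-quality measure: the chi-square form `x^2 / y` of the log-rank
#' test between the records covered by a rule and the remaining records.
#' Over the distinct event times `t` of both groups,
#' \deqn{x = \sum_t \left(d_u^t - \frac{r_u^t}{r_c^t + r_u^t}(d_c^t + d_u^t)\right)}
#' \deqn{y = \sum_t \frac{r_c^t r_u^t (d_c^t + d_u^t)(r_c^t + r_u^t - d_c^t - d_u^t)}
#'   {(r_c^t + r_u^t)^2 (r_c^t + r_u^t - 1)}}
#' Terms with total at-risk weight `<= 1` contribute 0 (their denominator is
#' 0 with a 0 numerator), and the statistic is defined as 0 whenever `y = 0`
#' — in particular when either group is empty or no events exist — so that
#' rule quality is totally ordered even for degenerate candidate rules.
#' Weights enter all counts as fractional multiplicities.
#'
#' @inheritParams build_risk_table
#' @return The non-negative statistic; under the null it is approximately
#'   chi-square with 1 degree of freedom.
#' @examples
#' # covered events at times 1, 2; uncovered events at 3, 4
#' logrank_statistic(1:4, rep(1, 4), c(TRUE, TRUE, FALSE, FALSE))
#' @export
logrank_statistic <- function(time, status, covered, weights = NULL) {
  rt <- build_risk_table(time, status, covered, weights)
  d <- rt$d_c + rt$d_u
  r <- rt$r_c + rt$r_u
  keep <- r > 1
  if (!any(keep)) return(0)
  x <- sum(rt$d_u[keep] - rt$r_u[keep] / r[keep] * d[keep])
  y <- sum(rt$r_c[keep] * rt$r_u[keep] * d[keep] * (r[keep] - d[keep]) /
             (r[keep]^2 * (r[keep] - 1)))
  if (y <= 0) return(0)
  x^2 / y
}

# fast path used by the induction loop; same contract as logrank_statistic
.logrank_mask <- function(time, status, covered, weights) {
  .logrank_mask_cpp(as.numeric(time), as.integer(status),
                    as.numeric(weights), as.logical(covered))
}

#' P-value of the log-rank statistic
#'
#' Upper-tail probability of the chi-square distribution with one degree of
#' freedom, the reference distribution of the two-sample log-rank statistic.
#'
#' @param statistic non-negative log-rank statistic(s).
#' @return p-value(s) in `[0, 1]`.
#' @export
logrank_pvalue <- function(statistic) {
  if (any(is.na(statistic)) || any(statistic < 0))
    stop("'statistic' must be non-negative")
  stats::pchisq(statistic, df = 1, lower.tail = FALSE)
}
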