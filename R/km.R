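#' Kaplan-Meier curve objects
#'
#' A `survrules_km` object is a right-continuous step function estimate of a
#' survival function: survival probabilities at the distinct event times of
#' the sample it was fitted on. Before the first event time the curve equals
#' 1; beyond the last stored time it stays at its last value.
#'
#' @param times strictly increasing numeric vector of event times.
#' @param probs survival probabilities aligned with `times`, non-increasing,
#'   in `[0, 1]`.
#' @param n_effective total weight of the records the curve was fitted on.
#' @return An object of class `survrules_km`.
#' @export
km_curve <- function(times, probs, n_effective = NA_real_) {
  times <- as.numeric(times)
  probs <- as.numeric(probs)
  if (length(times) != length(probs))
    stop("'times' and 'probs' must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (length(probs) && (any(probs < -1e-12) || any(probs > 1 + 1e-12)))
    stop("'probs' must lie in [0, 1]")
  if (length(probs) > 1 && any(diff(probs) > 1e-12))
    stop("'probs' must be non-increasing")
  structure(list(times = times, probs = pmin(pmax(probs, 0), 1),
                 n_effective = as.numeric(n_effective)),
            class = "survrules_km")
}

#' Weighted Kaplan-Meier (product-limit) estimate
#'
#' Fits the product-limit estimator on right-censored data. Weights act as
#' fractional multiplicities in both the event and the at-risk counts, so a
#' record with weight 2 is equivalent to two identical unit-weight records.
#' At a time carrying both events and censorings, events are processed first
#' (the censored records are still at risk at that time).
#'
#' @param time non-negative observation times.
#' @param status event indicator: 1 = event, 0 = censored.
#' @param weights optional positive case weights (default all 1).
#' @return A [km_curve()] object with one step per distinct event time.
#' @examples
#' km_fit(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
#' @export
km_fit <- function(time, status, weights = NULL) {
  n <- length(time)
  if (n == 0) stop("no records to estimate a survival curve from")
  if (length(status) != n) stop("'time' and 'status' lengths differ")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(is.na(time)) || any(time < 0)) stop("'time' must be non-negative")
  if (!all(status %in% c(0, 1))) stop("'status' must be 0 or 1")
  if (any(weights <= 0)) stop("'weights' must be positive")

  ord <- order(time)
  time <- time[ord]; status <- status[ord]; weights <- weights[ord]
  total <- sum(weights)

  # at-risk weight just before each distinct time; events counted at the time
  ut <- unique(time)
  d <- vapply(ut, function(t) sum(weights[time == t & status == 1]), 0)
  r <- total - c(0, cumsum(vapply(ut, function(t) sum(weights[time == t]), 0)))[seq_along(ut)]

  ev <- d > 0
  s <- cumprod(1 - d[ev] / r[ev])
  km_curve(ut[ev], s, n_effective = total)
}

#' Evaluate a Kaplan-Meier curve
#'
#' Right-continuous evaluation of the step function: `km_eval(curve, t)` is 1
#' for `t` before the first event time, the probability attached to the
#' latest event time `<= t` otherwise, and the last stored value beyond the
#' last time.
#'
#' @param curve a [km_curve()] object.
#' @param t non-negative evaluation time(s); vectorized.
#' @return Survival probabilities, one per element of `t`.
#' @export
km_eval <- function(curve, t) {
  if (!inherits(curve, "survrules_km")) stop("'curve' must be a survrules_km")
  if (any(is.na(t)) || any(t < 0)) stop("'t' must be non-negative")
  if (length(curve$times) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, curve$times)
  ifelse(idx == 0, 1, curve$probs[pmax(idx, 1)])
}

# left limit S(t-): value just before t; used for the censoring weights
km_eval_left <- function(curve, t) {
  if (length(curve$times) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, curve$times, left.open = TRUE)
  ifelse(idx == 0, 1, curve$probs[pmax(idx, 1)])
}

#' Average several Kaplan-Meier curves
#'
#' Pointwise unweighted arithmetic mean of step functions, evaluated
#' right-continuously. The result is a step function on the union of the
#' input jump times; each covering rule contributes equally.
#'
#' @param curves non-empty list of [km_curve()] objects.
#' @return A [km_curve()] object.
#' @export
average_curves <- function(curves) {
  if (!is.list(curves) || length(curves) == 0)
    stop("'curves' must be a non-empty list of survival curves")
  if (length(curves) == 1) return(curves[[1]])
  times <- sort(unique(unlist(lapply(curves, function(cv) cv$times))))
  if (length(times) == 0)
    return(km_curve(numeric(0), numeric(0),
                    sum(vapply(curves, function(cv) cv$n_effective, 0))))
  probs <- rowMeans(matrix(vapply(curves, function(cv) km_eval(cv, times),
                                  numeric(length(times))),
                           nrow = length(times)))
  km_curve(times, probs,
           n_effective = sum(vapply(curves, function(cv) cv$n_effective, 0)))
}

#' @export
print.survrules_km <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$times), "event times, n_effective =",
      format(x$n_effective), "\n")
  if (length(x$times)) {
    show <- utils::head(data.frame(time = x$times, surv = x$probs), 10)
    print(show, row.names = FALSE)
    if (length(x$times) > 10) cat("... (", length(x$times) - 10, " more)\n", sep = "")
  }
  invisible(x)
}
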