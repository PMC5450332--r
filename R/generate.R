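#' Attribute marginals for the synthetic generator
#'
#' `attr_numeric()` declares a numeric covariate drawn uniformly from
#' `[min, max]`; `attr_nominal()` a nominal covariate drawn from `domain`
#' with probabilities `probs` (uniform by default).
#'
#' @param min,max bounds of the uniform numeric marginal.
#' @param domain character vector of nominal values.
#' @param probs optional sampling probabilities aligned with `domain`.
#' @return An attribute specification used by [generate_survival_data()].
#' @export
attr_numeric <- function(min = 0, max = 1) {
  stopifnot(is.numeric(min), is.numeric(max), min < max)
  list(kind = "numeric", min = min, max = max)
}

#' @rdname attr_numeric
#' @export
attr_nominal <- function(domain, probs = NULL) {
  domain <- as.character(domain)
  stopifnot(length(domain) >= 1)
  if (!is.null(probs)) stopifnot(length(probs) == length(domain), all(probs >= 0))
  list(kind = "nominal", domain = domain, probs = probs)
}

#' Region specification: a rule-shaped hazard region
#'
#' A region is defined by a conjunction of [condition()]s over the declared
#' attributes; records falling in the region draw their latent event time
#' from an exponential distribution with the region's rate. Regions may
#' overlap: the first matching region in the configured order wins.
#'
#' @param conditions list of [condition()] objects.
#' @param rate exponential event rate (events per time unit), `> 0`.
#' @return A region specification used by [generate_survival_data()].
#' @export
region_spec <- function(conditions, rate) {
  stopifnot(is.list(conditions), length(conditions) >= 1,
            is.numeric(rate), rate > 0)
  for (cond in conditions)
    if (!inherits(cond, "survrules_condition"))
      stop("every region condition must be created with condition()")
  list(conditions = conditions, rate = rate)
}

#' Generate a right-censored survival dataset with known region structure
#'
#' Covariates are drawn i.i.d. from the declared marginals; each record's
#' latent event time is exponential with the rate of the first region whose
#' conditions it satisfies (the baseline rate if none matches). Censoring is
#' an independent exponential time: its rate is either given directly
#' (`censoring_rate`), or calibrated so the expected fraction of censored
#' records equals `censoring_fraction` (solving
#' `mean(mu / (lambda_i + mu)) = fraction` over the drawn per-record event
#' rates). The recorded time is the minimum of the two latent times and
#' `status` indicates whether the event came first. Missing values are
#' injected completely at random per attribute at rate `missing_rate`.
#' Everything is reproducible from `seed`.
#'
#' @param n number of records.
#' @param attributes named list of [attr_numeric()] / [attr_nominal()] specs.
#' @param regions ordered list of [region_spec()]s; first match wins.
#' @param baseline_rate exponential event rate outside every region.
#' @param censoring_fraction target fraction of censored records in `[0, 1)`;
#'   0 disables censoring.
#' @param censoring_rate explicit exponential censoring rate; overrides
#'   `censoring_fraction`.
#' @param missing_rate per-attribute probability of a missing value.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `survrules_sim`: `data` (data frame with the
#'   covariates plus `time` and `status`), `region` (integer ground-truth
#'   labels, 0 = baseline), and the generating configuration.
#' @examples
#' sim <- generate_survival_data(
#'   n = 50,
#'   attributes = list(g = attr_nominal(c("lo", "hi"))),
#'   regions = list(region_spec(list(condition("g", "=", "hi")), rate = 2)),
#'   baseline_rate = 0.1, censoring_fraction = 0.3, seed = 7)
#' table(sim$data$status)
#' @export
generate_survival_data <- function(n, attributes, regions = list(),
                                   baseline_rate = 0.1,
                                   censoring_fraction = 0,
                                   censoring_rate = NULL,
                                   missing_rate = 0, seed = NULL) {
  stopifnot(n > 0, baseline_rate > 0, length(attributes) >= 1,
            censoring_fraction >= 0, censoring_fraction < 1,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(names(attributes)) || any(!nzchar(names(attributes))))
    stop("'attributes' must be a named list")
  validate_regions(regions, attributes)
  if (!is.null(seed)) set.seed(seed)

  X <- as.data.frame(lapply(attributes, function(a) {
    if (a$kind == "numeric") stats::runif(n, a$min, a$max)
    else factor(sample(a$domain, n, replace = TRUE, prob = a$probs),
                levels = a$domain)
  }), optional = TRUE)
  names(X) <- names(attributes)

  region <- rep(0L, n)
  rate <- rep(baseline_rate, n)
  for (k in seq_along(regions)) {
    hit <- region == 0L & rule_covers(regions[[k]]$conditions, X)
    region[hit] <- k
    rate[hit] <- regions[[k]]$rate
  }

  event_time <- stats::rexp(n, rate = rate)
  if (is.null(censoring_rate) && censoring_fraction > 0) {
    censoring_rate <- stats::uniroot(
      function(mu) mean(mu / (rate + mu)) - censoring_fraction,
      lower = 1e-12, upper = 1e12, tol = 1e-12)$root
  }
  if (!is.null(censoring_rate)) {
    stopifnot(censoring_rate > 0)
    cens_time <- stats::rexp(n, rate = censoring_rate)
    status <- as.integer(event_time <= cens_time)
    time <- pmin(event_time, cens_time)
  } else {
    status <- rep(1L, n)
    time <- event_time
  }

  if (missing_rate > 0) {
    for (j in seq_along(X)) {
      miss <- stats::runif(n) < missing_rate
      X[[j]][miss] <- NA
    }
  }

  structure(list(
    data = cbind(X, data.frame(time = time, status = status)),
    region = region,
    config = list(n = n, attributes = attributes, regions = regions,
                  baseline_rate = baseline_rate,
                  censoring_fraction = censoring_fraction,
                  censoring_rate = censoring_rate,
                  missing_rate = missing_rate, seed = seed)
  ), class = "survrules_sim")
}

validate_regions <- function(regions, attributes) {
  for (reg in regions) {
    if (!is.list(reg) || is.null(reg$conditions) || is.null(reg$rate))
      stop("every region must be created with region_spec()")
    for (cond in reg$conditions) {
      a <- attributes[[cond$attribute]]
      if (is.null(a))
        stop("region condition uses undeclared attribute '",
             cond$attribute, "'")
      if (cond$op == "=") {
        if (a$kind != "nominal" || !cond$value %in% a$domain)
          stop("no record can match region condition '",
               format_rule(list(cond)), "'")
      } else {
        if (a$kind != "numeric")
          stop("numeric region condition on nominal attribute '",
               cond$attribute, "'")
        satisfiable <- switch(cond$op,
          "<"  = a$min < cond$value,
          ">=" = a$max >= cond$value,
          "in" = cond$value[1] <= a$max && cond$value[2] > a$min)
        if (!satisfiable)
          stop("no record can match region condition '",
               format_rule(list(cond)), "'")
      }
    }
  }
  invisible(TRUE)
}

#' Deterministic hand-written test datasets
#'
#' Small fixed datasets used throughout the unit tests: `"km_basic"` is the
#' five-record product-limit hand-check (events at 1, 3, 5; censorings at
#' 2, 4); `"logrank_pair"` splits four events into two groups of two;
#' `"ibs_mixed"` has 10 records with 4 censorings and two covariates;
#' `"merge_coverage"` has 20 records with one numeric and one nominal
#' attribute (including missing values) for coverage and merging checks.
#'
#' @param name one of `"km_basic"`, `"logrank_pair"`, `"ibs_mixed"`,
#'   `"merge_coverage"`.
#' @return A data frame with `time` and `status` columns (plus covariates
#'   where the fixture has them; `logrank_pair` has a logical `covered`).
#' @export
make_fixture <- function(name) {
  switch(name,
    km_basic = data.frame(time = 1:5, status = c(1L, 0L, 1L, 0L, 1L)),
    logrank_pair = data.frame(time = 1:4, status = 1L,
                              covered = c(TRUE, TRUE, FALSE, FALSE)),
    ibs_mixed = data.frame(
      time = c(1, 2, 2, 3, 4, 5, 6, 7, 8, 10),
      status = c(1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
      age = c(61, 45, 52, 70, 38, 66, 49, 73, 55, 41),
      sex = factor(c("f", "m", "f", "m", "m", "f", "f", "m", "f", "m"))),
    merge_coverage = data.frame(
      time = c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20,
               1, 3, 5, 7, 9, 11, 13, 15, 17, 19),
      status = rep(c(1L, 0L), 10),
      a = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5, 8.5, 9.5,
            NA, 1.0, 2.0, 3.0, 4.0, 5.0, 6.0, 7.0, 8.0, NA),
      g = factor(c("x", "y", "x", "y", "x", NA, "y", "x", "y", "x",
                   "y", "x", "y", "x", NA, "y", "x", "y", "x", "y"),
                 levels = c("x", "y"))),
    stop("unknown fixture: '", name, "'")
  )
}
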