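# Independent oracles and small random-data generators shared by the tests.
# Everything here is deliberately brute-force and kept independent of the
# package's own computation paths.

# random right-censored frame with one nominal and two numeric covariates
random_survival_frame <- function(n, seed, censor_p = 0.3) {
  set.seed(seed)
  data.frame(
    g = factor(sample(c("a", "b"), n, replace = TRUE)),
    x1 = runif(n),
    x2 = round(runif(n, 0, 5)),
    time = round(rexp(n, 0.2), 3),
    status = rbinom(n, 1, 1 - censor_p)
  )
}

# product-limit estimate via survival::survfit (reference implementation)
survfit_probs <- function(time, status, eval_times, weights = NULL) {
  df <- data.frame(time = time, status = status)
  sf <- if (is.null(weights))
    survival::survfit(survival::Surv(time, status) ~ 1, data = df)
  else
    survival::survfit(survival::Surv(time, status) ~ 1, data = df,
                      weights = weights)
  summary(sf, times = eval_times, extend = TRUE)$surv
}

# left limit of a survival::survfit curve at t
survfit_left <- function(time, status, t) {
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  steps <- stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
  # left limit: value of the step function just below t
  vapply(t, function(tt) {
    below <- sf$time < tt
    if (!any(below)) 1 else sf$surv[max(which(below))]
  }, 0)
}

# Brute-force censoring-weighted Brier score at one horizon, written directly
# from the three-branch definition; G given as vectors of its own fit data.
oracle_bs_at <- function(time, status, surv_at_tstar, g_time, g_status, t_star) {
  G_left <- function(t) survfit_left(g_time, 1 - g_status, t)
  n <- length(time)
  vals <- numeric(0)
  for (i in seq_len(n)) {
    s <- surv_at_tstar[i]
    if (time[i] <= t_star && status[i] == 1) {
      g <- G_left(time[i])
      if (g > 0) vals <- c(vals, s^2 / g)
    } else if (time[i] > t_star) {
      g <- G_left(t_star)
      if (g > 0) vals <- c(vals, (1 - s)^2 / g)
    } else {
      vals <- c(vals, 0)
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# Brute-force IBS on the same grid contract: left-rectangle sum over the
# sorted distinct observed times augmented with 0 and max(time).
oracle_ibs <- function(time, status, pred_fun, g_time, g_status) {
  t_max <- max(time)
  grid <- c(0, sort(unique(time[time < t_max])), t_max)
  left <- grid[-length(grid)]
  widths <- diff(grid)
  total <- 0
  for (k in seq_along(left)) {
    s_hat <- vapply(seq_along(time), function(i) pred_fun(i, left[k]), 0)
    bs <- oracle_bs_at(time, status, s_hat, g_time, g_status, left[k])
    if (!is.na(bs)) total <- total + bs * widths[k]
  }
  total / t_max
}

# Uncensored Brier time-average: direct formula, no censoring weights at all
oracle_uncensored_ibs <- function(time, status, pred_fun) {
  stopifnot(all(status == 1))
  t_max <- max(time)
  grid <- c(0, sort(unique(time[time < t_max])), t_max)
  left <- grid[-length(grid)]
  widths <- diff(grid)
  total <- 0
  for (k in seq_along(left)) {
    bs <- mean(vapply(seq_along(time), function(i) {
      s <- pred_fun(i, left[k])
      truth <- as.numeric(time[i] > left[k])
      (truth - s)^2
    }, 0))
    total <- total + bs * widths[k]
  }
  total / t_max
}

# exhaustive best log-rank statistic over all non-empty condition subsets
exhaustive_best_subset <- function(conds, data, time, status) {
  k <- length(conds)
  best <- -Inf
  for (m in seq_len(2^k - 1)) {
    pick <- which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0)
    cov <- rule_covers(conds[pick], data)
    s <- logrank_statistic(time, status, cov)
    if (s > best) best <- s
  }
  best
}

# planted-structure generator configuration used by the recovery checks:
# one dominant binary risk factor among ten noise covariates
planted_config <- function(n = 300, seed = 1, censoring_fraction = 0.3,
                           hazard_ratio = 25) {
  noise <- setNames(replicate(10, attr_numeric(0, 1), simplify = FALSE),
                    paste0("x", 1:10))
  list(
    n = n,
    attributes = c(list(risk = attr_nominal(c("low", "high"))), noise),
    regions = list(region_spec(list(condition("risk", "=", "high")),
                               rate = 0.04 * hazard_ratio)),
    baseline_rate = 0.04,
    censoring_fraction = censoring_fraction,
    seed = seed
  )
}

planted_dataset <- function(n = 300, seed = 1, censoring_fraction = 0.3,
                            hazard_ratio = 25) {
  cfg <- planted_config(n, seed, censoring_fraction, hazard_ratio)
  do.call(generate_survival_data, cfg)
}
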