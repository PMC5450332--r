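#' Censoring survival estimate
#'
#' The inverse-probability-of-censoring weight function G-hat: a Kaplan-Meier
#' estimate fitted on the training records with the censoring status flipped
#' (`1 - status`), so that censorings are the "events". Used to weight the
#' Brier score under right censoring.
#'
#' @inheritParams km_fit
#' @return A [km_curve()] object estimating the censoring survival function.
#' @export
censoring_km <- function(time, status, weights = NULL) {
  km_fit(time, 1 - status, weights)
}

#' Censoring-weighted Brier score of one record
#'
#' The squared difference between the true event status at horizon `t_star`
#' and the predicted survival probability, reweighted by the inverse of the
#' censoring survival estimate `G`:
#' * `(1/G(T-)) * (0 - S(t_star))^2` if the record's event occurred at or
#'   before `t_star` (`time <= t_star`, `status = 1`),
#' * `(1/G(t_star-)) * (1 - S(t_star))^2` if the record is still under
#'   observation (`time > t_star`),
#' * `0` if the record was censored at or before `t_star`.
#'
#' `G` is evaluated as a left limit so a record scored at its own censoring
#' time is not divided by a post-drop value. When the required `G` value is
#' 0 the score is `NA`; such records are excluded from the mean at that
#' horizon.
#'
#' @param time,status observation time and event indicator of the record(s).
#' @param curve predicted survival curve: a single [km_curve()], or a list of
#'   curves (one per record).
#' @param G censoring estimate from [censoring_km()].
#' @param t_star evaluation horizon, `t_star >= 0`.
#' @return Numeric vector of per-record scores (`NA` where the censoring
#'   weight is undefined).
#' @export
brier_score_at <- function(time, status, curve, G, t_star) {
  stopifnot(length(t_star) == 1, t_star >= 0)
  n <- length(time)
  s_hat <- if (inherits(curve, "survrules_km"))
    rep(km_eval(curve, t_star), n)
  else vapply(curve, function(cv) km_eval(cv, t_star), 0)

  g_ti <- km_eval_left(G, time)
  g_ts <- km_eval_left(G, t_star)
  out <- numeric(n)
  ev <- time <= t_star & status == 1
  alive <- time > t_star
  out[ev] <- ifelse(g_ti[ev] > 0, s_hat[ev]^2 / g_ti[ev], NA_real_)
  out[alive] <- if (g_ts > 0) (1 - s_hat[alive])^2 / g_ts else NA_real_
  out
}

# mean Brier score across records at one horizon, dropping undefined weights
bs_mean <- function(time, status, curves, G, t_star) {
  bs <- brier_score_at(time, status, curves, G, t_star)
  if (all(is.na(bs))) return(NA_real_)
  mean(bs, na.rm = TRUE)
}

#' Integrated Brier score
#'
#' Time-averaged censoring-weighted Brier score over the observed follow-up
#' of the test set:
#' \deqn{IBS = \frac{1}{\max T_i} \int_0^{\max T_i} BS(T^\ast)\, dT^\ast}
#' where `BS(T*)` is the mean of the per-record scores. `BS` is a step
#' function between observed times, so the integral is evaluated exactly as a
#' left-rectangle sum over the sorted distinct observed test times augmented
#' with 0 and `max T_i`. Lower is better; 0.25 is the score of a constant
#' one-half prediction without censoring.
#'
#' @param time,status test-set observation times and event indicators.
#' @param predictions predicted survival curves: a list of [km_curve()]
#'   objects (one per record) or a single curve used for every record.
#' @param G censoring estimate from [censoring_km()], fitted on the
#'   corresponding training records.
#' @return The non-negative integrated Brier score.
#' @export
integrated_brier_score <- function(time, status, predictions, G) {
  n <- length(time)
  if (n == 0) stop("empty test set")
  stopifnot(length(status) == n)
  t_max <- max(time)
  if (t_max <= 0) stop("all observation times are zero")
  grid <- c(0, sort(unique(time[time < t_max])), t_max)
  left <- grid[-length(grid)]
  widths <- diff(grid)
  bs <- vapply(left, function(ts) bs_mean(time, status, predictions, G, ts), 0)
  keep <- !is.na(bs)
  sum(bs[keep] * widths[keep]) / t_max
}

#' Censoring-stratified cross-validation folds
#'
#' Partitions records into `k` folds, separately dealing the events and the
#' censored records so every fold preserves the overall event/censoring
#' proportion; remainders are spread one per fold. The schedule is
#' reproducible from `seed`.
#'
#' @param status event indicator of every record.
#' @param k number of folds (>= 2).
#' @param repeats number of independent repetitions.
#' @param seed integer seed.
#' @return A list of length `repeats`; each element is an integer vector
#'   assigning every record to a fold in `1:k`.
#' @export
stratified_cv_folds <- function(status, k = 10, repeats = 10, seed = 1) {
  if (k < 2) stop("'k' must be at least 2")
  n <- length(status)
  if (n < k) stop("fewer records than folds")
  set.seed(seed)
  lapply(seq_len(repeats), function(rep_i) {
    fold <- integer(n)
    for (s in unique(status)) {
      idx <- sample(which(status == s))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    fold
  })
}

#' Cross-validated evaluation of the rule learner
#'
#' Repeated censoring-stratified k-fold cross-validation. Per fold, a rule
#' set is fitted on the training split, survival curves are predicted for
#' the test split, the censoring estimate is fitted on the training split,
#' and the integrated Brier score is computed on the test split. For
#' reference, `ibs_km` scores the default-curve-only predictor (the training
#' Kaplan-Meier estimate applied to every test record) on identical folds.
#' Folds whose training split contains no events are skipped with a warning.
#'
#' @inheritParams survrules
#' @param k folds per repetition (default 10).
#' @param repeats number of repetitions (default 10).
#' @param seed integer seed making the fold schedule reproducible.
#' @return An object of class `survrules_cv`: a list with `folds` (one row
#'   per evaluated fold: `rep`, `fold`, `n_test`, `ibs`, `ibs_km`,
#'   `n_rules`, `mean_rule_length`, `mean_coverage_fraction`,
#'   `fraction_significant`) and `aggregate` (means over folds).
#' @export
cross_validate <- function(formula, data, weights = NULL, mincov = 7,
                           k = 10, repeats = 10, seed = 1) {
  schedule <- NULL
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y) || attr(y, "type") != "right")
    stop("the response must be a right-censored survival::Surv object")
  time <- as.numeric(y[, "time"])
  status <- as.integer(y[, "status"])
  n <- nrow(data)
  if (is.null(weights)) weights <- rep(1, n)
  schedule <- stratified_cv_folds(status, k = k, repeats = repeats,
                                  seed = seed)

  rows <- list()
  for (r in seq_len(repeats)) {
    fold <- schedule[[r]]
    for (f in seq_len(k)) {
      test <- fold == f
      train <- !test
      if (sum(status[train]) == 0) {
        warning("repetition ", r, ", fold ", f,
                ": training split has no events; fold skipped")
        next
      }
      fit <- survrules(formula, data = data[train, , drop = FALSE],
                       weights = weights[train], mincov = mincov)
      G <- censoring_km(time[train], status[train], weights[train])
      preds <- predict(fit, data[test, , drop = FALSE])
      ibs <- integrated_brier_score(time[test], status[test], preds, G)
      ibs_km <- integrated_brier_score(time[test], status[test],
                                       fit$default_curve, G)
      ch <- characterize_ruleset(fit)
      rows[[length(rows) + 1]] <- data.frame(
        rep = r, fold = f, n_test = sum(test), ibs = ibs, ibs_km = ibs_km,
        n_rules = ch$n_rules, mean_rule_length = ch$mean_rule_length,
        mean_coverage_fraction = ch$mean_coverage_fraction,
        fraction_significant = ch$fraction_significant)
    }
  }
  folds <- do.call(rbind, rows)
  aggregate <- as.list(colMeans(folds[, setdiff(names(folds),
                                                c("rep", "fold"))]))
  structure(list(folds = folds, aggregate = aggregate, k = k,
                 repeats = repeats, seed = seed, mincov = mincov),
            class = "survrules_cv")
}

#' @export
print.survrules_cv <- function(x, ...) {
  cat(sprintf("%d x %d-fold censoring-stratified cross-validation (mincov = %s)\n",
              x$repeats, x$k, format(x$mincov)))
  cat(sprintf("  mean IBS (rules):      %.4f\n", x$aggregate$ibs))
  cat(sprintf("  mean IBS (KM default): %.4f\n", x$aggregate$ibs_km))
  cat(sprintf("  mean rules per fold:   %.1f\n", x$aggregate$n_rules))
  invisible(x)
}

#' Characterize a fitted rule set
#'
#' The descriptive statistics used to report rule sets: rule count, mean
#' premise length after interval merging, mean fraction of training records
#' covered per rule, and the fraction of rules significant at 0.05 after
#' Benjamini-Hochberg adjustment of the per-rule log-rank p-values (covered
#' vs uncovered training records).
#'
#' @param object a fitted [survrules()] model.
#' @return A list with `n_rules`, `mean_rule_length`,
#'   `mean_coverage_fraction`, `fraction_significant`, and the vector of
#'   BH-adjusted p-values `p_adjusted`.
#' @export
characterize_ruleset <- function(object) {
  stopifnot(inherits(object, "survrules"))
  p <- vapply(object$rules, function(r) r$p_value, 0)
  p_adj <- stats::p.adjust(p, method = "BH")
  list(
    n_rules = length(object$rules),
    mean_rule_length = mean(vapply(object$rules,
                                   function(r) length(r$conditions), 0)),
    mean_coverage_fraction = mean(vapply(object$rules,
                                         function(r) r$coverage_count, 0)) /
      object$n_effective,
    fraction_significant = mean(p_adj < 0.05),
    p_adjusted = p_adj)
}
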