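#' Fit a survival rule set by separate-and-conquer covering
#'
#' Learns an ordered set of conjunctive survival rules from right-censored
#' data. Rules are added one at a time: each rule is grown greedily by adding
#' the elementary condition that maximizes the two-sample log-rank statistic
#' between the records it covers and the rest of the training set (subject to
#' covering at least `mincov` previously uncovered weight), then pruned by
#' hill-climbing removal of conditions while the statistic strictly improves,
#' and finally its numeric conditions are merged into intervals. Each rule
#' concludes with the Kaplan-Meier curve of its covered records. Induction
#' stops once every training record is covered; a default curve fitted on the
#' whole training set handles records no rule covers at prediction time.
#'
#' Missing covariate values follow the ignored-value strategy: conditions are
#' built from known values only and a record missing a tested attribute is
#' not covered by that rule. With case weights, all event/at-risk counts and
#' the `mincov` constraint are sums of weights. For the final rule the
#' effective constraint is `min(mincov, remaining uncovered weight)` so the
#' covering loop can always terminate with full coverage.
#'
#' @param formula a formula with a [survival::Surv()] right-censored response,
#'   e.g. `Surv(time, status) ~ .`. Nominal attributes are factors or
#'   character columns; everything else is treated as numeric.
#' @param data data frame containing the variables. Missing covariate values
#'   are allowed; missing time or status is an error.
#' @param weights optional positive case weights.
#' @param mincov minimum (weighted) number of previously uncovered records a
#'   new rule must cover; default 7.
#' @param max_conditions optional cap on the number of conditions grown per
#'   rule (default unlimited).
#' @return An object of class `survrules`: a list with `rules` (each with
#'   `conditions`, `conclusion`, `quality`, `quality_grown`,
#'   `coverage_count`, `p_value`), `default_curve`, `attributes`, `mincov`,
#'   `n`, `call` and the training `coverage` matrix.
#' @seealso [predict.survrules()], [summary.survrules()], [cross_validate()]
#' @examples
#' sim <- generate_survival_data(
#'   n = 120,
#'   attributes = list(g = attr_nominal(c("a", "b")), z = attr_numeric(0, 1)),
#'   regions = list(region_spec(list(condition("g", "=", "a")), rate = 1)),
#'   baseline_rate = 0.04, seed = 1)
#' fit <- survrules(survival::Surv(time, status) ~ ., data = sim$data)
#' fit
#' @export
survrules <- function(formula, data, weights = NULL, mincov = 7,
                      max_conditions = Inf) {
  cl <- match.call()
  if (!is.numeric(mincov) || length(mincov) != 1 || mincov <= 0)
    stop("'mincov' must be a single positive number")

  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y) || attr(y, "type") != "right")
    stop("the response must be a right-censored survival::Surv object")
  time <- as.numeric(y[, "time"])
  status <- as.integer(y[, "status"])
  if (any(is.na(time)) || any(is.na(status)))
    stop("missing values in time or status are not allowed")
  if (any(time < 0)) stop("'time' must be non-negative")

  X <- mf[, setdiff(names(mf), names(mf)[1]), drop = FALSE]
  if (ncol(X) == 0) stop("at least one covariate is required")
  X[] <- lapply(X, function(col) {
    if (is.character(col) || is.logical(col)) factor(col) else col
  })

  n <- nrow(X)
  if (n == 0) stop("empty dataset")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(is.na(weights)) || any(weights <= 0))
    stop("'weights' must be positive and match the number of records")

  fit <- fit_survrules(X, time, status, weights, mincov, max_conditions)
  fit$call <- cl
  fit$terms <- stats::terms(mf)
  fit
}

# attribute metadata: named list of list(kind, domain)
attr_meta <- function(X) {
  out <- lapply(X, function(col) {
    if (is.factor(col)) list(kind = "nominal", domain = levels(col))
    else list(kind = "numeric", domain = NULL)
  })
  names(out) <- names(X)
  out
}

# covariates as a numeric matrix for the C++ grower: factor level codes for
# nominal columns, raw values for numeric ones, NA preserved
covariate_matrix <- function(X) {
  m <- vapply(X, function(col) {
    if (is.factor(col)) as.numeric(col) else as.numeric(col)
  }, numeric(nrow(X)))
  matrix(m, nrow = nrow(X), ncol = ncol(X), dimnames = list(NULL, names(X)))
}

# translate one row of the grower's output into a condition object
decode_condition <- function(attr_idx, op_code, value, X, attrs) {
  name <- names(attrs)[attr_idx]
  if (op_code == 1L) {
    if (attrs[[name]]$kind == "nominal")
      condition(name, "=", attrs[[name]]$domain[as.integer(value)])
    else condition(name, "=", value)
  } else if (op_code == 2L) condition(name, "<", value)
  else condition(name, ">=", value)
}

fit_survrules <- function(X, time, status, weights, mincov, max_conditions) {
  attrs <- attr_meta(X)
  Xm <- covariate_matrix(X)
  nominal <- vapply(attrs, function(a) a$kind == "nominal", TRUE)
  n <- nrow(Xm)
  maxc <- if (is.finite(max_conditions)) as.integer(max_conditions) else 0L

  prev_covered <- rep(FALSE, n)
  rules <- list()
  coverage <- NULL

  while (any(!prev_covered)) {
    eff_mincov <- min(mincov, sum(weights[!prev_covered]))
    g <- .grow_rule_cpp(Xm, nominal, time, status, weights, prev_covered,
                        eff_mincov, maxc)
    if (length(g$attr) == 0) {
      if (length(rules) == 0)
        stop("no admissible condition: no candidate covers ", eff_mincov,
             " uncovered weight (records with only missing values cannot ",
             "be covered)")
      warning(sum(!prev_covered), " record(s) cannot be covered by any ",
              "condition and remain outside the rule set")
      break
    }
    conds <- lapply(seq_along(g$attr), function(i)
      decode_condition(g$attr[i], g$op[i], g$value[i], X, attrs))
    quality_grown <- .logrank_mask(time, status, g$covered, weights)

    pr <- prune_conditions(conds, X, time, status, weights)
    merged <- merge_numeric_conditions(pr$conditions)
    covered <- pr$covered

    rule <- structure(list(
      conditions = merged,
      conclusion = km_fit(time[covered], status[covered], weights[covered]),
      quality = pr$quality,
      quality_grown = quality_grown,
      coverage_count = sum(weights[covered]),
      p_value = logrank_pvalue(pr$quality)
    ), class = "survrules_rule")

    rules[[length(rules) + 1]] <- rule
    coverage <- cbind(coverage, covered)
    prev_covered <- prev_covered | covered
  }

  colnames(coverage) <- paste0("rule_", seq_len(ncol(coverage)))
  structure(list(
    rules = rules,
    default_curve = km_fit(time, status, weights),
    attributes = attrs,
    mincov = mincov,
    n = n,
    n_effective = sum(weights),
    coverage = coverage
  ), class = "survrules")
}

# Hill-climbing condition removal: at each step evaluate dropping every
# condition and perform the drop that yields the largest STRICT increase of
# the log-rank statistic; stop when none improves or one condition remains.
prune_conditions <- function(conds, X, time, status, weights) {
  masks <- vapply(conds, function(cn) condition_covers(cn, X),
                  logical(nrow(X)))
  masks <- matrix(masks, nrow = nrow(X))
  pr <- .prune_rule_cpp(masks, as.numeric(time), as.integer(status),
                        as.numeric(weights))
  list(conditions = conds[pr$keep], covered = pr$covered,
       quality = pr$quality)
}

#' @export
print.survrules <- function(x, digits = 4, ...) {
  cat("Survival rule set:", length(x$rules), "rules (mincov =", x$mincov,
      ", n =", x$n, ")\n\n")
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    cat(sprintf("Rule %d: IF %s\n", i, format_rule(r)))
    cat(sprintf("  covers %s records | log-rank = %s | p = %s\n",
                format(r$coverage_count, digits = digits),
                format(r$quality, digits = digits),
                format.pval(r$p_value, digits = digits)))
  }
  invisible(x)
}

#' Summarize a fitted survival rule set
#'
#' Rule-set characterization on the training data: number of rules, mean
#' premise length (after interval merging), mean fraction of training records
#' covered per rule, and the fraction of rules whose log-rank test (covered
#' vs uncovered training records) is significant at 0.05 after
#' Benjamini-Hochberg false-discovery-rate adjustment.
#'
#' @param object a fitted [survrules()] model.
#' @param ... unused.
#' @return An object of class `summary.survrules`.
#' @export
summary.survrules <- function(object, ...) {
  ch <- characterize_ruleset(object)
  structure(c(ch, list(mincov = object$mincov, n = object$n)),
            class = "summary.survrules")
}

#' @export
print.summary.survrules <- function(x, ...) {
  cat("Survival rule set on", x$n, "records (mincov =", x$mincov, ")\n")
  cat(sprintf("  rules:                 %d\n", x$n_rules))
  cat(sprintf("  mean rule length:      %.2f\n", x$mean_rule_length))
  cat(sprintf("  mean coverage:         %.1f%%\n",
              100 * x$mean_coverage_fraction))
  cat(sprintf("  significant rules:     %.1f%% (BH-adjusted p < 0.05)\n",
              100 * x$fraction_significant))
  invisible(x)
}

#' Predict survival curves from a rule set
#'
#' Each record gets the pointwise unweighted average of the Kaplan-Meier
#' conclusions of all rules covering it; a record covered by no rule gets the
#' default curve fitted on the full training set.
#'
#' @param object a fitted [survrules()] model.
#' @param newdata data frame of covariates.
#' @param times optional evaluation times; when given, a numeric matrix of
#'   survival probabilities (rows = records, columns = `times`) is returned
#'   instead of curve objects.
#' @param ... unused.
#' @return A list of [km_curve()] objects, or a matrix when `times` is given.
#' @export
predict.survrules <- function(object, newdata, times = NULL, ...) {
  cover <- vapply(object$rules, function(r) rule_covers(r, newdata),
                  logical(nrow(newdata)))
  cover <- matrix(cover, nrow = nrow(newdata))
  curves <- lapply(seq_len(nrow(newdata)), function(i) {
    hit <- which(cover[i, ])
    if (length(hit) == 0) object$default_curve
    else average_curves(lapply(object$rules[hit], function(r) r$conclusion))
  })
  if (is.null(times)) return(curves)
  t(vapply(curves, function(cv) km_eval(cv, times), numeric(length(times))))
}

#' Plot the survival curves of a rule set
#'
#' Step plot of each rule's Kaplan-Meier conclusion together with the default
#' (whole training set) curve, drawn dashed.
#'
#' @param x a fitted [survrules()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.survrules <- function(x, ...) {
  curves <- c(lapply(x$rules, function(r) r$conclusion),
              list(x$default_curve))
  xmax <- max(unlist(lapply(curves, function(cv) cv$times)), 1)
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "time", ylab = "survival probability", ...)
  for (i in seq_along(x$rules)) {
    cv <- x$rules[[i]]$conclusion
    graphics::lines(stats::stepfun(cv$times, c(1, cv$probs)), col = i,
                    do.points = FALSE)
  }
  dc <- x$default_curve
  graphics::lines(stats::stepfun(dc$times, c(1, dc$probs)), lty = 2,
                  do.points = FALSE)
  graphics::legend("bottomleft", bty = "n", lty = c(rep(1, length(x$rules)), 2),
                   col = c(seq_along(x$rules), 1),
                   legend = c(paste("rule", seq_along(x$rules)), "default"))
  invisible(x)
}
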