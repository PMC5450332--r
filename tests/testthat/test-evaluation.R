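test_that("censoring estimate is the flipped-status Kaplan-Meier", {
  # no censored records: G is 1 everywhere
  G <- censoring_km(c(1, 2, 3), c(1, 1, 1))
  expect_length(G$times, 0)
  expect_equal(km_eval(G, c(0, 10)), c(1, 1))
  # all censored: G is the KM of the times treated as events
  Gc <- censoring_km(c(1, 2, 3), c(0, 0, 0))
  ref <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(Gc$times, ref$times)
  expect_equal(Gc$probs, ref$probs)
  # mixed data: agrees with a reference product-limit fit on flipped status
  df <- random_survival_frame(25, 123)
  Gm <- censoring_km(df$time, df$status)
  grid <- sort(unique(df$time))
  expect_equal(km_eval(Gm, grid),
               survfit_probs(df$time, 1 - df$status, grid), tolerance = 1e-10)
})

test_that("Brier score follows the three-branch definition", {
  G1 <- km_curve(numeric(0), numeric(0))  # no censoring: G = 1
  flat <- km_curve(numeric(0), numeric(0))
  # survivor predicted perfectly: zero loss
  expect_equal(brier_score_at(10, 1, flat, G1, 5), 0)
  # event before the horizon with S-hat = 0.5: squared error 0.25
  half <- km_curve(0.5, 0.5)
  expect_equal(brier_score_at(2, 1, half, G1, 5), 0.25)
  # censored at or before the horizon: zero contribution
  expect_equal(brier_score_at(2, 0, half, G1, 5), 0)
  # weights use the left limit of G
  G <- km_fit(c(2, 6), c(1, 1))   # drops to 0.5 at 2, to 0 at 6
  # record censored at 4 and scored at its own event horizon uses G(4-) = 0.5
  expect_equal(brier_score_at(4, 1, half, G, 5), 0.25 / 0.5)
  # record alive beyond the horizon t* = 2 uses G(2-) = 1
  expect_equal(brier_score_at(3, 1, half, G, 2), 0.25 / 1)
  # an undefined weight (G = 0) is NA and excluded from means
  expect_true(is.na(brier_score_at(7, 1, half, G, 8)))
})

test_that("IBS reduces to the uncensored Brier time-average without censoring", {
  set.seed(21)
  tm <- round(rexp(15, 0.3), 2); st <- rep(1L, 15)
  G <- censoring_km(tm, st)
  # oracle predictor: S_i = 1 before T_i, 0 at and after
  preds <- lapply(tm, function(t) km_curve(t, 0))
  expect_equal(integrated_brier_score(tm, st, preds, G), 0, tolerance = 1e-12)
  # constant one-half prediction scores exactly 0.25
  const_half <- km_curve(0, 0.5)
  expect_equal(integrated_brier_score(tm, st, const_half, G), 0.25,
               tolerance = 1e-12)
  # arbitrary step predictions match the direct uncensored formula
  preds2 <- lapply(seq_along(tm), function(i) km_fit(tm[-i], st[-i]))
  ibs <- integrated_brier_score(tm, st, preds2, G)
  oracle <- oracle_uncensored_ibs(tm, st,
                                  function(i, t) km_eval(preds2[[i]], t))
  expect_equal(ibs, oracle, tolerance = 1e-12)
})

test_that("IBS matches the brute-force oracle under mixed censoring", {
  fx <- make_fixture("ibs_mixed")
  fit <- survrules(survival::Surv(time, status) ~ age + sex, data = fx,
                   mincov = 3)
  preds <- predict(fit, fx)
  G <- censoring_km(fx$time, fx$status)
  ibs <- integrated_brier_score(fx$time, fx$status, preds, G)
  oracle <- oracle_ibs(fx$time, fx$status,
                       function(i, t) km_eval(preds[[i]], t),
                       fx$time, fx$status)
  expect_equal(ibs, oracle, tolerance = 1e-6)
  # record order does not matter
  perm <- sample(nrow(fx))
  expect_equal(integrated_brier_score(fx$time[perm], fx$status[perm],
                                      preds[perm], G), ibs,
               tolerance = 1e-12)
  expect_gte(ibs, 0)
})

test_that("stratified folds preserve the event/censoring balance", {
  status <- rep(c(1L, 0L), c(60, 40))
  folds <- stratified_cv_folds(status, k = 10, repeats = 3, seed = 11)
  expect_length(folds, 3)
  for (f in folds) {
    expect_equal(sort(unique(f)), 1:10)
    expect_true(all(table(f) == 10))
    for (k in 1:10) {
      expect_equal(sum(status[f == k] == 0), 4)
      expect_equal(sum(status[f == k] == 1), 6)
    }
  }
  # 43 censored records across 10 folds: counts are 4 or 5 and sum to 43
  status2 <- rep(c(1L, 0L), c(57, 43))
  f2 <- stratified_cv_folds(status2, k = 10, repeats = 1, seed = 2)[[1]]
  cens_counts <- vapply(1:10, function(k) sum(status2[f2 == k] == 0), 0)
  expect_true(all(cens_counts %in% c(4, 5)))
  expect_equal(sum(cens_counts), 43)
  expect_error(stratified_cv_folds(status, k = 1), "at least 2")
  # reproducibility
  expect_identical(stratified_cv_folds(status, 10, 2, seed = 5),
                   stratified_cv_folds(status, 10, 2, seed = 5))
})

test_that("cross-validation is deterministic, leak-free and non-negative", {
  sim <- planted_dataset(n = 120, seed = 31)
  cv1 <- cross_validate(survival::Surv(time, status) ~ ., data = sim$data,
                        mincov = 7, k = 5, repeats = 1, seed = 77)
  cv2 <- cross_validate(survival::Surv(time, status) ~ ., data = sim$data,
                        mincov = 7, k = 5, repeats = 1, seed = 77)
  expect_identical(cv1$folds, cv2$folds)
  expect_true(all(cv1$folds$ibs >= 0))
  expect_true(all(cv1$folds$ibs_km >= 0))
  expect_equal(nrow(cv1$folds), 5)
  # fold schedules partition the data: no test record is in its train split
  sched <- stratified_cv_folds(sim$data$status, k = 5, repeats = 2, seed = 77)
  for (f in sched) {
    for (k in 1:5) expect_length(intersect(which(f == k), which(f != k)), 0)
    expect_setequal(unlist(lapply(1:5, function(k) which(f == k))),
                    seq_along(f))
  }
})

test_that("folds without training events are skipped with a warning", {
  df <- data.frame(x = rnorm(12), time = c(5, 1:11),
                   status = c(1L, rep(0L, 11)))
  expect_warning(
    cv <- cross_validate(survival::Surv(time, status) ~ x, data = df,
                         mincov = 2, k = 2, repeats = 1, seed = 1),
    "no events")
  expect_lt(nrow(cv$folds), 2)
})

test_that("rule-set characterization applies the BH step-up correction", {
  # hand-checked Benjamini-Hochberg adjustment
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.9), method = "BH"),
               c(0.04, 0.04, 0.04, 0.9))
  # degenerate one-rule model: full coverage, statistic 0, nothing significant
  df <- data.frame(g = factor(rep("only", 10)), time = 1:10,
                   status = rep(1L, 10))
  fit <- survrules(survival::Surv(time, status) ~ g, data = df)
  ch <- characterize_ruleset(fit)
  expect_equal(ch$n_rules, 1)
  expect_equal(ch$mean_coverage_fraction, 1)
  expect_equal(ch$fraction_significant, 0)
  expect_equal(ch$p_adjusted, 1)
  # mean rule length is the arithmetic mean of premise lengths
  sim <- planted_dataset(n = 100, seed = 13)
  fit2 <- survrules(survival::Surv(time, status) ~ ., data = sim$data)
  expect_equal(characterize_ruleset(fit2)$mean_rule_length,
               mean(vapply(fit2$rules, function(r) length(r$conditions), 0)))
  # BH keeps the p ordering and stays within [0, 1]
  p <- vapply(fit2$rules, function(r) r$p_value, 0)
  adj <- characterize_ruleset(fit2)$p_adjusted
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  # monotone non-decreasing when walked in raw-p order
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})
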