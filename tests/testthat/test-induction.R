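test_that("a single-valued nominal attribute yields one all-covering rule", {
  df <- data.frame(g = factor(rep("only", 12)),
                   time = c(1:10, 4, 8), status = rep(1L, 12))
  fit <- survrules(survival::Surv(time, status) ~ g, data = df)
  expect_length(fit$rules, 1)
  expect_equal(format_rule(fit$rules[[1]]), "g = only")
  expect_true(all(rule_covers(fit$rules[[1]], df)))
  expect_equal(fit$rules[[1]]$quality, 0)
  expect_equal(fit$rules[[1]]$p_value, 1)
})

test_that("candidate enumeration builds midpoint splits and observed values", {
  df <- data.frame(num = c(1, 2, 4), nom = factor(c("a", "b", "a"),
                                                  levels = c("a", "b", "c")))
  conds <- enumerate_conditions(df)
  txt <- vapply(conds, function(cn) format_rule(list(cn)), "")
  expect_equal(txt, c("num < 1.5", "num >= 1.5", "num < 3", "num >= 3",
                      "nom = a", "nom = b"))
  # attributes entirely missing among covered records contribute nothing
  dfm <- data.frame(num = c(NA_real_, NA_real_), nom = factor(c("a", "a")))
  expect_equal(vapply(enumerate_conditions(dfm),
                      function(cn) cn$attribute, ""), "nom")
  expect_error(enumerate_conditions(df[0, ]), "no covered records")
})

test_that("growing prefers the larger coverage on tied statistics", {
  # all records share one event time: every split has statistic 0, so the
  # coverage tie-break decides; 'a' covers 6 of 10 records
  df <- data.frame(g = factor(rep(c("a", "b"), c(6, 4))),
                   time = rep(2, 10), status = rep(1L, 10))
  fit <- survrules(survival::Surv(time, status) ~ g, data = df, mincov = 1)
  expect_equal(format_rule(fit$rules[[1]]), "g = a")

  # duplicated covariate: the tie resolves to the first declared attribute
  df2 <- data.frame(u = c(1, 1, 2, 2, 3, 3, 4, 4), v = c(1, 1, 2, 2, 3, 3, 4, 4),
                    time = c(1, 2, 1, 2, 5, 6, 7, 8),
                    status = rep(1L, 8))
  fit2 <- survrules(survival::Surv(time, status) ~ u + v, data = df2,
                    mincov = 2)
  expect_equal(fit2$rules[[1]]$conditions[[1]]$attribute, "u")
})

test_that("learning covers every record and honors the mincov constraint", {
  for (seed in 1:6) {
    mincov <- c(1, 3, 7)[(seed %% 3) + 1]
    sim <- planted_dataset(n = 150, seed = seed)
    fit <- survrules(survival::Surv(time, status) ~ ., data = sim$data,
                     mincov = mincov)
    cov <- fit$coverage
    expect_true(all(rowSums(cov) >= 1))
    # replay the induction order: each non-final rule covered >= mincov
    # previously uncovered records when it was added
    prev <- rep(FALSE, nrow(cov))
    for (k in seq_len(ncol(cov))) {
      new_w <- sum(cov[, k] & !prev)
      if (k < ncol(cov)) expect_gte(new_w, mincov)
      else expect_gte(new_w, min(mincov, sum(!prev)))
      prev <- prev | cov[, k]
    }
    # pruning never decreased the statistic
    for (r in fit$rules) expect_gte(r$quality, r$quality_grown - 1e-9)
  }
})

test_that("pruning is hill-climbing within exhaustive-subset reach", {
  for (seed in 1:12) {
    df <- random_survival_frame(30, seed + 40, censor_p = 0.2)
    X <- df[, c("g", "x1", "x2")]
    g <- survrules:::.grow_rule_cpp(
      survrules:::covariate_matrix(X), c(TRUE, FALSE, FALSE),
      df$time, as.integer(df$status), rep(1, 30), rep(FALSE, 30),
      mincov = 3, max_conditions = 4L)
    if (length(g$attr) == 0) next
    attrs <- survrules:::attr_meta(X)
    conds <- lapply(seq_along(g$attr), function(i)
      survrules:::decode_condition(g$attr[i], g$op[i], g$value[i], X, attrs))
    grown_q <- logrank_statistic(df$time, df$status, rule_covers(conds, X))
    pr <- survrules:::prune_conditions(conds, X, df$time, df$status,
                                       rep(1, 30))
    # never worse than the grown rule, never better than the best subset
    expect_gte(pr$quality, grown_q - 1e-9)
    best <- exhaustive_best_subset(conds, X, df$time, df$status)
    expect_lte(pr$quality, best + 1e-9)
    # a one-condition rule is returned unchanged
    one <- survrules:::prune_conditions(conds[1], X, df$time, df$status,
                                        rep(1, 30))
    expect_length(one$conditions, 1)
    expect_equal(one$conditions[[1]], conds[[1]])
  }
})

test_that("growing respects the max_conditions cap", {
  sim <- planted_dataset(n = 120, seed = 3)
  fit <- survrules(survival::Surv(time, status) ~ ., data = sim$data,
                   mincov = 7, max_conditions = 2)
  # premises are capped before merging, so merged length is at most 2
  expect_true(all(vapply(fit$rules,
                         function(r) length(r$conditions), 0) <= 2))
})

test_that("induction is deterministic for a fixed dataset and order", {
  sim <- planted_dataset(n = 120, seed = 5)
  f1 <- survrules(survival::Surv(time, status) ~ ., data = sim$data)
  f2 <- survrules(survival::Surv(time, status) ~ ., data = sim$data)
  p1 <- tempfile(); p2 <- tempfile()
  write_ruleset(f1, p1); write_ruleset(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the planted risk factor heads the first rule on a seeded run", {
  sim <- planted_dataset(n = 300, seed = 17)
  fit <- survrules(survival::Surv(time, status) ~ ., data = sim$data)
  attrs_used <- vapply(fit$rules[[1]]$conditions,
                       function(cn) cn$attribute, "")
  expect_true("risk" %in% attrs_used)
})

test_that("records impossible to cover are reported and skipped", {
  # the last two records are missing every covariate, so no condition can
  # ever cover them
  df <- data.frame(x = c(rnorm(10), NA, NA),
                   time = c(1:10, 3, 4), status = rep(1L, 12))
  expect_warning(fit <- survrules(survival::Surv(time, status) ~ x,
                                  data = df, mincov = 2),
                 "cannot be covered")
  expect_length(fit$rules, length(fit$rules))
  expect_true(all(rowSums(fit$coverage)[1:10] >= 1))
})
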