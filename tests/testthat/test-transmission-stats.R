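test_that("the 2x2 independence test reproduces known statistics", {
  # printed progeny table: horned/polled x female/male
  tab <- matrix(c(31, 14, 29, 2), 2, byrow = TRUE)
  res <- chi2_independence_2x2(tab)
  expect_equal(res$statistic, 6.7156, tolerance = 1e-4)
  expect_identical(res$df, 1)
  expect_lt(res$p, 0.01)

  expect_identical(chi2_independence_2x2(matrix(10, 2, 2))$statistic, 0)
  # all expected cells 2.5: hand computation gives 10
  expect_equal(chi2_independence_2x2(matrix(c(5, 0, 0, 5), 2))$statistic, 10)

  expect_error(chi2_independence_2x2(matrix(c(5, 5, 0, 0), 2, byrow = TRUE)),
               class = "hemidel_stats_error")
})

test_that("the 2x2 statistic is invariant under permutation and transposition", {
  tab <- matrix(c(31, 14, 29, 2), 2, byrow = TRUE)
  s0 <- chi2_independence_2x2(tab)$statistic
  expect_equal(chi2_independence_2x2(tab[2:1, ])$statistic, s0)
  expect_equal(chi2_independence_2x2(tab[, 2:1])$statistic, s0)
  expect_equal(chi2_independence_2x2(t(tab))$statistic, s0)
})

test_that("goodness of fit against dominant expectation matches the known value", {
  res <- chi2_goodness_of_fit(c(31, 29, 14, 2), rep(0.25, 4))
  expect_equal(res$statistic, 558 / 19, tolerance = 1e-10)  # = 29.368
  expect_identical(res$df, 3)
  expect_lt(res$p, 1e-4)

  expect_equal(chi2_goodness_of_fit(c(8, 2), c(0.5, 0.5))$statistic, 3.6)
  expect_identical(chi2_goodness_of_fit(c(20, 10, 10), c(0.5, 0.25, 0.25))$statistic, 0)
  expect_error(chi2_goodness_of_fit(c(1, 1), c(1, 0)),
               class = "hemidel_stats_error")
  expect_error(chi2_goodness_of_fit(c(0, 0), c(0.5, 0.5)),
               class = "hemidel_stats_error")
})

test_that("goodness of fit is zero exactly when observed is proportional", {
  set.seed(5)
  for (i in 1:20) {
    p <- as.vector(stats::rmultinom(1, 40, rep(0.25, 4)) + 1)
    p <- p / sum(p)
    k <- sample(1:5, 1)
    expect_equal(chi2_goodness_of_fit(p * 40 * k, p)$statistic, 0)
    obs <- p * 40; obs[1] <- obs[1] + 1
    expect_gt(chi2_goodness_of_fit(obs, p)$statistic, 0)
  }
})

test_that("stage comparison tests the later stage against the earlier proportions", {
  ref <- transmission_counts("sperm", c(M.del = 10L, M.wt = 20L,
                                        F.del = 12L, F.wt = 18L))
  obs <- transmission_counts("blastocyst", c(M.del = 20L, M.wt = 40L,
                                             F.del = 24L, F.wt = 36L))
  expect_equal(stage_comparison(obs, ref)$statistic, 0)
  expect_identical(stage_comparison(obs, ref)$df, 3)

  # frozen from the oracle chisq.test(c(10,10,10,10), p = c(.4,.3,.2,.1))
  res <- stage_comparison(c(M.del = 10, M.wt = 10, F.del = 10, F.wt = 10),
                          c(M.del = 0.4, M.wt = 0.3, F.del = 0.2, F.wt = 0.1) * 40)
  expect_equal(res$statistic, 12.0833, tolerance = 1e-4)

  # a zero reference cell pools with the opposite-sex same-carrier cell
  ref0 <- transmission_counts("blastocyst", c(M.del = 0L, M.wt = 20L,
                                              F.del = 12L, F.wt = 18L))
  res0 <- stage_comparison(obs, ref0)
  expect_identical(res0$df, 2)
  expect_match(res0$method, "pooled")

  ref00 <- transmission_counts("blastocyst", c(M.del = 0L, M.wt = 20L,
                                               F.del = 0L, F.wt = 18L))
  expect_error(stage_comparison(obs, ref00), class = "hemidel_stats_error")
})

test_that("stage distributions drift only at birth in simulated cohorts", {
  # the male-lethality signal: sperm and blastocyst share proportions, birth
  # departs. 60 seeds; medians characterize the expected pattern.
  p_sb <- c(); p_bb <- c(); p_sbirth <- c()
  set.seed(42)
  for (s in 1:60) {
    tc <- simulate_transmission_counts(simulation_config(seed = s))
    p_sb <- c(p_sb, stage_comparison(tc$blastocyst, tc$sperm)$p)
    p_bb <- c(p_bb, stage_comparison(tc$birth, tc$blastocyst)$p)
    p_sbirth <- c(p_sbirth, stage_comparison(tc$birth, tc$sperm)$p)
  }
  expect_gt(stats::median(p_sb), 0.05)      # no selection before implantation
  expect_lt(stats::median(p_sbirth), 0.05)  # male carriers vanish by birth
  expect_gt(mean(p_sbirth < 0.05), 0.6)
  expect_lt(stats::median(p_bb), stats::median(p_sb))
})

test_that("Welch's t from summaries agrees with t.test on raw data", {
  res0 <- welch_t(10, 2, 30, 10, 2, 30)
  expect_identical(res0$statistic, 0)
  expect_identical(res0$p, 1)

  # epidermis-thickness summaries: |t| = 13.23, df = 189.9, p ~ 1e-28
  res <- welch_t(15.8, 3.0, 100, 22.1, 3.7, 100)
  expect_equal(abs(res$statistic), 13.2258, tolerance = 1e-3)
  expect_equal(res$df, 189.887, tolerance = 1e-2)
  expect_lt(res$p, 1e-26)
  expect_gt(res$p, 1e-31)

  # cross-check against stats::t.test on raw vectors with these exact summaries
  set.seed(8)
  x <- rnorm(40); x <- (x - mean(x)) / sd(x) * 1.7 + 5.2
  y <- rnorm(25); y <- (y - mean(y)) / sd(y) * 2.9 + 6.1
  ref <- stats::t.test(x, y)
  mine <- welch_t(mean(x), sd(x), 40, mean(y), sd(y), 25)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)

  expect_error(welch_t(1, 1, 1, 2, 1, 10), class = "hemidel_stats_error")
  expect_error(welch_t(1, 0, 10, 2, 1, 10), class = "hemidel_stats_error")
})

test_that("mosaicism doubles the sperm fraction with a doubled exact CI", {
  est33 <- mosaicism_from_sperm(33, 100)
  expect_identical(est33$mosaicism, 0.66)
  expect_identical(mosaicism_from_sperm(35, 100)$mosaicism, 0.7)

  # the CI is the doubled Clopper-Pearson interval, capped at 1
  bt <- stats::binom.test(33, 100)
  expect_equal(est33$ci, pmin(1, 2 * as.numeric(bt$conf.int)))
  expect_true(est33$ci[1] <= est33$mosaicism && est33$mosaicism <= est33$ci[2])

  est0 <- mosaicism_from_sperm(0, 50)
  expect_identical(est0$mosaicism, 0)
  expect_identical(est0$ci[1], 0)

  expect_identical(mosaicism_from_sperm(80, 100)$mosaicism, 1)
  expect_error(mosaicism_from_sperm(1, 0), class = "hemidel_stats_error")
})

test_that("the doubled exact interval keeps nominal coverage for mosaicism", {
  set.seed(77)
  n_draws <- 2000
  covered <- logical(n_draws)
  for (i in seq_len(n_draws)) {
    m <- stats::runif(1, 0.05, 0.95)
    n <- sample(100:1500, 1)
    k <- stats::rbinom(1, n, m / 2)
    ci <- mosaicism_from_sperm(k, n)$ci
    covered[i] <- ci[1] <= m && m <= ci[2]
  }
  expect_gte(mean(covered), 0.95)
})

test_that("AI filtering applies rules in order with disjoint attribution", {
  set.seed(17)
  rec <- simulate_ai_records(simulation_config(seed = 17))
  flt <- filter_ai_records(rec)
  expect_identical(nrow(flt$retained), 20L)
  expect_identical(sort(unique(flt$discarded$reason)),
                   c("adjacent_ai", "low_fertility", "superovulation"))

  # a record matching two rules goes to the first applicable rule only
  both <- ai_records(data.frame(
    cow_id = c("c1", "c1", "c1", "c1"),
    ai_day = c(1L, 2L, 3L, 44L),
    outcome = "failure", superovulation = c(TRUE, FALSE, FALSE, FALSE),
    next_event = c("ai", "ai", "ai", "none"),
    next_event_day = c(2L, 3L, 44L, NA),
    consecutive_failures_for_cow = 1:4))
  flt2 <- filter_ai_records(both)
  expect_identical(nrow(flt2$retained), 0L)
  # record 1 is superovulation even though its next AI is a day later and
  # the cow is low-fertility
  expect_identical(flt2$discarded$reason,
                   c("superovulation", "adjacent_ai", "low_fertility",
                     "low_fertility"))

  empty <- filter_ai_records(both[integer(0), ])
  expect_identical(nrow(empty$retained), 0L)
})

test_that("lethality bounds follow the cycle/gestation arithmetic", {
  cfg <- lethality_config()
  rec <- ai_records(data.frame(
    cow_id = c("a", "b", "c"), ai_day = c(0L, 0L, 0L), outcome = "failure",
    superovulation = FALSE, next_event = c("ai", "calving", "ai"),
    next_event_day = c(42L, 400L, 10L), consecutive_failures_for_cow = 1L))
  lw <- lethality_window(rec, cfg)
  expect_identical(lw$bounds$bound_days, c(21, 94, -11))
  expect_identical(lw$bounds$valid, c(TRUE, TRUE, FALSE))
  expect_identical(lw$max_bound_days, 94)

  # all bounds non-positive: explicit empty maximum
  rec2 <- rec; rec2$next_event_day <- c(10L, 200L, 5L)
  lw2 <- lethality_window(rec2, cfg)
  expect_true(is.na(lw2$max_bound_days))

  # invariance under a global day offset
  rec3 <- rec; rec3$ai_day <- rec3$ai_day + 500L
  rec3$next_event_day <- rec3$next_event_day + 500L
  expect_identical(lethality_window(rec3, cfg)$bounds$bound_days,
                   lw$bounds$bound_days)

  none <- rec; none$next_event <- "none"; none$next_event_day <- NA_integer_
  expect_error(lethality_window(none, cfg), class = "hemidel_stats_error")
})

test_that("the inheritance report assembles every statistic", {
  # printed birth table
  rep1 <- inheritance_report(recorded_birth_counts())
  expect_equal(rep1$independence_sex_phenotype$statistic, 6.7156,
               tolerance = 1e-4)
  expect_equal(rep1$dominant_gof$statistic, 558 / 19, tolerance = 1e-6)
  expect_equal(rep1$lambda_hat, 1 - 2 / 14)

  # trivial all-equal counts
  flat <- transmission_counts("birth", c(M.del = 10L, M.wt = 10L,
                                         F.del = 10L, F.wt = 10L))
  rep2 <- inheritance_report(flat)
  expect_equal(rep2$independence_sex_phenotype$statistic, 0)
  expect_equal(rep2$dominant_gof$statistic, 0)

  # full simulated cohort
  b <- simulate_cohort(simulation_config(seed = 23))
  rep3 <- inheritance_report(b$counts$birth, b$counts$sperm,
                             b$counts$blastocyst, b$ai_records)
  expect_named(rep3$stage_tests,
               c("sperm_vs_blastocyst", "blastocyst_vs_birth", "sperm_vs_birth"))
  expect_s3_class(rep3$mosaicism, "mosaicism_estimate")
  expect_identical(rep3$lethality$n_retained, 20L)
  expect_lte(rep3$lethality$max_bound_days, 88)
  expect_true(rep3$mosaicism$ci[1] <= rep3$mosaicism$mosaicism)
})
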