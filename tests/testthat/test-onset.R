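test_that("onset intervals come from day-precision dates with the same-day rule", {
  fx <- fixture_small()
  reports <- build_reports(fx$tables)
  split <- build_cohort(reports, c("VOCLOSPORIN", "LUPKYNIS"))
  tto <- onset_days(split$cohort, c("VOCLOSPORIN", "LUPKYNIS"))
  expect_equal(tto$days[tto$caseid == "C001"], 10)
  expect_equal(tto$days[tto$caseid == fx$expected$same_day_caseid], 0.5)
  expect_true(is.na(tto$days[tto$caseid == "C004"]))  # month-precision event
  expect_equal(tto$reason[tto$caseid == "C004"], "partial_event_date")
})

test_that("a negative interval sanitizes to missing with its reason", {
  rep1 <- reports_from_cases(pts = list("Headache"))
  rep1$cases$event_dt <- "20230110"
  rep1$therapy <- tibble::tibble(primaryid = "T0001", dsg_drug_seq = "1",
                                 start_dt = "20230120", end_dt = "")
  tto <- onset_days(rep1, "VOCLOSPORIN")
  expect_true(is.na(tto$days))
  expect_equal(tto$reason, "negative_interval")
})

test_that("the earliest day-precision start among target therapy rows is used", {
  rep1 <- reports_from_cases(pts = list("Headache"))
  rep1$cases$event_dt <- "20230301"
  rep1$drugs <- tibble::tibble(primaryid = "T0001", drug_seq = c("1", "2"),
                               role_cod = c("PS", "C"),
                               drugname = c("VOCLOSPORIN", "OTHER"),
                               prod_ai = c("VOCLOSPORIN", "OTHER"))
  rep1$therapy <- tibble::tibble(
    primaryid = "T0001", dsg_drug_seq = c("1", "1", "2"),
    start_dt = c("20230210", "20230201", "20230101"), end_dt = "")
  tto <- onset_days(rep1, "VOCLOSPORIN")
  # the concomitant drug's earlier start is ignored; earliest target start wins
  expect_equal(tto$days, 28)
})

test_that("onset bins are right-closed 30/60/90/180/360 windows", {
  b <- bin_onsets(c(10, 30, 31))
  expect_equal(b$n[b$bin == "(0,30]"], 2L)
  expect_equal(b$n[b$bin == "(30,60]"], 1L)
  expect_equal(sum(bin_onsets(numeric(0))$n), 0L)
  set.seed(1)
  x <- rweibull(500, 1, 120)
  expect_equal(sum(bin_onsets(x)$n), length(x))
})

test_that("onset summary uses linear-interpolation quantiles", {
  s <- summarize_onset(c(1, 2, 3, 4, 5))
  expect_equal(c(s$median, s$q1, s$q3), c(3, 2, 4))
  s1 <- summarize_onset(7)
  expect_equal(c(s1$median, s1$q1, s1$q3), c(7, 7, 7))
  expect_error(summarize_onset(NA_real_), "empty")
})

test_that("the onset median is permutation-invariant and shift-monotone", {
  set.seed(3)
  x <- rweibull(101, 0.8, 90)
  expect_equal(summarize_onset(sample(x))$median, summarize_onset(x)$median)
  expect_equal(summarize_onset(x + 5)$median, summarize_onset(x)$median + 5)
})

test_that("draws from a constant-hazard model land near the closed-form median", {
  set.seed(11)
  x <- rweibull(500, shape = 1, scale = 143)
  expect_lt(abs(summarize_onset(x)$median - 143 * log(2)), 15)
})

test_that("the Kruskal-Wallis H matches rank enumeration and degenerates to 0", {
  # pooled ranks 1..6: R1 = 6, R2 = 15 -> H = 12/(6*7)*(12 + 75) - 21 = 27/7
  out <- compare_onset_groups(list(a = c(1, 2, 3), b = c(10, 20, 30)))
  expect_equal(out$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(out$df, 1L)

  same <- compare_onset_groups(list(a = c(5, 5), b = c(5, 5, 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  ident <- compare_onset_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident$statistic, 0, tolerance = 1e-12)
})

test_that("Weibull fitting recovers planted parameters and flags degeneracy", {
  set.seed(21)
  x <- rweibull(2000, 0.7, 100)
  fit <- fit_weibull(x, ci_reps = 300, seed = 22)
  expect_lt(abs(fit$shape - 0.7), 0.05)
  expect_equal(fit$failure_type, "early")
  expect_true(fit$shape_ci_low <= fit$shape && fit$shape <= fit$shape_ci_high)

  expect_error(fit_weibull(rep(5, 50), ci_reps = 50), "converge")
  expect_error(fit_weibull(c(1, 2, 3), ci_reps = 50), "at least 10")
  expect_error(fit_weibull(c(rep(1, 20), 0), ci_reps = 50), "positive")
})

test_that("the MLE matches fitdistrplus and maximizes the log-likelihood", {
  set.seed(31)
  x <- rweibull(400, 1.3, 60)
  fit <- fit_weibull(x, ci_reps = 50, seed = 1)
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-4)
  expect_equal(fit$scale, unname(ref$estimate["scale"]), tolerance = 1e-4)
  # MLE property: planted truth cannot beat the fitted likelihood
  expect_gte(weibull_loglik(x, fit$shape, fit$scale),
             weibull_loglik(x, 1.3, 60) - 1e-8)
})

test_that("wear-out classification triggers when the shape CI clears 1", {
  set.seed(41)
  fit <- fit_weibull(rweibull(1500, 1.6, 200), ci_reps = 300, seed = 42)
  expect_equal(fit$failure_type, "wear_out")
  expect_gt(fit$shape_ci_low, 1)
})

test_that("the Weibull median closed form matches large planted samples", {
  set.seed(51)
  for (shape in c(0.7, 1, 1.5)) {
    x <- rweibull(20000, shape, 100)
    expect_equal(median(x), 100 * log(2)^(1 / shape), tolerance = 0.05)
  }
})

test_that("per-term onset tables summarize and classify each group", {
  planted <- tibble::tibble(pt = "PT_100", ror = 6, stratum = NA_character_)
  g <- generate_faers(generator_config(n_cases = 20000,
                                       planted_signals = planted,
                                       missing_date_prob = 0, seed = 61))
  reports <- build_reports(g$tables)
  split <- build_cohort(reports, "VOCLOSPORIN")
  map <- generator_pt_map(generator_config(n_cases = 1))
  tab <- onset_by_term(split$cohort, "VOCLOSPORIN", "SOC", map,
                       min_n = 30, ci_reps = 100, seed = 62)
  expect_true(all(tab$n >= 1))
  fitted <- tab[!is.na(tab$shape), ]
  expect_gt(nrow(fitted), 0)
  expect_true(all(fitted$failure_type %in% c("early", "random", "wear_out")))
  expect_true(all(fitted$shape_ci_low <= fitted$shape &
                    fitted$shape <= fitted$shape_ci_high))
})
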