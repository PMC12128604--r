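test_that("deduplication keeps the latest FDA_DT, ties to higher PRIMARYID", {
  demo <- dplyr::bind_rows(
    demo_rows(10, "C1", "20220101"),
    demo_rows(11, "C1", "20220301")
  )
  expect_equal(deduplicate_reports(demo)$primaryid, "11")

  demo <- dplyr::bind_rows(
    demo_rows(10, "C1", "20220101"),
    demo_rows(12, "C1", "20220101")
  )
  expect_equal(deduplicate_reports(demo)$primaryid, "12")

  single <- demo_rows(10, "C1", "20220101")
  expect_equal(deduplicate_reports(single), single)
})

test_that("a version with an unparseable FDA_DT loses every comparison", {
  demo <- dplyr::bind_rows(
    demo_rows(99, "C1", "bad-date"),
    demo_rows(10, "C1", "20220101")
  )
  expect_equal(deduplicate_reports(demo)$primaryid, "10")
  alone <- demo_rows(99, "C2", "")
  expect_equal(deduplicate_reports(alone)$primaryid, "99")
})

test_that("deduplication is idempotent and yields one row per caseid", {
  g <- generate_faers(generator_config(n_cases = 2000, seed = 11))
  demo <- g$tables$demo
  once <- deduplicate_reports(demo)
  expect_equal(nrow(once), length(unique(demo$caseid)))
  expect_equal(deduplicate_reports(once), once)
})

test_that("drug name matching is substring-based over drugname and prod_ai", {
  tokens <- c("VOCLOSPORIN", "LUPKYNIS")
  expect_true(match_drug("LUPKYNIS 7.9MG", "", tokens))
  expect_true(match_drug("", "VOCLOSPORIN", tokens))
  expect_true(match_drug("voclosporin capsules", "", tokens))  # case folded
  expect_false(match_drug("CYCLOSPORINE", "CYCLOSPORINE", tokens))
})

test_that("the cohort keeps only primary-suspect matches and partitions input", {
  # same drug, different roles: only the PS report enters the cohort
  rep_ps <- reports_from_cases(pts = list("Headache"), role = "PS")
  rep_c <- reports_from_cases(pts = list("Nausea"), role = "C")
  rep_c$cases$caseid <- rep_c$cases$primaryid <- "C0001"
  rep_c$drugs$primaryid <- rep_c$reactions$primaryid <- "C0001"
  merged <- new_faers_reports(
    dplyr::bind_rows(rep_ps$cases, rep_c$cases),
    drugs = dplyr::bind_rows(rep_ps$drugs, rep_c$drugs),
    reactions = dplyr::bind_rows(rep_ps$reactions, rep_c$reactions)
  )
  split <- build_cohort(merged, "VOCLOSPORIN")
  expect_equal(split$cohort$cases$caseid, "T0001")
  expect_equal(split$background$cases$caseid, "C0001")

  # empty input
  empty <- filter_empty <- build_cohort(
    new_faers_reports(rep_ps$cases[0, ],
                      drugs = rep_ps$drugs[0, ],
                      reactions = rep_ps$reactions[0, ]),
    "VOCLOSPORIN")
  expect_equal(nrow(empty$cohort$cases), 0L)
  expect_equal(nrow(empty$background$cases), 0L)
})

test_that("build_cohort partitions random synthetic reports", {
  g <- generate_faers(generator_config(n_cases = 3000, seed = 5))
  reports <- build_reports(g$tables)
  split <- build_cohort(reports, c("VOCLOSPORIN", "LUPKYNIS"))
  expect_equal(nrow(split$cohort$cases) + nrow(split$background$cases),
               nrow(reports$cases))
  expect_length(intersect(split$cohort$cases$caseid,
                          split$background$cases$caseid), 0L)
})

test_that("cohort summary computes half-up percentages that sum to ~100", {
  g <- generate_faers(generator_config(n_cases = 4000, seed = 3))
  reports <- build_reports(g$tables)
  split <- build_cohort(reports, "VOCLOSPORIN")
  s <- summarize_cohort(split$cohort)
  for (nm in c("by_sex", "by_age_band", "by_outcome", "by_reporter",
               "by_country")) {
    expect_equal(sum(s[[nm]]$n), s$n_total, info = nm)
    expect_lt(abs(sum(s[[nm]]$pct) - 100), 0.021)
  }
})

test_that("a case with several outcomes counts only its most severe", {
  rep1 <- reports_from_cases(sex = "M", pts = list("Headache"))
  rep1$outcomes <- tibble::tibble(primaryid = rep("T0001", 3),
                                  outc_cod = c("HO", "OT", "DE"))
  s <- summarize_cohort(rep1)
  expect_equal(s$by_outcome$n[s$by_outcome$category == "death"], 1L)
  expect_equal(sum(s$by_outcome$n), 1L)
  expect_equal(s$by_sex$pct[s$by_sex$category == "M"], 100)

  rep1$outcomes <- tibble::tibble(primaryid = "T0001", outc_cod = "LT")
  s2 <- summarize_cohort(rep1)
  expect_equal(s2$by_outcome$n[s2$by_outcome$category == "other"], 1L)
})

test_that("reports with no reaction rows are dropped and counted", {
  tables <- list(
    demo = dplyr::bind_rows(demo_rows(1, "C1", "20220101"),
                            demo_rows(2, "C2", "20220102")),
    drug = tibble::tibble(primaryid = c("1", "2"), drug_seq = "1",
                          role_cod = "PS", drugname = "X", prod_ai = "X"),
    reac = tibble::tibble(primaryid = "1", pt = "Headache"),
    ther = NULL, outc = NULL
  )
  reports <- build_reports(tables)
  expect_equal(nrow(reports$cases), 1L)
  expect_equal(reports$log$n_dropped_no_reaction, 1L)
})
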