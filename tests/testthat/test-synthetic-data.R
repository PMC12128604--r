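test_that("generated quarterly files parse back with zero skipped rows", {
  dir <- withr::local_tempdir()
  g <- generate_faers(generator_config(n_cases = 800, seed = 17), dir = dir)
  tables <- read_faers_quarters(dir)
  for (kind in names(tables)) {
    expect_equal(nrow(tables[[kind]]), nrow(g$tables[[kind]]), info = kind)
  }
  skipped <- unlist(lapply(attr(tables, "read_summary"),
                           function(ss) vapply(ss, `[[`, 0L, "rows_skipped")))
  expect_true(all(skipped == 0L))
  expect_true(file.exists(file.path(dir, "pt_soc_map.tsv")))
  map <- load_pt_soc_map(file.path(dir, "pt_soc_map.tsv"))
  expect_true(all(soc_of(unique(tables$reac$pt), map) != UNMAPPED))
})

test_that("generation is fully reproducible under the seed", {
  cfg <- generator_config(n_cases = 500, seed = 23)
  g1 <- generate_faers(cfg)
  g2 <- generate_faers(cfg)
  expect_identical(g1$tables, g2$tables)
  expect_identical(g1$manifest$onset_truth, g2$manifest$onset_truth)
})

test_that("config invariants are validated before anything is generated", {
  expect_error(generator_config(0), "n_cases")
  expect_error(generator_config(10, target_drug_prob = 1.4), "probabilities")
  expect_error(generator_config(10, sex_probs = c(F = 0.6, M = 0.6, UNK = 0)),
               "sum to 1")
  expect_error(
    generator_config(10, planted_signals = tibble::tibble(pt = "PT_001",
                                                          ror = -2)),
    "odds ratios")
  expect_error(
    generator_config(10, planted_signals = tibble::tibble(pt = "NOT_THERE",
                                                          ror = 2)),
    "NOT_THERE")
})

test_that("after deduplication the case count equals the manifest's", {
  g <- generate_faers(generator_config(n_cases = 4000, duplicate_prob = 0.2,
                                       seed = 29))
  expect_gt(g$manifest$n_duplicates, 0)
  expect_equal(nrow(g$tables$demo),
               g$manifest$n_cases + g$manifest$n_duplicates)
  dedup <- deduplicate_reports(g$tables$demo)
  expect_equal(nrow(dedup), g$manifest$n_cases)
  # duplicates are the older versions: every kept primaryid is the original
  expect_true(all(substr(dedup$primaryid, nchar(dedup$primaryid),
                         nchar(dedup$primaryid)) == "2"))
})

test_that("empirical case-level odds ratios track planted values (log-log)", {
  planted <- tibble::tibble(
    pt = c("PT_040", "PT_050", "PT_060", "PT_070", "PT_080"),
    ror = c(0.5, 1, 2, 5, 10), stratum = NA_character_)
  g <- generate_faers(generator_config(n_cases = 40000, duplicate_prob = 0,
                                       planted_signals = planted, seed = 31))
  demo <- g$tables$demo
  drug <- g$tables$drug
  tgt <- unique(drug$primaryid[match_drug(drug$drugname, drug$prod_ai,
                                          "VOCLOSPORIN") &
                                 drug$role_cod == "PS"])
  is_tgt <- demo$primaryid %in% tgt
  emp <- vapply(planted$pt, function(p) {
    has <- demo$primaryid %in% g$tables$reac$primaryid[g$tables$reac$pt == p]
    a <- sum(is_tgt & has); b <- sum(is_tgt & !has)
    c <- sum(!is_tgt & has); d <- sum(!is_tgt & !has)
    (a * d) / (b * c)
  }, numeric(1))
  slope <- coef(lm(log(emp) ~ log(planted$ror)))[2]
  expect_lt(abs(slope - 1), 0.15)
})

test_that("onset truth per organ class passes goodness-of-fit across seeds", {
  models <- default_onset_models()
  pass <- vapply(1:20, function(s) {
    g <- generate_faers(generator_config(n_cases = 2500, seed = 100 + s))
    truth <- g$manifest$onset_truth
    soc <- models$term[1]  # a shape-1 class with a known model
    x <- truth$tto_days[truth$index_soc == soc]
    ks <- suppressWarnings(
      ks.test(x, "pweibull", shape = models$shape[1], scale = models$scale[1]))
    ks$p.value > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("recovered onset days match the planted continuous interval", {
  g <- generate_faers(generator_config(n_cases = 5000, missing_date_prob = 0,
                                       duplicate_prob = 0, seed = 37))
  reports <- build_reports(g$tables)
  tto <- onset_days(reports, c("VOCLOSPORIN", "LUPKYNIS",
                               "BACKGROUND DRUG"))
  truth <- g$manifest$onset_truth
  joined <- dplyr::inner_join(tto[!is.na(tto$days), ], truth, by = "caseid")
  expect_gt(nrow(joined), 3000)
  # event date = start + floor(tto); same-day recodes to 0.5
  expect_true(all(joined$days == pmax(floor(joined$tto_days), 0.5)))
})

test_that("the tiny fixture is deterministic and hand-checkable", {
  fx1 <- fixture_small()
  fx2 <- fixture_small()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (kind in names(fx1$tables)) {
    write_faers_table(fx1$tables[[kind]], file.path(d1, paste0(kind, ".txt")),
                      toupper(kind))
    write_faers_table(fx2$tables[[kind]], file.path(d2, paste0(kind, ".txt")),
                      toupper(kind))
    expect_identical(readLines(file.path(d1, paste0(kind, ".txt"))),
                     readLines(file.path(d2, paste0(kind, ".txt"))))
  }

  reports <- build_reports(fx1$tables)
  expect_equal(reports$log$n_raw_versions, fx1$expected$n_versions)
  expect_equal(nrow(reports$cases), fx1$expected$n_cases)
  expect_true(fx1$expected$kept_version_c001 %in% reports$cases$primaryid)
  expect_true(fx1$expected$kept_version_c002 %in% reports$cases$primaryid)

  split <- build_cohort(reports, c("VOCLOSPORIN", "LUPKYNIS"))
  tab <- build_contingency_tables(split$cohort, split$background, "PT")
  h <- tab[tab$term == "Headache", ]
  expect_equal(unlist(h[, c("a", "b", "c", "d")], use.names = FALSE),
               unname(fx1$expected$headache))
  # hand arithmetic: (6*16)/(4*4) = 6; CI = exp(log 6 -+ 1.959964*se),
  # se = sqrt(1/6 + 1/4 + 1/4 + 1/16)
  est <- ror_ci(h$a, h$b, h$c, h$d)
  expect_equal(est$ror, fx1$expected$headache_ror)
  se <- sqrt(1 / 6 + 1 / 4 + 1 / 4 + 1 / 16)
  expect_equal(est$ci_low, 6 * exp(-1.959964 * se), tolerance = 1e-12)
  expect_equal(est$ci_high, 6 * exp(1.959964 * se), tolerance = 1e-12)
})
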