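# Synthetic FAERS-like data with known ground truth: planted case-level odds
# ratios per PT, planted Weibull onset distributions per organ class, a
# configurable demographic mix, and injected duplicate report versions. Every
# pipeline stage is testable against the generating truth without any
# database download.

#' Default synthetic PT catalog
#'
#' 100 synthetic preferred terms spread round-robin across 15 synthetic
#' organ classes, with baseline per-case reporting probabilities log-spaced
#' from 0.002 to 0.15. The resulting case-level profile is realistic for
#' spontaneous reports: about 3-4 PTs per case on average, a long tail of
#' rare terms, and a ~3% chance of a report carrying no reaction at all.
#' Term labels are deliberately synthetic (`PT_001` ... / `SOC_01` ...) —
#' this is not a MedDRA excerpt.
#'
#' @return Tibble `pt`, `soc`, `baseline_prob`.
#' @export
default_pt_catalog <- function() {
  n_pt <- 100L
  n_soc <- 15L
  tibble::tibble(
    pt = sprintf("PT_%03d", seq_len(n_pt)),
    soc = sprintf("SOC_%02d", rep_len(seq_len(n_soc), n_pt)),
    baseline_prob = exp(seq(log(0.002), log(0.15), length.out = n_pt))
  )
}

#' Default synthetic onset models
#'
#' One Weibull time-to-onset model per SOC in the catalog. Two organ classes
#' get a constant-hazard (shape 1) model and the rest get decreasing-hazard
#' (shape < 1) models, mirroring the typical spontaneous-report pattern in
#' which most event classes cluster shortly after treatment start while a
#' couple accrue at a roughly constant rate. Scales span ~60-190 days so the
#' pooled median lands near 100 days.
#'
#' @param pt_catalog A catalog tibble (for the SOC labels).
#' @return Tibble `term`, `shape`, `scale` (term is a SOC label; a PT label
#'   here would override its SOC's model).
#' @export
default_onset_models <- function(pt_catalog = default_pt_catalog()) {
  socs <- sort(unique(pt_catalog$soc))
  k <- length(socs)
  shape <- rep(c(0.7, 0.8, 0.9), length.out = k)
  shape[seq_len(min(2L, k))] <- 1.0  # two random-failure classes
  tibble::tibble(
    term = socs,
    shape = shape,
    scale = seq(60, 190, length.out = k)
  )
}

default_probs <- function() {
  list(
    # demographic mix of the synthetic cohort: predominantly female, mostly
    # age-unreported, consumer-reported, US-based — the case mix typical of
    # a recently approved specialty drug in FAERS
    sex_probs = c(F = 0.84, M = 0.1470, UNK = 0.013),
    age_band_probs = c("<18" = 0.009, "18-44" = 0.668, "45-64" = 0.274,
                       ">64" = 0.049),
    missing_age_prob = 0.605,
    reporter_probs = c(consumer = 0.830, physician = 0.0695,
                       pharmacist = 0.005, other_health_professional = 0.0955),
    country_probs = c(US = 0.995, SE = 0.002, ES = 0.002, GB = 0.001),
    outcome_probs = c(HO = 0.094, DE = 0.006, DS = 0.001, OT = 0.092,
                      none = 0.807)
  )
}

check_probs <- function(p, name) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop(name, " must be probabilities in [0, 1]", call. = FALSE)
  }
}
check_dist <- function(p, name) {
  check_probs(p, name)
  if (abs(sum(p) - 1) > 1e-6) {
    stop(name, " must sum to 1 (got ", sum(p), ")", call. = FALSE)
  }
}

#' Configuration for the synthetic FAERS generator
#'
#' @param n_cases Number of distinct cases (before duplicate injection).
#' @param target_drug_prob Probability a case's primary-suspect drug is the
#'   target drug; the rest get a background suspect drug.
#' @param pt_catalog Tibble `pt`, `soc`, `baseline_prob`: each PT is drawn
#'   independently per case with its baseline probability.
#' @param planted_signals Tibble `pt`, `ror`, `stratum`: for target-drug
#'   cases (in the stratum, if given: `"F"`, `"M"`, `"18-64"`, `">=65"`, or
#'   `NA` for all), the PT's probability is raised so the case-level odds
#'   ratio versus background is exactly `ror`.
#' @param onset_models Tibble `term`, `shape`, `scale`: Weibull onset model
#'   per SOC (or per PT, overriding its SOC).
#' @param sex_probs,age_band_probs,reporter_probs,country_probs,outcome_probs
#'   Categorical distributions (must each sum to 1).
#' @param missing_age_prob Probability a case reports no age.
#' @param missing_date_prob Probability a date field is degraded (half to
#'   month precision, half to empty), applied independently to the event
#'   date and the therapy start date.
#' @param duplicate_prob Probability a case additionally emits an earlier
#'   report version (lower PRIMARYID; usually an earlier FDA_DT, sometimes
#'   the same date so the PRIMARYID tie-break is exercised).
#' @param seed Integer seed; generation is fully reproducible under it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_cases,
                             target_drug_prob = 0.05,
                             pt_catalog = default_pt_catalog(),
                             planted_signals = NULL,
                             onset_models = default_onset_models(pt_catalog),
                             sex_probs = NULL, age_band_probs = NULL,
                             reporter_probs = NULL, country_probs = NULL,
                             outcome_probs = NULL,
                             missing_age_prob = NULL,
                             missing_date_prob = 0.10,
                             duplicate_prob = 0.20,
                             seed = 1L) {
  defaults <- default_probs()
  cfg <- list(
    n_cases = as.integer(n_cases),
    target_drug_prob = target_drug_prob,
    pt_catalog = tibble::as_tibble(pt_catalog),
    planted_signals = if (is.null(planted_signals)) {
      tibble::tibble(pt = character(0), ror = numeric(0),
                     stratum = character(0))
    } else {
      ps <- tibble::as_tibble(planted_signals)
      if (!"stratum" %in% names(ps)) ps$stratum <- NA_character_
      ps
    },
    onset_models = tibble::as_tibble(onset_models),
    sex_probs = sex_probs %||% defaults$sex_probs,
    age_band_probs = age_band_probs %||% defaults$age_band_probs,
    reporter_probs = reporter_probs %||% defaults$reporter_probs,
    country_probs = country_probs %||% defaults$country_probs,
    outcome_probs = outcome_probs %||% defaults$outcome_probs,
    missing_age_prob = missing_age_prob %||% defaults$missing_age_prob,
    missing_date_prob = missing_date_prob,
    duplicate_prob = duplicate_prob,
    seed = as.integer(seed)
  )
  if (cfg$n_cases < 1L) stop("n_cases must be >= 1", call. = FALSE)
  check_probs(cfg$target_drug_prob, "target_drug_prob")
  check_probs(cfg$missing_age_prob, "missing_age_prob")
  check_probs(cfg$missing_date_prob, "missing_date_prob")
  check_probs(cfg$duplicate_prob, "duplicate_prob")
  check_probs(cfg$pt_catalog$baseline_prob, "pt_catalog$baseline_prob")
  for (nm in c("sex_probs", "age_band_probs", "reporter_probs",
               "country_probs", "outcome_probs")) {
    check_dist(cfg[[nm]], nm)
  }
  if (nrow(cfg$planted_signals)) {
    if (any(cfg$planted_signals$ror <= 0)) {
      stop("planted odds ratios must be > 0", call. = FALSE)
    }
    unknown <- setdiff(cfg$planted_signals$pt, cfg$pt_catalog$pt)
    if (length(unknown)) {
      stop("planted signal PTs not in catalog: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(cfg, class = "generator_config")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' The PT-to-SOC map implied by a generator catalog
#' @param config A `generator_config`.
#' @return A `pt_soc_map` covering every catalog PT.
#' @export
generator_pt_map <- function(config) {
  pt_soc_map(config$pt_catalog$pt, config$pt_catalog$soc)
}

# Raise a baseline probability p0 so the planted case-level odds ratio is
# exactly ror: p1/(1-p1) = ror * p0/(1-p0).
planted_prob <- function(p0, ror) {
  odds <- ror * p0 / (1 - p0)
  odds / (1 + odds)
}

date_token <- function(dates) format(dates, "%Y%m%d")

quarter_of <- function(dates) {
  paste0(format(dates, "%Y"), "Q", (as.integer(format(dates, "%m")) - 1L) %/% 3L + 1L)
}

# Degrade date tokens: with prob p, half to month precision, half to empty.
degrade_dates <- function(tokens, p) {
  n <- length(tokens)
  u <- stats::runif(n)
  tokens[u < p / 2] <- substr(tokens[u < p / 2], 1L, 6L)
  tokens[u >= p / 2 & u < p] <- ""
  tokens
}

background_drug_pool <- sprintf("BACKGROUND DRUG %02d", 1:12)

#' Generate a synthetic FAERS-like dataset
#'
#' Produces the five quarterly ASCII streams (DEMO, DRUG, REAC, THER, OUTC)
#' plus a ground-truth manifest. Per case: the suspect drug is the target
#' with probability `target_drug_prob` (role PS) and 0-2 concomitant drugs
#' are added; each catalog PT is drawn independently, with planted signals
#' raising the target-arm probability so the case-level odds ratio equals
#' the planted value exactly; one of the case's drawn PTs (uniformly chosen,
#' the "index" reaction) drives the event onset, drawn from its SOC's (or
#' its own) Weibull model and added to a random therapy start date; the FDA
#' receipt date follows the event by a 0-90 day reporting lag, clamped into
#' the 2021Q1-2024Q2 window; duplicates are cloned as an earlier report
#' version with a lower PRIMARYID. Fully reproducible under `config$seed`.
#'
#' @param config A `generator_config`.
#' @param dir Optional directory: when given, writes per-quarter ASCII files
#'   (`demo_2021q1.txt`, ...), the catalog's PT-to-SOC dictionary
#'   (`pt_soc_map.tsv`) and the manifest (`manifest.json`).
#' @return List with `tables` (the five tibbles, concatenated over
#'   quarters) and `manifest` (ground truth: `n_cases` before duplication,
#'   `n_duplicates`, planted signals, onset models, per-case index PT and
#'   true continuous onset interval, seed).
#' @export
generate_faers <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_cases
  cat_tab <- config$pt_catalog

  caseid_num <- 1000000L + seq_len(n)
  caseid <- as.character(caseid_num)
  primaryid <- as.character(caseid_num * 10 + 2)

  sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
  age_missing <- stats::runif(n) < config$missing_age_prob
  band <- sample(names(config$age_band_probs), n, TRUE, config$age_band_probs)
  age_years <- dplyr::case_match(band,
    "<18" ~ stats::runif(n, 2, 17),
    "18-44" ~ stats::runif(n, 18, 44),
    "45-64" ~ stats::runif(n, 45, 64),
    ">64" ~ stats::runif(n, 65, 85)
  )
  age <- as.character(round(age_years))
  age_cod <- rep("YR", n)
  infant <- !age_missing & age_years < 2
  age[infant] <- as.character(round(age_years[infant] * 12))
  age_cod[infant] <- "MON"
  age[age_missing] <- ""
  age_cod[age_missing] <- ""

  occp_map <- c(consumer = "CN", physician = "MD", pharmacist = "PH",
                other_health_professional = "HP")
  occp <- unname(occp_map[sample(names(config$reporter_probs), n, TRUE,
                                 config$reporter_probs)])
  country <- sample(names(config$country_probs), n, TRUE, config$country_probs)

  target <- stats::runif(n) < config$target_drug_prob

  # per-PT independent draws, with planted odds ratios on the target arm
  in_stratum <- function(s) {
    if (is.na(s)) rep(TRUE, n)
    else switch(s,
      "F" = sex == "F",
      "M" = sex == "M",
      "18-64" = !age_missing & age_years >= 18 & age_years <= 64,
      ">=65" = !age_missing & age_years >= 65,
      stop("unknown planted stratum: ", s, call. = FALSE))
  }
  pt_mat <- matrix(FALSE, n, nrow(cat_tab))
  for (j in seq_len(nrow(cat_tab))) {
    p <- rep(cat_tab$baseline_prob[j], n)
    hits <- which(config$planted_signals$pt == cat_tab$pt[j])
    for (h in hits) {
      sel <- target & in_stratum(config$planted_signals$stratum[h])
      p[sel] <- planted_prob(cat_tab$baseline_prob[j],
                             config$planted_signals$ror[h])
    }
    pt_mat[, j] <- stats::runif(n) < p
  }
  rx_idx <- which(pt_mat, arr.ind = TRUE)
  reac <- tibble::tibble(case = rx_idx[, 1L],
                         pt = cat_tab$pt[rx_idx[, 2L]])
  reac <- reac[order(reac$case), , drop = FALSE]

  # index reaction per case (uniform among the case's drawn PTs) drives onset
  pick <- order(reac$case, stats::runif(nrow(reac)))
  first <- pick[!duplicated(reac$case[pick])]
  index_case <- reac$case[first]
  index_pt <- reac$pt[first]

  # onset model: PT-specific row wins over the PT's SOC row
  om <- config$onset_models
  soc_of_pt <- cat_tab$soc[match(index_pt, cat_tab$pt)]
  mi <- match(index_pt, om$term)
  mi[is.na(mi)] <- match(soc_of_pt[is.na(mi)], om$term)
  if (anyNA(mi)) stop("no onset model for some catalog SOCs", call. = FALSE)
  tto <- stats::rweibull(length(index_case), om$shape[mi], om$scale[mi])

  start_date <- as.Date("2021-01-01") + sample(0:1094, n, TRUE)
  event_date <- rep(as.Date(NA), n)
  event_date[index_case] <- start_date[index_case] + floor(tto)
  lag <- sample(0:90, n, TRUE)
  fda_date <- ifelse(is.na(event_date), start_date + lag, event_date + lag)
  fda_date <- as.Date(fda_date, origin = "1970-01-01")
  fda_date <- pmin(pmax(fda_date, as.Date("2021-01-02")), as.Date("2024-06-30"))

  event_tok <- ifelse(is.na(event_date), "", date_token(event_date))
  has_ev <- nzchar(event_tok)
  event_tok[has_ev] <- degrade_dates(event_tok[has_ev], config$missing_date_prob)
  start_tok <- degrade_dates(date_token(start_date), config$missing_date_prob)

  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid,
    fda_dt = date_token(fda_date), event_dt = event_tok,
    sex = sex, age = age, age_cod = age_cod, occp_cod = occp,
    reporter_country = country, quarter = quarter_of(fda_date)
  )

  ps_name <- ifelse(target,
                    sample(c("VOCLOSPORIN", "LUPKYNIS", "LUPKYNIS 7.9MG"),
                           n, TRUE),
                    sample(background_drug_pool, n, TRUE))
  ps_ai <- ifelse(target, "VOCLOSPORIN", ps_name)
  n_conc <- sample(0:2, n, TRUE)
  conc_case <- rep(seq_len(n), n_conc)
  drug <- tibble::tibble(
    primaryid = c(primaryid, primaryid[conc_case]),
    drug_seq = c(rep("1", n), as.character(
      sequence(n_conc[n_conc > 0]) + 1L)),
    role_cod = c(rep("PS", n), rep("C", length(conc_case))),
    drugname = c(ps_name, sample(background_drug_pool, length(conc_case), TRUE)),
    prod_ai = c(ps_ai, rep("", length(conc_case)))
  )
  drug$prod_ai[drug$role_cod == "C"] <- drug$drugname[drug$role_cod == "C"]

  reac_out <- tibble::tibble(primaryid = primaryid[reac$case], pt = reac$pt)

  ther <- tibble::tibble(primaryid = primaryid, dsg_drug_seq = "1",
                         start_dt = start_tok, end_dt = "")

  outc_draw <- sample(names(config$outcome_probs), n, TRUE,
                      config$outcome_probs)
  has_outc <- outc_draw != "none"
  extra <- has_outc & outc_draw != "OT" & stats::runif(n) < 0.02
  outc <- tibble::tibble(
    primaryid = c(primaryid[has_outc], primaryid[extra]),
    outc_cod = c(outc_draw[has_outc], rep("OT", sum(extra)))
  )

  # duplicate (earlier) report versions: lower primaryid, earlier-or-equal
  # fda_dt; an equal date exercises the higher-PRIMARYID tie-break
  dup <- which(stats::runif(n) < config$duplicate_prob)
  if (length(dup)) {
    back <- sample(0:60, length(dup), TRUE)
    back[stats::runif(length(dup)) < 0.25] <- 0L
    dup_fda <- pmax(fda_date[dup] - back, as.Date("2021-01-01"))
    dup_pid <- as.character(caseid_num[dup] * 10 + 1)
    demo_dup <- demo[dup, , drop = FALSE]
    demo_dup$primaryid <- dup_pid
    demo_dup$fda_dt <- date_token(dup_fda)
    demo_dup$quarter <- quarter_of(dup_fda)
    demo <- dplyr::bind_rows(demo, demo_dup)
    clone <- function(x) {
      i <- match(x$primaryid, primaryid[dup])
      y <- x[!is.na(i), , drop = FALSE]
      y$primaryid <- dup_pid[i[!is.na(i)]]
      dplyr::bind_rows(x, y)
    }
    drug <- clone(drug); reac_out <- clone(reac_out)
    ther <- clone(ther); outc <- clone(outc)
  }

  tables <- list(demo = demo, drug = drug, reac = reac_out,
                 ther = ther, outc = outc)
  manifest <- list(
    n_cases = n,
    n_duplicates = length(dup),
    n_target_cases = sum(target),
    planted_signals = config$planted_signals,
    onset_models = config$onset_models,
    onset_truth = tibble::tibble(caseid = caseid[index_case],
                                 index_pt = index_pt,
                                 index_soc = soc_of_pt,
                                 tto_days = tto),
    seed = config$seed
  )

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (q in sort(unique(demo$quarter))) {
      pids <- demo$primaryid[demo$quarter == q]
      tag <- tolower(q)
      write_faers_table(demo[demo$quarter == q, ],
                        file.path(dir, paste0("demo_", tag, ".txt")), "DEMO")
      for (kind in c("drug", "reac", "ther", "outc")) {
        tb <- tables[[kind]]
        write_faers_table(tb[tb$primaryid %in% pids, ],
                          file.path(dir, paste0(kind, "_", tag, ".txt")),
                          toupper(kind))
      }
    }
    write_pt_soc_map(generator_pt_map(config), file.path(dir, "pt_soc_map.tsv"))
    man_json <- manifest
    man_json$planted_signals <- as.data.frame(man_json$planted_signals)
    man_json$onset_models <- as.data.frame(man_json$onset_models)
    man_json$onset_truth <- NULL  # bulky; in-memory manifest keeps it
    jsonlite::write_json(man_json, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(tables = tables, manifest = manifest)
}

#' Tiny deterministic fixture dataset
#'
#' A hand-built, hand-checkable dataset of 30 cases (no randomness): 10
#' cohort cases with the target drug VOCLOSPORIN/LUPKYNIS as primary
#' suspect, 20 background cases. It contains, by construction: a case with
#' two report versions resolved by FDA_DT, another resolved by the
#' higher-PRIMARYID tie-break, a month-precision event date, an unknown-sex
#' case, a same-day onset, and a planted PT ("Headache": 6 of 10 cohort
#' cases vs 4 of 20 background cases, so the 2x2 is a=6, b=4, c=4, d=16 and
#' the ROR is exactly 6) plus a universal PT ("Fatigue") that exercises the
#' zero-cell correction (b = 0).
#'
#' @return List with `tables` (the five tibbles), `map` (a `pt_soc_map`
#'   for the two PTs), and `expected` (hand-computed values asserted in the
#'   tests: the 2x2 cells and case counts).
#' @export
fixture_small <- function() {
  n <- 30L
  caseid <- sprintf("C%03d", seq_len(n))
  primaryid <- paste0("9", sprintf("%03d", seq_len(n)), "2")

  fda <- rep("20230601", n)
  event <- sprintf("2023%02d15", rep(1:5, 6))
  sex <- rep(c("F", "F", "UNK", "M", "F"), 6)
  age <- as.character(rep(c(34, 51, 28, 67, NA), 6))
  age[is.na(rep(c(34, 51, 28, 67, NA), 6))] <- ""
  age_cod <- ifelse(nzchar(age), "YR", "")

  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid, fda_dt = fda, event_dt = event,
    sex = sex, age = age, age_cod = age_cod,
    occp_cod = rep(c("CN", "MD", "CN", "HP", "PH"), 6),
    reporter_country = rep("US", n), quarter = "2023Q2"
  )
  # C001: an older version superseded by FDA_DT; C002: same-date tie broken
  # by the higher PRIMARYID
  demo$event_dt[4] <- "202303"   # month-precision event date
  old_versions <- tibble::tibble(
    primaryid = c("90011", "90021"), caseid = c("C001", "C002"),
    fda_dt = c("20230101", "20230601"), event_dt = c("20230115", "20230215"),
    sex = c("M", "M"), age = c("", ""), age_cod = c("", ""),
    occp_cod = c("CN", "CN"), reporter_country = c("US", "US"),
    quarter = c("2023Q1", "2023Q2")
  )
  demo <- dplyr::bind_rows(demo, old_versions)

  cohort_ids <- primaryid[1:10]
  drug <- tibble::tibble(
    primaryid = primaryid,
    drug_seq = "1",
    role_cod = "PS",
    drugname = c(rep(c("VOCLOSPORIN", "LUPKYNIS 7.9MG"), 5),
                 rep("OTHER DRUG", 20)),
    prod_ai = c(rep("VOCLOSPORIN", 10), rep("OTHER DRUG", 20))
  )

  # Headache: cohort cases 1-6, background cases 11-14 -> a=6 b=4 c=4 d=16
  headache <- primaryid[c(1:6, 11:14)]
  reac <- dplyr::bind_rows(
    tibble::tibble(primaryid = headache, pt = "Headache"),
    tibble::tibble(primaryid = primaryid, pt = "Fatigue")
  )

  # day-precision therapy starts for the cohort; case C005 is a same-day onset
  start <- sprintf("2023%02d%02d", rep(1:5, 2), rep(c(5, 10), each = 5))
  start[5] <- "20230515"
  ther <- tibble::tibble(
    primaryid = cohort_ids, dsg_drug_seq = "1",
    start_dt = start, end_dt = ""
  )
  demo$event_dt[5] <- "20230515"

  outc <- tibble::tibble(
    primaryid = c(primaryid[1], primaryid[1], primaryid[2], primaryid[11]),
    outc_cod = c("HO", "OT", "DE", "HO")
  )

  list(
    tables = list(demo = demo, drug = drug, reac = reac, ther = ther,
                  outc = outc),
    map = pt_soc_map(c("Headache", "Fatigue"),
                     c("Nervous system disorders",
                       "General disorders and administration site conditions")),
    expected = list(
      n_cases = 30L, n_versions = 32L,
      kept_version_c001 = "90012", kept_version_c002 = "90022",
      headache = c(a = 6, b = 4, c = 4, d = 16), headache_ror = 6,
      same_day_caseid = "C005"
    )
  )
}
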