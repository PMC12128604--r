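# Case assembly: dedup raw report versions, normalize demographics, and bundle
# the five raw streams into one relational `faers_reports` object.

sex_levels <- c("F", "M", "UNK")
age_band_levels <- c("<18", "18-44", "45-64", ">64", "unknown")
reporter_levels <- c("consumer", "physician", "pharmacist",
                     "other_health_professional", "unknown")
outcome_levels <- c("death", "disability", "hospitalization", "other", "unknown")

#' Deduplicate FAERS report versions
#'
#' A FAERS case (CASEID) may be submitted in several versions, each with its
#' own PRIMARYID. Following the FDA-recommended rule, versions are grouped by
#' CASEID and the version with the most recent FDA receipt date (FDA_DT) is
#' kept; ties on FDA_DT are broken by the numerically higher PRIMARYID. A
#' version whose FDA_DT does not parse loses every comparison (it is kept only
#' if it is the sole version of its case). Output order is stable by CASEID.
#'
#' @param demo Tibble of raw DEMO records (columns `primaryid`, `caseid`,
#'   `fda_dt`, ...), as returned by [read_faers_table()].
#' @return The subset of `demo` with exactly one row per `caseid`.
#' @export
deduplicate_reports <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  if (nrow(demo) == 0L) return(demo)
  key_dt <- partial_date_key(demo$fda_dt)
  key_id <- suppressWarnings(as.numeric(demo$primaryid))
  key_id[is.na(key_id)] <- -Inf
  ord <- order(demo$caseid, -key_dt, -key_id)
  demo <- demo[ord, , drop = FALSE]
  demo[!duplicated(demo$caseid), , drop = FALSE]
}

#' Match drug rows against target name tokens
#'
#' A drug row matches when any token is a substring of the upper-cased
#' `drugname` or `prod_ai` — the keyword retrieval used to find a target
#' drug (e.g. generic name plus trade name) in the free-text DRUG table.
#'
#' @param drugname,prod_ai Character vectors.
#' @param names Non-empty character vector of name tokens (upper-cased
#'   internally).
#' @return Logical vector.
#' @examples
#' match_drug("LUPKYNIS 7.9MG", "", c("VOCLOSPORIN", "LUPKYNIS"))
#' @export
match_drug <- function(drugname, prod_ai, names) {
  stopifnot(length(names) > 0)
  names <- toupper(trimws(names))
  dn <- toupper(as.character(drugname))
  ai <- toupper(as.character(prod_ai))
  dn[is.na(dn)] <- ""
  ai[is.na(ai)] <- ""
  hit <- rep(FALSE, length(dn))
  for (tok in names) {
    hit <- hit | grepl(tok, dn, fixed = TRUE) | grepl(tok, ai, fixed = TRUE)
  }
  hit
}

normalize_sex <- function(sex) {
  s <- toupper(trimws(as.character(sex)))
  out <- ifelse(s %in% c("F", "M"), s, "UNK")
  out[is.na(s)] <- "UNK"
  out
}

normalize_reporter <- function(occp_cod) {
  o <- toupper(trimws(as.character(occp_cod)))
  o[is.na(o)] <- ""
  dplyr::case_match(o,
    "CN" ~ "consumer",
    "MD" ~ "physician",
    "PH" ~ "pharmacist",
    c("HP", "OT") ~ "other_health_professional",
    .default = "unknown"
  )
}

age_band_of <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "unknown",
    age_years < 18 ~ "<18",
    age_years <= 44 ~ "18-44",
    age_years <= 64 ~ "45-64",
    TRUE ~ ">64"
  )
}

# Most severe outcome per case: death > disability > hospitalization > other;
# cases with no OUTC row are "unknown".
outcome_category <- function(outc_cod) {
  dplyr::case_match(toupper(trimws(as.character(outc_cod))),
    "DE" ~ "death",
    "DS" ~ "disability",
    "HO" ~ "hospitalization",
    c("LT", "CA", "RI", "OT") ~ "other",
    .default = "unknown"
  )
}

#' Assemble deduplicated safety reports
#'
#' Runs [deduplicate_reports()] on the DEMO stream, restricts the DRUG, REAC,
#' THER and OUTC streams to the surviving report versions, normalizes
#' demographic codes (sex to F/M/UNK, age to years with derived age band,
#' reporter occupation, country), and drops cases with no reaction rows
#' (counted in the build log — a report without any adverse-event term
#' carries no analyzable signal information).
#'
#' @param tables Named list of raw tibbles `demo`, `drug`, `reac`, `ther`,
#'   `outc`, as from [read_faers_quarters()] or [generate_faers()].
#' @return A `faers_reports` object: list of tibbles `cases` (one row per
#'   case), `drugs`, `reactions`, `therapy`, `outcomes` (all keyed by
#'   `primaryid`/`caseid`), plus a `log` list with `n_raw_versions`,
#'   `n_duplicates_removed`, `n_dropped_no_reaction`.
#' @export
build_reports <- function(tables) {
  stopifnot(all(c("demo", "drug", "reac") %in% names(tables)))
  demo <- tables$demo
  dedup <- deduplicate_reports(demo)
  keep_ids <- dedup$primaryid

  reac <- dplyr::filter(tables$reac, .data$primaryid %in% keep_ids)
  reac$pt <- gsub("\\s+", " ", trimws(reac$pt))
  reac <- dplyr::filter(reac, nzchar(.data$pt))
  reac <- dplyr::distinct(reac, .data$primaryid, .data$pt)

  has_reac <- dedup$primaryid %in% reac$primaryid
  dropped_no_reaction <- sum(!has_reac)
  cases <- dedup[has_reac, , drop = FALSE]

  age_years <- normalize_age(cases$age, cases$age_cod)
  cases <- tibble::tibble(
    primaryid = cases$primaryid,
    caseid = cases$caseid,
    fda_dt = cases$fda_dt,
    event_dt = cases$event_dt,
    sex = normalize_sex(cases$sex),
    age_years = age_years,
    age_band = age_band_of(age_years),
    reporter = normalize_reporter(cases$occp_cod),
    country = trimws(cases$reporter_country),
    quarter = cases$quarter
  )

  filter_ids <- function(x) {
    if (is.null(x)) return(NULL)
    dplyr::filter(x, .data$primaryid %in% cases$primaryid)
  }
  drugs <- filter_ids(tables$drug)
  if (!is.null(drugs)) {
    drugs$role_cod <- toupper(trimws(drugs$role_cod))
  }
  outc <- filter_ids(tables$outc)
  if (!is.null(outc)) {
    outc$outc_cod <- toupper(trimws(outc$outc_cod))
  }

  new_faers_reports(
    cases = cases,
    drugs = drugs,
    reactions = dplyr::filter(reac, .data$primaryid %in% cases$primaryid),
    therapy = filter_ids(tables$ther),
    outcomes = outc,
    log = list(
      n_raw_versions = nrow(demo),
      n_duplicates_removed = nrow(demo) - nrow(dedup),
      n_dropped_no_reaction = dropped_no_reaction
    )
  )
}

#' Construct a `faers_reports` object from component tibbles
#'
#' Low-level constructor for the relational container the analysis functions
#' operate on. [build_reports()] is the usual entry point; this constructor
#' exists for building cohorts directly in code (simulation studies, worked
#' examples with prescribed category counts).
#'
#' @param cases Tibble with one row per case: `primaryid`, `caseid`,
#'   `fda_dt`, `event_dt`, `sex`, `age_years`, `age_band`, `reporter`,
#'   `country` (missing optional columns are filled with `NA`).
#' @param drugs,reactions,therapy,outcomes Tibbles keyed by `primaryid`
#'   (`reactions` requires columns `primaryid`, `pt`).
#' @param log List of build counters.
#' @return A validated `faers_reports` object.
#' @export
new_faers_reports <- function(cases, drugs = NULL, reactions = NULL,
                              therapy = NULL, outcomes = NULL, log = list()) {
  stopifnot(is.data.frame(cases),
            all(c("primaryid", "caseid") %in% names(cases)))
  cases <- tibble::as_tibble(cases)
  for (col in c("fda_dt", "event_dt", "country", "quarter")) {
    if (!col %in% names(cases)) cases[[col]] <- NA_character_
  }
  if (!"sex" %in% names(cases)) cases$sex <- "UNK"
  if (!"age_years" %in% names(cases)) cases$age_years <- NA_real_
  if (!"age_band" %in% names(cases)) cases$age_band <- age_band_of(cases$age_years)
  if (!"reporter" %in% names(cases)) cases$reporter <- "unknown"
  if (anyDuplicated(cases$caseid)) {
    stop("`cases` must have one row per caseid (deduplicate first)",
         call. = FALSE)
  }
  if (!all(cases$sex %in% sex_levels)) {
    stop("`sex` must be one of ", paste(sex_levels, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(reactions)) {
    reactions <- tibble::tibble(primaryid = character(0), pt = character(0))
  }
  structure(
    list(cases = tibble::as_tibble(cases),
         drugs = drugs, reactions = tibble::as_tibble(reactions),
         therapy = therapy, outcomes = outcomes, log = log),
    class = "faers_reports"
  )
}

#' @export
print.faers_reports <- function(x, ...) {
  cat("<faers_reports> ", nrow(x$cases), " cases, ",
      nrow(x$reactions), " reaction rows, ",
      length(unique(x$reactions$pt)), " distinct PTs\n", sep = "")
  if (length(x$log)) {
    cat("  build log:",
        paste(names(x$log), unlist(x$log), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of cases in a `faers_reports` object
#' @param reports A `faers_reports` object.
#' @return Integer case count.
#' @export
n_cases <- function(reports) nrow(reports$cases)

# Subset a faers_reports object to a set of caseids, keeping all component
# tables consistent.
filter_reports <- function(reports, caseids) {
  keep <- reports$cases$caseid %in% caseids
  cases <- reports$cases[keep, , drop = FALSE]
  ids <- cases$primaryid
  sub <- function(x) if (is.null(x)) NULL else
    dplyr::filter(x, .data$primaryid %in% ids)
  new_faers_reports(cases,
                    drugs = sub(reports$drugs),
                    reactions = sub(reports$reactions),
                    therapy = sub(reports$therapy),
                    outcomes = sub(reports$outcomes),
                    log = reports$log)
}

#' Split reports into a target-drug cohort and its background
#'
#' A case belongs to the cohort when at least one of its drug rows matches
#' the target name tokens *and* carries the requested role code (the default
#' `"PS"` keeps only reports naming the target as the primary suspect).
#' Everything else is background; the two parts partition the input.
#'
#' @param reports A deduplicated `faers_reports` object with a `drugs` table.
#' @param names Character vector of target drug name tokens.
#' @param role FAERS role code the matching drug row must carry
#'   (`"PS"`, `"SS"`, `"C"`, `"I"`).
#' @return `list(cohort = , background = )` of `faers_reports`.
#' @export
build_cohort <- function(reports, names, role = "PS") {
  stopifnot(inherits(reports, "faers_reports"), !is.null(reports$drugs))
  role <- match.arg(toupper(role), faers_role_codes)
  drugs <- reports$drugs
  hit <- match_drug(drugs$drugname, drugs$prod_ai, names) &
    drugs$role_cod == role
  cohort_pids <- unique(drugs$primaryid[hit])
  cohort_caseids <- reports$cases$caseid[reports$cases$primaryid %in% cohort_pids]
  list(
    cohort = filter_reports(reports, cohort_caseids),
    background = filter_reports(reports,
                                setdiff(reports$cases$caseid, cohort_caseids))
  )
}

# Half-up rounding to `digits` decimals (base round() is half-even; reported
# percentages follow the half-up convention of the published tables).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Summarize a cohort's clinical characteristics
#'
#' Produces the standard case-characteristics table for a spontaneous-report
#' cohort: counts and percentages by sex, age band, most severe outcome,
#' reporter occupation, and reporter country. A case with several outcome
#' codes contributes only its most severe one, under the precedence
#' death > disability > hospitalization > other; a case with no outcome row
#' is "unknown". Percentages are 100*count/n_total rounded half-up to two
#' decimals.
#'
#' @param cohort A non-empty `faers_reports` object.
#' @return A `cohort_summary`: list with `n_total` and tibbles `by_sex`,
#'   `by_age_band`, `by_outcome`, `by_reporter`, `by_country`, each with
#'   columns `category`, `n`, `pct`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "faers_reports"))
  n_total <- nrow(cohort$cases)
  if (n_total == 0L) stop("cannot summarize an empty cohort", call. = FALSE)

  tab <- function(values, levels) {
    counts <- table(factor(values, levels = levels))
    tibble::tibble(category = names(counts),
                   n = as.integer(counts),
                   pct = round_half_up(100 * as.integer(counts) / n_total, 2))
  }

  # most severe outcome per case
  severity <- stats::setNames(seq_along(outcome_levels), outcome_levels)
  worst <- rep("unknown", n_total)
  if (!is.null(cohort$outcomes) && nrow(cohort$outcomes)) {
    oc <- cohort$outcomes
    cat_rank <- severity[outcome_category(oc$outc_cod)]
    best <- tapply(cat_rank, oc$primaryid, min)
    idx <- match(cohort$cases$primaryid, names(best))
    worst[!is.na(idx)] <- outcome_levels[best[idx[!is.na(idx)]]]
  }

  country <- cohort$cases$country
  country[is.na(country) | !nzchar(country)] <- "unknown"

  structure(list(
    n_total = n_total,
    by_sex = tab(cohort$cases$sex, sex_levels),
    by_age_band = tab(cohort$cases$age_band, age_band_levels),
    by_outcome = tab(worst, outcome_levels),
    by_reporter = tab(cohort$cases$reporter, reporter_levels),
    by_country = tab(country, sort(unique(country)))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", x$n_total, "cases\n")
  for (nm in c("by_sex", "by_age_band", "by_outcome", "by_reporter")) {
    tb <- x[[nm]]
    cat(" ", sub("^by_", "", nm), ": ",
        paste0(tb$category, " ", tb$n, " (", sprintf("%.2f", tb$pct), "%)",
               collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a cohort summary as a delimited table
#'
#' @param x A `cohort_summary`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(x, path) {
  rows <- dplyr::bind_rows(lapply(
    c("by_sex", "by_age_band", "by_outcome", "by_reporter", "by_country"),
    function(nm) dplyr::mutate(x[[nm]], breakdown = sub("^by_", "", nm),
                               .before = 1)
  ))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
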