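# Time to onset (TTO): days from the start of the suspect drug's therapy to
# the reported event onset, with binned distributions, median/IQR summaries,
# Kruskal-Wallis group comparison, and Weibull failure-type classification.

onset_bin_breaks <- c(0, 30, 60, 90, 180, 360, Inf)
onset_bin_labels <- c("(0,30]", "(30,60]", "(60,90]", "(90,180]",
                      "(180,360]", "(360,Inf)")

#' Time to onset per case
#'
#' For each case, takes the earliest day-precision therapy start date among
#' the therapy rows belonging to a drug row that matches the target name
#' tokens, and the report's day-precision event onset date, and returns the
#' interval in whole days. Same-day onset maps to 0.5 day (so it stays in
#' the analysis and in the first bin); a negative interval or any
#' partial-precision date yields a missing value, with the reason recorded.
#'
#' @param reports A `faers_reports` object with `drugs` and `therapy`.
#' @param names Target drug name tokens (as in [match_drug()]).
#' @return Tibble `caseid`, `days` (positive or `NA`), `reason` (`"ok"`,
#'   `"no_event_date"`, `"partial_event_date"`, `"no_start_date"`,
#'   `"negative_interval"`).
#' @export
onset_days <- function(reports, names) {
  stopifnot(inherits(reports, "faers_reports"),
            !is.null(reports$drugs), !is.null(reports$therapy))
  cases <- reports$cases

  drugs <- reports$drugs
  hit <- match_drug(drugs$drugname, drugs$prod_ai, names)
  target_drugs <- drugs[hit, c("primaryid", "drug_seq"), drop = FALSE]

  ther <- dplyr::inner_join(
    reports$therapy, target_drugs,
    by = c("primaryid", "dsg_drug_seq" = "drug_seq")
  )
  ther$start_date <- partial_date_to_date(ther$start_dt)
  starts <- ther[!is.na(ther$start_date), c("primaryid", "start_date")]
  if (nrow(starts)) {
    starts <- dplyr::summarise(dplyr::group_by(starts, .data$primaryid),
                               start_date = min(.data$start_date),
                               .groups = "drop")
  }

  ev <- parse_partial_date(cases$event_dt)
  event_date <- partial_date_to_date(cases$event_dt)
  start_date <- starts$start_date[match(cases$primaryid, starts$primaryid)]

  raw_days <- as.numeric(event_date - start_date)
  days <- ifelse(!is.na(raw_days) & raw_days == 0, 0.5, raw_days)
  days[!is.na(days) & days < 0] <- NA_real_

  reason <- dplyr::case_when(
    is.na(ev$precision) ~ "no_event_date",
    ev$precision != "day" ~ "partial_event_date",
    is.na(start_date) ~ "no_start_date",
    raw_days < 0 ~ "negative_interval",
    TRUE ~ "ok"
  )
  tibble::tibble(caseid = cases$caseid, days = days, reason = reason)
}

#' Bin onset intervals into the standard reporting windows
#'
#' Right-closed bins at 30, 60, 90, 180 and 360 days ((0,30] is "the first
#' month"); counts partition the non-missing sample.
#'
#' @param days Numeric vector of onset intervals (NAs dropped).
#' @return Tibble `bin`, `n`, `pct` (half-up, two decimals; `NaN` on an
#'   empty sample).
#' @export
bin_onsets <- function(days) {
  days <- days[!is.na(days)]
  counts <- table(cut(days, breaks = onset_bin_breaks, right = TRUE,
                      labels = onset_bin_labels))
  tibble::tibble(bin = onset_bin_labels,
                 n = as.integer(counts),
                 pct = round_half_up(100 * as.integer(counts) / length(days), 2))
}

#' Median and IQR of an onset sample
#'
#' Quantiles use the linear-interpolation definition (`stats::quantile`
#' type 7, the R default); stated explicitly because IQRs differ across
#' quantile definitions.
#'
#' @param days Numeric vector of onset intervals (NAs dropped; must leave
#'   at least one value).
#' @return Tibble `n`, `median`, `q1`, `q3`.
#' @export
summarize_onset <- function(days) {
  days <- days[!is.na(days)]
  if (!length(days)) stop("empty onset sample", call. = FALSE)
  q <- stats::quantile(days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(days), median = q[2], q1 = q[1], q3 = q[3])
}

#' Kruskal-Wallis comparison of onset distributions across groups
#'
#' Rank-based test of whether the onset-time distributions differ across
#' event groups (SOCs or PTs), with the usual tie correction and the
#' chi-squared approximation on groups-1 degrees of freedom. The degenerate
#' all-identical case returns H = 0, p = 1.
#'
#' @param samples Named list of numeric vectors (>= 2 groups, each
#'   non-empty after NA removal).
#' @return Tibble `statistic` (H), `df`, `p_value`.
#' @export
compare_onset_groups <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  samples <- lapply(samples, function(x) x[!is.na(x)])
  if (any(lengths(samples) == 0L)) {
    stop("every group needs at least one observation", call. = FALSE)
  }
  values <- unlist(samples, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(statistic = 0, df = length(samples) - 1L,
                          p_value = 1))
  }
  g <- factor(rep(seq_along(samples), lengths(samples)))
  kt <- stats::kruskal.test(values, g)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value)
}

#' Per-group onset table for a cohort
#'
#' Joins each case's onset interval to its event terms and summarizes per
#' term: n, median, IQR, and (for groups with at least `min_n` onsets) the
#' Weibull fit with failure-type classification.
#'
#' @param reports `faers_reports` cohort.
#' @param names Target drug tokens (for [onset_days()]).
#' @param level `"PT"` or `"SOC"`.
#' @param map `pt_soc_map` (SOC level only).
#' @param terms Optional character vector restricting the groups (e.g. the
#'   positive signals); default all observed terms.
#' @param min_n Minimum onsets for a Weibull fit (default 10).
#' @param ci_reps Bootstrap resamples for the shape CI.
#' @param seed Seed for the bootstrap.
#' @return Tibble `term`, `n`, `median`, `q1`, `q3`, `shape`,
#'   `shape_ci_low`, `shape_ci_high`, `scale`, `failure_type` (`NA` where no
#'   fit was attempted).
#' @export
onset_by_term <- function(reports, names, level = c("PT", "SOC"), map = NULL,
                          terms = NULL, min_n = 10L, ci_reps = 1000L,
                          seed = NULL) {
  level <- match.arg(toupper(level), c("PT", "SOC"))
  tto <- onset_days(reports, names)
  tto <- tto[!is.na(tto$days), c("caseid", "days")]
  rx <- reports$reactions
  rx$caseid <- reports$cases$caseid[match(rx$primaryid, reports$cases$primaryid)]
  rx$term <- if (level == "PT") rx$pt else soc_of(rx$pt, map)
  rx <- dplyr::distinct(rx[rx$term != UNMAPPED, c("caseid", "term")])
  joined <- dplyr::inner_join(rx, tto, by = "caseid")
  if (!is.null(terms)) joined <- joined[joined$term %in% terms, , drop = FALSE]

  groups <- split(joined$days, joined$term)
  rows <- lapply(names(groups), function(tm) {
    d <- groups[[tm]]
    s <- summarize_onset(d)
    fit <- if (length(d) >= min_n) {
      tryCatch(fit_weibull(d, ci_reps = ci_reps, seed = seed),
               error = function(e) NULL)
    }
    tibble::tibble(
      term = tm, n = s$n, median = s$median, q1 = s$q1, q3 = s$q3,
      shape = if (is.null(fit)) NA_real_ else fit$shape,
      shape_ci_low = if (is.null(fit)) NA_real_ else fit$shape_ci_low,
      shape_ci_high = if (is.null(fit)) NA_real_ else fit$shape_ci_high,
      scale = if (is.null(fit)) NA_real_ else fit$scale,
      failure_type = if (is.null(fit)) NA_character_ else fit$failure_type
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$n), .data$term)
}
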