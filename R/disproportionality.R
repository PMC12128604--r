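# Disproportionality analysis: 2x2 contingency tables per drug-event term and
# the reporting odds ratio (ROR) with its Wald 95% confidence interval.
#
# For a target drug and an event term, over deduplicated cases:
#   a = cohort cases reporting the term      b = cohort cases not reporting it
#   c = background cases reporting the term  d = background cases not reporting it
# ROR = (a*d)/(b*c);  95% CI = exp(log ROR +/- z*sqrt(1/a + 1/b + 1/c + 1/d)).

Z_95 <- 1.959964

#' Build per-term 2x2 contingency tables
#'
#' The counting unit is the deduplicated case: a case contributes at most 1
#' to a term's event cell no matter how many of its PTs equal the term (PT
#' level) or map into the SOC (SOC level). At SOC level PTs are resolved to
#' their primary SOC through `map`; unmapped PTs are excluded from SOC-level
#' counting (they remain visible at PT level).
#'
#' @param cohort,background Disjoint, deduplicated `faers_reports` objects.
#' @param level `"PT"` or `"SOC"`.
#' @param map A `pt_soc_map`; required when `level = "SOC"`.
#' @return Tibble with columns `term`, `a`, `b`, `c`, `d`, one row per term
#'   observed in either arm.
#' @export
build_contingency_tables <- function(cohort, background,
                                     level = c("PT", "SOC"), map = NULL) {
  level <- match.arg(toupper(level), c("PT", "SOC"))
  stopifnot(inherits(cohort, "faers_reports"),
            inherits(background, "faers_reports"))
  if (level == "SOC" && is.null(map)) {
    stop("SOC-level tables need a pt_soc_map", call. = FALSE)
  }

  term_cases <- function(reports) {
    rx <- reports$reactions
    term <- if (level == "PT") rx$pt else soc_of(rx$pt, map)
    keep <- term != UNMAPPED
    dplyr::distinct(tibble::tibble(primaryid = rx$primaryid[keep],
                                   term = term[keep]))
  }
  n_coh <- nrow(cohort$cases)
  n_bg <- nrow(background$cases)

  ca <- dplyr::count(term_cases(cohort), .data$term, name = "a")
  cc <- dplyr::count(term_cases(background), .data$term, name = "c")
  tab <- dplyr::full_join(ca, cc, by = "term")
  tab$a[is.na(tab$a)] <- 0L
  tab$c[is.na(tab$c)] <- 0L
  tab$b <- n_coh - tab$a
  tab$d <- n_bg - tab$c
  dplyr::arrange(tab[, c("term", "a", "b", "c", "d")], .data$term)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' Computes `ROR = (a*d)/(b*c)` and the two-sided CI
#' `exp(log ROR +/- z*sqrt(1/a + 1/b + 1/c + 1/d))`. Zero-cell handling:
#' a table with `a = 0` gets no estimate (`NA`); when `a >= 3` and one of
#' `b`, `c`, `d` is zero the Haldane–Anscombe correction (0.5 added to all
#' four cells) is applied and the row is marked `corrected`; any other table
#' with a zero cell gets no estimate. The interval is symmetric about the
#' point estimate on the log scale.
#'
#' @param a,b,c,d Integer vectors of cell counts (recycled).
#' @param z Normal quantile; the default 1.959964 gives the two-sided 95%
#'   interval.
#' @return Tibble with columns `ror`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' ror_ci(10, 20, 30, 240)  # ROR 4, CI ~ (1.71, 9.35)
#' @export
ror_ci <- function(a, b, c, d, z = Z_95) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  corrected <- a >= 3 & a > 0 & (b == 0 | c == 0 | d == 0)
  a2 <- ifelse(corrected, a + 0.5, a)
  b2 <- ifelse(corrected, b + 0.5, b)
  c2 <- ifelse(corrected, c + 0.5, c)
  d2 <- ifelse(corrected, d + 0.5, d)
  estimable <- a2 > 0 & b2 > 0 & c2 > 0 & d2 > 0
  log_ror <- ifelse(estimable, log(a2) + log(d2) - log(b2) - log(c2), NA_real_)
  se <- ifelse(estimable, sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2), NA_real_)
  tibble::tibble(
    ror = exp(log_ror),
    ci_low = exp(log_ror - z * se),
    ci_high = exp(log_ror + z * se),
    corrected = corrected & estimable
  )
}

#' Signal positivity rule
#'
#' A term is a positive signal when the lower 95% CI bound exceeds 1.0
#' (strictly) and the term was reported in at least three cohort cases.
#'
#' @param n Event count in the cohort (the `a` cell).
#' @param ci_low Lower CI bound (`NA` when not estimable).
#' @return Logical vector.
#' @export
flag_signal <- function(n, ci_low) {
  !is.na(ci_low) & n >= 3 & ci_low > 1.0
}

#' Full signal table for one cohort/background split
#'
#' Convenience wrapper: builds the contingency tables, computes ROR/CI, and
#' applies the positivity rule.
#'
#' @inheritParams build_contingency_tables
#' @param stratum Label recorded in the `stratum` column (default
#'   `"overall"`).
#' @return Tibble `level`, `stratum`, `term`, `n`, `ror`, `ci_low`,
#'   `ci_high`, `is_signal`, `corrected`, sorted by term.
#' @export
signal_table <- function(cohort, background, level = c("PT", "SOC"),
                         map = NULL, stratum = "overall") {
  level <- match.arg(toupper(level), c("PT", "SOC"))
  tab <- build_contingency_tables(cohort, background, level, map)
  est <- ror_ci(tab$a, tab$b, tab$c, tab$d)
  tibble::tibble(
    level = level,
    stratum = stratum,
    term = tab$term,
    n = tab$a,
    ror = est$ror,
    ci_low = est$ci_low,
    ci_high = est$ci_high,
    is_signal = flag_signal(tab$a, est$ci_low),
    corrected = est$corrected
  )
}

#' Rank a signal table
#'
#' Stable descending sort by report frequency (`n`) or signal strength
#' (`ror`); ties are broken by the other key, then by term text.
#'
#' @param results A signal tibble (from [signal_table()]).
#' @param by `"frequency"` or `"ror"`.
#' @param k Number of rows to keep (all if larger than the table).
#' @return The top-`k` rows in rank order.
#' @export
rank_signals <- function(results, by = c("frequency", "ror"), k = Inf) {
  by <- match.arg(by)
  ror_key <- ifelse(is.na(results$ror), -Inf, results$ror)
  ord <- if (by == "frequency") {
    order(-results$n, -ror_key, results$term)
  } else {
    order(-ror_key, -results$n, results$term)
  }
  utils::head(results[ord, , drop = FALSE], k)
}
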