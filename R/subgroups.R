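# Subgroup (stratified) disproportionality: recompute ROR signals within sex
# and age strata, each stratum using its own stratum-restricted background.

#' Define a stratum
#'
#' @param name Stratum label (appears in the `stratum` column of results).
#' @param predicate Function taking the `cases` tibble of a `faers_reports`
#'   object and returning a logical vector; cases failing it (including
#'   those with the relevant field missing) are excluded from the stratum
#'   entirely, on both the cohort and background side.
#' @return A `stratum_spec`.
#' @export
stratum_spec <- function(name, predicate) {
  stopifnot(is.character(name), length(name) == 1L, is.function(predicate))
  structure(list(name = name, predicate = predicate), class = "stratum_spec")
}

#' Built-in sex strata (female, male)
#'
#' Cases with unknown sex belong to neither stratum; the two strata are
#' mutually exclusive.
#' @return List of two `stratum_spec`s named `F` and `M`.
#' @export
sex_strata <- function() {
  list(
    F = stratum_spec("F", function(cases) cases$sex == "F"),
    M = stratum_spec("M", function(cases) cases$sex == "M")
  )
}

#' Built-in age strata (adults 18-64, elderly 65 and above)
#'
#' Cases under 18 or with missing age belong to neither stratum.
#' @return List of two `stratum_spec`s named `18-64` and `>=65`.
#' @export
age_strata <- function() {
  list(
    "18-64" = stratum_spec("18-64", function(cases)
      !is.na(cases$age_years) & cases$age_years >= 18 & cases$age_years <= 64),
    ">=65" = stratum_spec(">=65", function(cases)
      !is.na(cases$age_years) & cases$age_years >= 65)
  )
}

#' Disproportionality signals within one stratum
#'
#' Both the cohort and the background are filtered by the stratum predicate
#' before the 2x2 tables are built, so each stratum is compared against its
#' own background rather than the global one. An empty stratum cohort yields
#' an empty (zero-row) signal table.
#'
#' @param cohort,background `faers_reports` objects (disjoint, deduplicated).
#' @param spec A `stratum_spec`.
#' @param level `"PT"` or `"SOC"`.
#' @param map A `pt_soc_map` (required for SOC level).
#' @return Signal tibble as from [signal_table()], `stratum` set to the
#'   stratum name.
#' @export
stratified_signals <- function(cohort, background, spec,
                               level = c("PT", "SOC"), map = NULL) {
  stopifnot(inherits(spec, "stratum_spec"))
  level <- match.arg(toupper(level), c("PT", "SOC"))
  sub <- function(reports) {
    keep <- spec$predicate(reports$cases)
    keep[is.na(keep)] <- FALSE
    filter_reports(reports, reports$cases$caseid[keep])
  }
  coh <- sub(cohort)
  bg <- sub(background)
  if (nrow(coh$cases) == 0L) {
    return(signal_table(coh, bg, level, map, stratum = spec$name)[0, ])
  }
  signal_table(coh, bg, level, map, stratum = spec$name)
}

#' Compare the positive signal sets of two strata
#'
#' Set algebra on the flagged terms plus a side-by-side ROR/CI contrast. No
#' formal interaction test is computed: differences between strata are
#' reported descriptively by ROR magnitude.
#'
#' @param results_x,results_y Signal tibbles (any rows with
#'   `is_signal = FALSE` are dropped first).
#' @return List with `shared`, `only_x`, `only_y` (character vectors of
#'   terms) and `contrast`, a tibble with one row per term in either set and
#'   both strata's `n`, `ror`, `ci_low`, `ci_high` side by side plus a
#'   `classification` column (`shared` / `only_x` / `only_y`).
#' @export
compare_strata <- function(results_x, results_y) {
  x <- dplyr::filter(results_x, .data$is_signal)
  y <- dplyr::filter(results_y, .data$is_signal)
  shared <- intersect(x$term, y$term)
  only_x <- setdiff(x$term, y$term)
  only_y <- setdiff(y$term, x$term)

  cols <- c("term", "n", "ror", "ci_low", "ci_high")
  contrast <- dplyr::full_join(
    x[, cols], y[, cols], by = "term", suffix = c("_x", "_y")
  )
  contrast$classification <- ifelse(
    contrast$term %in% shared, "shared",
    ifelse(contrast$term %in% only_x, "only_x", "only_y")
  )
  list(shared = sort(shared), only_x = sort(only_x), only_y = sort(only_y),
       contrast = dplyr::arrange(contrast, .data$classification, .data$term))
}
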