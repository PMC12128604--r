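# End-to-end orchestration: ingest -> dedup -> cohort -> map -> signals ->
# subgroups -> onset, from a single declarative config, with a machine-
# readable run manifest and deterministic outputs under one seed.

#' Configuration for a full pipeline run
#'
#' @param input Either a directory of quarterly ASCII files (read with
#'   [read_faers_quarters()]) or an in-memory named list of the five raw
#'   tables (as from [generate_faers()]`$tables`).
#' @param target_names Non-empty character vector of target drug name
#'   tokens (generic and trade names).
#' @param map A `pt_soc_map`, or a path to a dictionary file for
#'   [load_pt_soc_map()]. `NULL` skips SOC-level analysis.
#' @param role Drug role defining the cohort (default `"PS"`,
#'   primary suspect).
#' @param strata Run the sex and age subgroup analyses (default `TRUE`).
#' @param onset Run the time-to-onset analysis (default `TRUE`).
#' @param onset_ci_reps Bootstrap resamples for Weibull shape CIs.
#' @param min_onset_n Minimum onsets per term for a Weibull fit.
#' @param seed Top-level seed; all randomness (the bootstrap) flows from it.
#' @param out_dir Optional output directory for the delimited result tables
#'   and the JSON manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(input, target_names, map = NULL, role = "PS",
                       strata = TRUE, onset = TRUE, onset_ci_reps = 1000L,
                       min_onset_n = 10L, seed = 1L, out_dir = NULL) {
  stopifnot(length(target_names) >= 1L, all(nzchar(target_names)))
  if (is.character(map)) map <- load_pt_soc_map(map)
  structure(list(input = input, target_names = toupper(target_names),
                 map = map, role = role, strata = strata, onset = onset,
                 onset_ci_reps = as.integer(onset_ci_reps),
                 min_onset_n = as.integer(min_onset_n),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full signal-detection pipeline
#'
#' Executes every stage on the configured input: reads and concatenates the
#' quarterly tables, deduplicates report versions, splits off the
#' primary-suspect cohort for the target drug, summarizes its clinical
#' characteristics, computes overall PT- and SOC-level ROR signal tables,
#' repeats the PT-level analysis within sex and age strata (each against
#' its stratum-restricted background) with cross-stratum comparisons, and
#' runs the time-to-onset analysis (overall bins and median/IQR, per-SOC
#' summaries with Weibull failure types, Kruskal-Wallis test across SOCs).
#' Identical config + input + seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result` list: `cohort_summary`, `signals` (named
#'   list of signal tibbles), `strata_comparisons`, `onset` (list of
#'   tibbles), `manifest` (stage counts), `reports` (the cohort/background
#'   split). Result tables are also written under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)

  tables <- if (is.character(config$input)) {
    read_faers_quarters(config$input)
  } else {
    config$input
  }
  read_summary <- attr(tables, "read_summary")

  reports <- build_reports(tables)
  split <- build_cohort(reports, config$target_names, config$role)
  cohort <- split$cohort
  background <- split$background
  if (nrow(cohort$cases) == 0L) {
    stop("empty cohort: no deduplicated report names any of [",
         paste(config$target_names, collapse = ", "),
         "] with role ", config$role, call. = FALSE)
  }

  summary <- summarize_cohort(cohort)

  signals <- list(pt_overall = signal_table(cohort, background, "PT"))
  if (!is.null(config$map)) {
    signals$soc_overall <- signal_table(cohort, background, "SOC", config$map)
  }

  comparisons <- list()
  if (isTRUE(config$strata)) {
    for (axis in list(sex_strata(), age_strata())) {
      res <- lapply(axis, function(sp)
        stratified_signals(cohort, background, sp, "PT"))
      names(res) <- paste0("pt_", names(axis))
      signals <- c(signals, res)
      comparisons[[paste(names(axis), collapse = "_vs_")]] <-
        compare_strata(res[[1L]], res[[2L]])
    }
  }

  onset_out <- NULL
  if (isTRUE(config$onset)) {
    tto <- onset_days(cohort, config$target_names)
    days <- tto$days[!is.na(tto$days)]
    onset_out <- list(per_case = tto,
                      bins = bin_onsets(days),
                      overall = if (length(days)) summarize_onset(days))
    if (!is.null(config$map) && length(days) >= config$min_onset_n) {
      pos_soc <- signals$soc_overall$term[signals$soc_overall$is_signal]
      onset_out$by_soc <- onset_by_term(
        cohort, config$target_names, "SOC", config$map,
        terms = if (length(pos_soc)) pos_soc else NULL,
        min_n = config$min_onset_n, ci_reps = config$onset_ci_reps,
        seed = config$seed
      )
      grp <- onset_soc_samples(cohort, config$target_names, config$map,
                               terms = onset_out$by_soc$term)
      if (length(grp) >= 2L) {
        onset_out$soc_test <- compare_onset_groups(grp)
      }
    }
  }

  manifest <- list(
    seed = config$seed,
    target_names = config$target_names,
    role = config$role,
    rows_read = if (!is.null(read_summary)) read_summary,
    n_raw_versions = reports$log$n_raw_versions,
    n_duplicates_removed = reports$log$n_duplicates_removed,
    n_dropped_no_reaction = reports$log$n_dropped_no_reaction,
    n_deduplicated = nrow(cohort$cases) + nrow(background$cases),
    n_cohort = nrow(cohort$cases),
    n_background = nrow(background$cases),
    terms_tested = vapply(signals, nrow, integer(1)),
    signals_flagged = vapply(signals, function(s) sum(s$is_signal), integer(1)),
    n_onset_observed = if (!is.null(onset_out))
      sum(!is.na(onset_out$per_case$days))
  )

  result <- structure(
    list(cohort_summary = summary, signals = signals,
         strata_comparisons = comparisons, onset = onset_out,
         manifest = manifest,
         reports = list(cohort = cohort, background = background)),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

# Onset samples per SOC (helper for the cross-SOC Kruskal-Wallis test).
onset_soc_samples <- function(cohort, target_names, map, terms = NULL) {
  tto <- onset_days(cohort, target_names)
  tto <- tto[!is.na(tto$days), c("caseid", "days")]
  rx <- cohort$reactions
  rx$caseid <- cohort$cases$caseid[match(rx$primaryid, cohort$cases$primaryid)]
  rx$term <- soc_of(rx$pt, map)
  rx <- dplyr::distinct(rx[rx$term != UNMAPPED, c("caseid", "term")])
  joined <- dplyr::inner_join(rx, tto, by = "caseid")
  if (!is.null(terms)) joined <- joined[joined$term %in% terms, , drop = FALSE]
  grp <- split(joined$days, joined$term)
  grp[lengths(grp) >= 2L]
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("<pipeline_result>\n",
      "  cohort ", m$n_cohort, " cases vs background ", m$n_background,
      " (", m$n_duplicates_removed, " duplicate versions removed)\n", sep = "")
  for (nm in names(x$signals)) {
    cat(sprintf("  %-14s %4d terms, %3d positive signals\n",
                nm, m$terms_tested[[nm]], m$signals_flagged[[nm]]))
  }
  if (!is.null(x$onset$overall)) {
    cat(sprintf("  onset: n=%d median=%.1f days (IQR %.1f-%.1f)\n",
                x$onset$overall$n, x$onset$overall$median,
                x$onset$overall$q1, x$onset$overall$q3))
  }
  invisible(x)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a pipeline result bundle as delimited tables plus a JSON manifest
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_summary(result$cohort_summary,
                       file.path(dir, "cohort_summary.tsv"))
  for (nm in names(result$signals)) {
    out <- result$signals[[nm]]
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "n"
    out[num] <- lapply(out[num], function(v) sprintf("%.2f", v))
    write_tsv(out, file.path(dir, paste0("signals_", gsub("[^A-Za-z0-9_-]", "", nm), ".tsv")))
  }
  for (nm in names(result$strata_comparisons)) {
    write_tsv(result$strata_comparisons[[nm]]$contrast,
              file.path(dir, paste0("strata_", gsub("[^A-Za-z0-9_-]", "", nm), ".tsv")))
  }
  if (!is.null(result$onset)) {
    write_tsv(result$onset$bins, file.path(dir, "onset_bins.tsv"))
    if (!is.null(result$onset$overall)) {
      write_tsv(result$onset$overall, file.path(dir, "onset_overall.tsv"))
    }
    if (!is.null(result$onset$by_soc)) {
      write_tsv(result$onset$by_soc, file.path(dir, "onset_by_soc.tsv"))
    }
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
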