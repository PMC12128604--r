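#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib faersignal, .registration = TRUE
NULL

# Canonical column sets for the five FAERS ASCII quarterly tables used here.
# Matching against file headers is case-insensitive; extra columns are ignored.
faers_table_columns <- list(
  DEMO = c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT", "SEX", "AGE",
           "AGE_COD", "OCCP_COD", "REPORTER_COUNTRY"),
  DRUG = c("PRIMARYID", "DRUG_SEQ", "ROLE_COD", "DRUGNAME", "PROD_AI"),
  REAC = c("PRIMARYID", "PT"),
  THER = c("PRIMARYID", "DSG_DRUG_SEQ", "START_DT", "END_DT"),
  OUTC = c("PRIMARYID", "OUTC_COD")
)

faers_role_codes <- c("PS", "SS", "C", "I")
faers_outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Read one FAERS quarterly ASCII table
#'
#' Reads a dollar-delimited FAERS quarterly extract table (the `DEMO$...`
#' dialect, header row naming the columns, no quoting) into a tibble of
#' character columns named by the lower-cased canonical FAERS names. Column
#' positions are taken from the header, not assumed; header matching is
#' case-insensitive and extra columns are ignored. Data lines whose field
#' count does not match the header are skipped and counted, never silently
#' mangled.
#'
#' @param path Path to the ASCII file.
#' @param table_kind One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`, `"OUTC"`.
#' @param quarter Optional quarter label (e.g. `"2021Q1"`) attached as a
#'   `quarter` column; defaults to a `"2021Q1"`-style token found in the file
#'   name, else `NA`.
#'
#' @return A tibble of character columns. The attribute `"read_summary"`
#'   holds `list(path, table_kind, rows_read, rows_skipped)`.
#' @seealso [write_faers_table()]
#' @export
read_faers_table <- function(path, table_kind, quarter = NULL) {
  table_kind <- match.arg(toupper(table_kind), names(faers_table_columns))
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(quarter)) {
    m <- regmatches(basename(path), regexpr("20[0-9]{2}[Qq][1-4]", basename(path)))
    quarter <- if (length(m)) toupper(m) else NA_character_
  }

  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop("empty file (no header): ", path, call. = FALSE)
  }
  header <- strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]
  wanted <- faers_table_columns[[table_kind]]
  idx <- match(wanted, toupper(trimws(header)))
  if (anyNA(idx)) {
    stop(sprintf("%s file %s is missing mandatory column(s): %s",
                 table_kind, path, paste(wanted[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }

  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "$", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; pad rather than reject
  nf <- lengths(fields)
  pad <- nf == length(header) - 1L
  if (any(pad)) {
    fields[pad] <- lapply(fields[pad], function(x) c(x, ""))
    nf[pad] <- length(header)
  }
  bad <- nf != length(header)
  skipped <- sum(bad)
  fields <- fields[!bad]

  if (length(fields)) {
    mat <- matrix(unlist(fields, use.names = FALSE),
                  nrow = length(fields), byrow = TRUE)
    cols <- lapply(idx, function(j) trimws(mat[, j]))
  } else {
    cols <- rep(list(character(0)), length(wanted))
  }
  names(cols) <- tolower(wanted)
  out <- tibble::as_tibble(cols)
  out$quarter <- rep(quarter, nrow(out))

  attr(out, "read_summary") <- list(path = path, table_kind = table_kind,
                                    rows_read = nrow(out),
                                    rows_skipped = skipped)
  out
}

#' Write a FAERS-style ASCII table
#'
#' Writes the dollar-delimited dialect [read_faers_table()] reads, with the
#' canonical upper-case header. Used by the synthetic generator; writing then
#' re-reading is field-identical (the round-trip property the tests check).
#'
#' @param x Tibble with (at least) the lower-cased canonical columns for
#'   `table_kind`.
#' @param path Output path.
#' @param table_kind One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`, `"OUTC"`.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(x, path, table_kind) {
  table_kind <- match.arg(toupper(table_kind), names(faers_table_columns))
  wanted <- faers_table_columns[[table_kind]]
  cols <- tolower(wanted)
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    stop("missing column(s) for ", table_kind, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vals <- lapply(cols, function(cn) {
    v <- as.character(x[[cn]])
    v[is.na(v)] <- ""
    if (any(grepl("$", v, fixed = TRUE))) {
      stop("field values must not contain the '$' delimiter", call. = FALSE)
    }
    v
  })
  lines <- c(paste(wanted, collapse = "$"),
             do.call(paste, c(vals, sep = "$")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a full set of quarterly tables from a directory
#'
#' Scans `dir` for files named `demo*.txt`, `drug*.txt`, `reac*.txt`,
#' `ther*.txt`, `outc*.txt` (case-insensitive), reads each with
#' [read_faers_table()], and row-binds the quarters per table kind — the
#' deduplication rule operates across quarters, so quarters are always
#' concatenated before any analysis.
#'
#' @param dir Directory containing the quarterly ASCII files.
#' @return Named list of tibbles (`demo`, `drug`, `reac`, `ther`, `outc`)
#'   with a `read_summary` attribute aggregating per-file counts.
#' @export
read_faers_quarters <- function(dir) {
  kinds <- names(faers_table_columns)
  summaries <- list()
  out <- lapply(kinds, function(kind) {
    paths <- sort(list.files(dir, pattern = paste0("^", tolower(kind), ".*\\.txt$"),
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(paths)) {
      stop("no ", kind, " files found under ", dir, call. = FALSE)
    }
    tabs <- lapply(paths, read_faers_table, table_kind = kind)
    summaries[[kind]] <<- lapply(tabs, attr, "read_summary")
    dplyr::bind_rows(tabs)
  })
  names(out) <- tolower(kinds)
  attr(out, "read_summary") <- summaries
  out
}

#' Convert a FAERS age to years
#'
#' FAERS records age as a value plus a unit code. Conversion uses a 365.25-day
#' year: `DEC` (decades) x10, `YR` identity, `MON` /12, `WK` /52.1775, `DY`
#' /365.25, `HR` /8766. A present value with a missing unit is taken as years
#' (the dominant FAERS convention). Results that are negative or above 120
#' years are treated as recording errors and set to `NA`.
#'
#' @param age_value Numeric vector (or character, coerced).
#' @param age_unit_code Character vector of FAERS unit codes.
#' @return Numeric vector of ages in years, `NA` where missing or implausible.
#' @examples
#' normalize_age(c(45, 6, 4.5), c("YR", "MON", "DEC"))
#' @export
normalize_age <- function(age_value, age_unit_code) {
  v <- suppressWarnings(as.numeric(age_value))
  u <- toupper(trimws(as.character(age_unit_code)))
  u[is.na(u)] <- ""
  divisor <- c(DEC = 0.1, YR = 1, MON = 12, WK = 52.1775, DY = 365.25, HR = 8766)
  fac <- divisor[u]
  fac[u == ""] <- 1          # missing unit, value present: assume years
  years <- v / unname(fac)   # unknown unit codes give NA via the lookup
  years[!is.na(years) & (years < 0 | years > 120)] <- NA_real_
  years
}
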