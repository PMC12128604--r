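#' Parse FAERS partial date tokens
#'
#' FAERS quarterly extracts encode dates as 4-, 6- or 8-digit numeric strings
#' (`YYYY`, `YYYYMM`, `YYYYMMDD`), and many are genuinely partial: the report
#' carries only the year, or year and month, of an event. `parse_partial_date()`
#' keeps that information instead of forcing every token into a `Date`.
#'
#' @param tokens Character vector of date tokens. Empty strings, `NA`, and
#'   anything that is not a 4/6/8-digit string (or encodes an impossible
#'   calendar date, such as `"20210230"`) parse to a missing row.
#'
#' @return A tibble with one row per token and columns `year`, `month`, `day`
#'   (integer, `NA` where absent) and `precision` (`"year"`, `"month"`,
#'   `"day"`, or `NA` for unparseable/missing tokens).
#'
#' @examples
#' parse_partial_date(c("20210115", "202103", "2021", "", "20210230"))
#' @export
parse_partial_date <- function(tokens) {
  tokens <- as.character(tokens)
  tokens[is.na(tokens)] <- ""
  tokens <- trimws(tokens)

  n <- length(tokens)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep(NA_character_, n)

  digits <- grepl("^[0-9]+$", tokens)
  len <- nchar(tokens)

  i4 <- digits & len == 4L
  year[i4] <- as.integer(tokens[i4])
  precision[i4] <- "year"

  i6 <- digits & len == 6L
  y6 <- as.integer(substr(tokens[i6], 1L, 4L))
  m6 <- as.integer(substr(tokens[i6], 5L, 6L))
  ok6 <- m6 >= 1L & m6 <= 12L
  year[i6][ok6] <- y6[ok6]
  month[i6][ok6] <- m6[ok6]
  precision[i6][ok6] <- "month"

  i8 <- digits & len == 8L
  if (any(i8)) {
    d <- as.Date(tokens[i8], format = "%Y%m%d")
    # as.Date() returns NA for impossible calendar dates (e.g. Feb 30)
    ok8 <- !is.na(d) & format(d, "%Y%m%d") == tokens[i8]
    year[i8][ok8] <- as.integer(substr(tokens[i8][ok8], 1L, 4L))
    month[i8][ok8] <- as.integer(substr(tokens[i8][ok8], 5L, 6L))
    day[i8][ok8] <- as.integer(substr(tokens[i8][ok8], 7L, 8L))
    precision[i8][ok8] <- "day"
  }

  tibble::tibble(year = year, month = month, day = day, precision = precision)
}

#' Format a partial date back to its FAERS numeric token
#'
#' Inverse of [parse_partial_date()] on valid input: a day-precision date
#' round-trips through its 8-digit form, month precision through 6 digits,
#' year precision through 4.
#'
#' @param year,month,day Integer vectors (`month`/`day` may be `NA`).
#' @return Character vector of tokens; `""` where `year` is `NA`.
#' @export
format_partial_date <- function(year, month = NA_integer_, day = NA_integer_) {
  n <- max(length(year), length(month), length(day))
  year <- rep_len(as.integer(year), n)
  month <- rep_len(as.integer(month), n)
  day <- rep_len(as.integer(day), n)

  out <- rep("", n)
  has_y <- !is.na(year)
  out[has_y] <- sprintf("%04d", year[has_y])
  has_m <- has_y & !is.na(month)
  out[has_m] <- paste0(out[has_m], sprintf("%02d", month[has_m]))
  has_d <- has_m & !is.na(day)
  out[has_d] <- paste0(out[has_d], sprintf("%02d", day[has_d]))
  out
}

# Sortable numeric key for dedup comparisons: unparseable dates lose against
# any parseable date; among parseable ones, missing month/day sort earliest.
partial_date_key <- function(tokens) {
  p <- parse_partial_date(tokens)
  key <- p$year * 10000 +
    ifelse(is.na(p$month), 0L, p$month) * 100 +
    ifelse(is.na(p$day), 0L, p$day)
  key[is.na(p$precision)] <- -Inf
  key
}

# Day-precision tokens -> Date; anything else -> NA.
partial_date_to_date <- function(tokens) {
  p <- parse_partial_date(tokens)
  out <- rep(as.Date(NA), length(tokens))
  i <- !is.na(p$precision) & p$precision == "day"
  if (any(i)) {
    out[i] <- as.Date(sprintf("%04d-%02d-%02d", p$year[i], p$month[i], p$day[i]))
  }
  out
}
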