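# PT -> SOC mapping through a user-supplied dictionary. MedDRA itself is
# licensed and is never bundled: the user provides a delimited table with the
# (multi-axial) PT-to-SOC links and a primary-SOC flag.

#' Sentinel SOC for PTs absent from the dictionary
#' @export
UNMAPPED <- "UNMAPPED"

normalize_pt <- function(pt) {
  toupper(gsub("\\s+", " ", trimws(as.character(pt))))
}

#' Load a PT-to-SOC dictionary
#'
#' Reads a delimited file with columns `pt`, `soc`, `primary_flag`
#' (`Y`/`N`), one row per PT–SOC link. MedDRA is multi-axial: a PT may link
#' to several SOCs but has exactly one primary SOC, and that invariant is
#' enforced here — a PT with zero or several primary links is a format
#' error naming the offenders. PT keys are unique after case/whitespace
#' normalization; duplicate (pt, soc) rows collapse to one.
#'
#' @param path Path to the dictionary file.
#' @param sep Field separator (default tab).
#' @return A `pt_soc_map`: list with `entries` (tibble `pt`, `soc`,
#'   `is_primary`) and an internal primary-SOC lookup.
#' @export
load_pt_soc_map <- function(path, sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character", strip.white = TRUE)
  names(raw) <- tolower(names(raw))
  need <- c("pt", "soc", "primary_flag")
  if (!all(need %in% names(raw))) {
    stop("dictionary must have columns pt, soc, primary_flag; found: ",
         paste(names(raw), collapse = ", "), call. = FALSE)
  }
  entries <- tibble::tibble(
    pt = gsub("\\s+", " ", trimws(raw$pt)),
    pt_key = normalize_pt(raw$pt),
    soc = gsub("\\s+", " ", trimws(raw$soc)),
    is_primary = toupper(trimws(raw$primary_flag)) %in% c("Y", "YES", "1", "TRUE")
  )
  entries <- dplyr::distinct(entries, .data$pt_key, .data$soc,
                             .keep_all = TRUE)
  n_primary <- tapply(entries$is_primary, entries$pt_key, sum)
  bad <- names(n_primary)[n_primary != 1L]
  if (length(bad)) {
    stop("each PT needs exactly one primary SOC; offenders: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  prim <- entries[entries$is_primary, , drop = FALSE]
  lookup <- stats::setNames(prim$soc, prim$pt_key)
  structure(list(entries = entries, lookup = lookup), class = "pt_soc_map")
}

#' Build a PT-to-SOC map from an in-memory catalog
#'
#' Companion to [load_pt_soc_map()] for code-built dictionaries, e.g. the
#' synthetic generator's PT catalog. Each PT maps to a single (primary) SOC.
#'
#' @param pt,soc Character vectors of equal length.
#' @return A `pt_soc_map`.
#' @export
pt_soc_map <- function(pt, soc) {
  entries <- dplyr::distinct(tibble::tibble(
    pt = gsub("\\s+", " ", trimws(pt)),
    pt_key = normalize_pt(pt),
    soc = gsub("\\s+", " ", trimws(soc)),
    is_primary = TRUE
  ))
  if (anyDuplicated(entries$pt_key)) {
    stop("each PT needs exactly one primary SOC; offenders: ",
         paste(unique(entries$pt_key[duplicated(entries$pt_key)]),
               collapse = ", "), call. = FALSE)
  }
  structure(list(entries = entries,
                 lookup = stats::setNames(entries$soc, entries$pt_key)),
            class = "pt_soc_map")
}

#' @export
print.pt_soc_map <- function(x, ...) {
  cat("<pt_soc_map> ", length(x$lookup), " PTs across ",
      length(unique(x$lookup)), " SOCs\n", sep = "")
  invisible(x)
}

#' Primary SOC of a PT
#'
#' Total function: every PT resolves either to its primary SOC or to the
#' [UNMAPPED] sentinel; lookups are insensitive to case and surrounding or
#' repeated whitespace.
#'
#' @param pt Character vector of PT texts.
#' @param map A `pt_soc_map`.
#' @return Character vector of SOC names (or `UNMAPPED`).
#' @examples
#' m <- pt_soc_map("Hypertension", "Vascular disorders")
#' soc_of(c("  hypertension ", "Unknown term"), m)
#' @export
soc_of <- function(pt, map) {
  stopifnot(inherits(map, "pt_soc_map"))
  out <- unname(map$lookup[normalize_pt(pt)])
  out[is.na(out)] <- UNMAPPED
  out
}

#' Write a PT-to-SOC map in the dictionary file format
#' @param map A `pt_soc_map`.
#' @param path Output path (tab-separated `pt`, `soc`, `primary_flag`).
#' @return `path`, invisibly.
#' @export
write_pt_soc_map <- function(map, path) {
  out <- data.frame(pt = map$entries$pt, soc = map$entries$soc,
                    primary_flag = ifelse(map$entries$is_primary, "Y", "N"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
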