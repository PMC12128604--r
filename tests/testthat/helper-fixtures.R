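# Shared helpers: small raw tables built in code, plus an independent
# closed-form ROR/CI oracle kept deliberately separate from ror_ci()'s
# arithmetic (odds computed per arm, variance term by term).

oracle_ror <- function(a, b, c, d, z = 1.959964) {
  odds_cohort <- a / b
  odds_background <- c / d
  est <- odds_cohort / odds_background
  var_log <- 1 / a + 1 / b + 1 / c + 1 / d
  half <- z * sqrt(var_log)
  list(ror = est,
       ci_low = est * exp(-half),
       ci_high = est * exp(half))
}

# minimal demo tibble builder
demo_rows <- function(primaryid, caseid, fda_dt, ...) {
  extra <- list(...)
  out <- tibble::tibble(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid),
    fda_dt = as.character(fda_dt),
    event_dt = "", sex = "F", age = "", age_cod = "",
    occp_cod = "CN", reporter_country = "US", quarter = "2021Q1"
  )
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# reports object with prescribed per-case sex/age/pts, all target-drug PS
reports_from_cases <- function(sex = NULL, age_years = NULL, pts,
                               drugname = "VOCLOSPORIN", role = "PS") {
  n <- length(pts)
  if (is.null(sex)) sex <- rep("F", n)
  if (is.null(age_years)) age_years <- rep(NA_real_, n)
  ids <- sprintf("T%04d", seq_len(n))
  cases <- tibble::tibble(
    primaryid = ids, caseid = ids, fda_dt = "20230101", event_dt = "",
    sex = sex, age_years = age_years,
    age_band = faersignal:::age_band_of(age_years),
    reporter = "consumer", country = "US", quarter = "2023Q1"
  )
  reactions <- tibble::tibble(
    primaryid = rep(ids, lengths(pts)),
    pt = unlist(pts, use.names = FALSE)
  )
  drugs <- tibble::tibble(primaryid = ids, drug_seq = "1", role_cod = role,
                          drugname = drugname, prod_ai = drugname)
  new_faers_reports(cases, drugs = drugs, reactions = reactions)
}
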