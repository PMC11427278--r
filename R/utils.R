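## Internal helpers: date handling, name normalization, quarter labels.

#' Parse FAERS-style compact dates
#'
#' FAERS date fields are numeric strings of 8 (`YYYYMMDD`), 6 (`YYYYMM`) or
#' 4 (`YYYY`) digits. Partial dates are imputed to the first day of the
#' missing month/day and flagged imprecise; anything else parses to `NA`.
#'
#' @param x integer or character vector of compact dates.
#' @return A `data.table` with columns `date` (class `Date`) and
#'   `imprecise` (logical; `NA` where `date` is `NA`).
#' @examples
#' parse_faers_date(c(20180105, 201801, 2018, NA))
#' @export
parse_faers_date <- function(x) {
  s <- sub("\\.0+$", "", as.character(x))
  s[!grepl("^[0-9]+$", s) | is.na(s)] <- NA_character_
  nc <- nchar(s)
  full <- ifelse(nc == 8L, s,
          ifelse(nc == 6L, paste0(s, "01"),
          ifelse(nc == 4L, paste0(s, "0101"), NA_character_)))
  date <- as.Date(full, format = "%Y%m%d")  # invalid calendar dates -> NA
  imprecise <- ifelse(is.na(date), NA, nc < 8L)
  data.table(date = date, imprecise = imprecise)
}

#' Normalize a drug name for dictionary matching
#'
#' Lower-cases, strips punctuation and squashes internal whitespace so that
#' `"NERLYNX "`, `"Nerlynx."` and `"nerlynx"` compare equal.
#'
#' @param x character vector of drug names as reported.
#' @return normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Sequence of year-quarter labels
#'
#' @param from,to labels of the form `"2017Q3"`.
#' @return character vector of consecutive quarter labels, inclusive.
#' @examples
#' quarter_seq("2017Q3", "2018Q2")
#' @export
quarter_seq <- function(from, to) {
  parse_q <- function(q) {
    m <- regmatches(q, regexec("^([0-9]{4})Q([1-4])$", q))[[1]]
    if (length(m) != 3L) stop("bad quarter label: ", q)
    as.integer(m[2]) * 4L + as.integer(m[3]) - 1L
  }
  i <- parse_q(from):parse_q(to)
  sprintf("%dQ%d", i %/% 4L, i %% 4L + 1L)
}

## first and last calendar day of a quarter label
quarter_days <- function(q) {
  y <- as.integer(substr(q, 1, 4)); qq <- as.integer(substr(q, 6, 6))
  start <- as.Date(sprintf("%d-%02d-01", y, (qq - 1L) * 3L + 1L))
  end <- seq(start, by = "3 months", length.out = 2)[2] - 1L
  list(start = start, end = end)
}

as_yyyymmdd <- function(d) as.integer(format(d, "%Y%m%d"))

## year from an integer yyyymmdd-ish field (8/6/4 digits), NA otherwise
year_of <- function(x) {
  s <- sub("\\.0+$", "", as.character(x))
  y <- suppressWarnings(as.integer(substr(s, 1, 4)))
  y[!grepl("^[0-9]{4,8}$", s)] <- NA_integer_
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## path to a shipped extdata file
fs_extdata <- function(file) {
  p <- system.file("extdata", file, package = "faersignal")
  if (!nzchar(p)) stop("extdata file not found: ", file)
  p
}
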