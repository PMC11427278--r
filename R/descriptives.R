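## Descriptive profile of the target drug's reports: yearly counts, sex,
## age bands, reporter occupation, country, serious outcomes and
## time-to-onset bins, each with its own explicit denominator.

.age_breaks <- c(18, 45, 65, 75, Inf)
.age_labels <- c("18-45", "45-65", "65-75", ">=75")
.tto_breaks <- c(0, 7, 28, 60, Inf)
.tto_labels <- c("<7", "7-28", "28-60", ">=60")
.occp_labels <- c(PH = "Pharmacist", OT = "Other health-professional",
                  CSM = "Consumer", MD = "Physician", LW = "Lawyer")
.outcome_labels <- c(HO = "Hospitalization", DE = "Death",
                     LT = "Life threatening", DS = "Disability",
                     RI = "Required intervention", OT = "Other serious")

block_table <- function(x, levels_order = NULL) {
  x[is.na(x) | !nzchar(as.character(x))] <- "Unknown"
  tab <- data.table(category = as.character(x))[, .(n = .N), by = category]
  denom <- sum(tab$n)
  tab[, pct := round(100 * n / denom, 2)]
  if (!is.null(levels_order)) {
    tab <- tab[order(match(category, c(levels_order, "Unknown")))]
  } else {
    setorder(tab, -n)
    tab <- rbind(tab[category != "Unknown"], tab[category == "Unknown"])
  }
  attr(tab, "denominator") <- denom
  tab[]
}

#' Per-report time to onset for the target drug
#'
#' Days from the earliest (precise) therapy start date of the target drug
#' to the (precise) event date. Negative differences and imprecise or
#' missing dates are unresolvable ("Unknown"). Bins are half-open:
#' `[0,7)`, `[7,28)`, `[28,60)`, `[60,Inf)` (so exactly 7 days falls in
#' "7-28").
#'
#' @param db a deduplicated [report_db()].
#' @param target_ids `primaryid`s of the target drug's reports.
#' @param target_seq optional `data.table(primaryid, drug_seq)` restricting
#'   therapy rows to the target drug's sequences; by default the target
#'   drug's `drug_seq`s are looked up with [neratinib_synonyms()] patterns
#'   absent, i.e. all therapy rows of the report are considered.
#' @return `data.table` with `primaryid`, `days`, `bin`.
#' @export
time_to_onset <- function(db, target_ids, target_seq = NULL) {
  validate_report_db(db)
  ther <- db$ther[primaryid %in% target_ids]
  if (!is.null(target_seq))
    ther <- ther[target_seq, on = c("primaryid", "drug_seq"), nomatch = NULL]
  sd <- parse_faers_date(ther$start_dt)
  ther <- ther[, .(primaryid, start = sd$date, imp = sd$imprecise)]
  ther <- ther[!is.na(start) & imp == FALSE]
  start <- if (nrow(ther)) ther[, .(start = min(start)), by = primaryid]
           else data.table(primaryid = integer(),
                           start = as.Date(integer(), origin = "1970-01-01"))
  ed <- parse_faers_date(db$demo$event_dt)
  demo <- db$demo[, .(primaryid, event = ed$date, eimp = ed$imprecise)]
  out <- demo[primaryid %in% target_ids]
  out <- merge(out, start, by = "primaryid", all.x = TRUE)
  out[, days := as.integer(event - start)]
  out[is.na(eimp) | eimp == TRUE | is.na(days) | days < 0, days := NA_integer_]
  out[, bin := .tto_labels[findInterval(days, .tto_breaks)]]
  out[is.na(days), bin := "Unknown"]
  out[, .(primaryid, days, bin)]
}

#' Descriptive summary of the target drug's reports
#'
#' Blocks and denominators:
#' * `year`, `sex`, `age`, `reporter`, `country`: one count per target
#'   report; denominator = number of target reports.
#' * `outcome`: denominator = reports with at least one serious outcome
#'   code; a report with several codes contributes only its most severe
#'   (severity order DE > LT > HO > DS > RI > OT).
#' * `tto`: all target reports; unresolvable dates count as "Unknown".
#'
#' @param db a deduplicated [report_db()].
#' @param target_ids `primaryid`s of the target drug's reports.
#' @param top_k_countries countries listed individually before collapsing
#'   the rest into "Other".
#' @return object of class `descriptive_summary`: named list of block
#'   `data.table`s (`category`, `n`, `pct`), each carrying a
#'   `denominator` attribute.
#' @export
summarize_reports <- function(db, target_ids, top_k_countries = 2L) {
  validate_report_db(db)
  demo <- db$demo[primaryid %in% target_ids]

  year <- year_of(demo$fda_dt)
  year <- fifelse(is.na(year), year_of(demo$event_dt), year)

  age_band <- rep(NA_character_, nrow(demo))
  known_age <- !is.na(demo$age) & demo$age >= 18
  age_band[known_age] <- .age_labels[findInterval(demo$age[known_age],
                                                  .age_breaks)]

  reporter <- .occp_labels[demo$occp_cod]

  country <- as.character(demo$reporter_country)
  country[is.na(country)] <- "Unknown"
  top <- names(sort(table(country[country != "Unknown"]),
                    decreasing = TRUE))
  top <- utils::head(top, top_k_countries)
  country[!country %in% c(top, "Unknown")] <- "Other"

  ## most severe outcome per report, among reports with any outcome code
  outc <- db$outc[primaryid %in% target_ids & outc_cod %in% .outcome_codes]
  worst <- outc[, .(code = outc_cod[which.min(.outcome_severity[outc_cod])]),
                by = primaryid]
  outcome_block <- block_table(.outcome_labels[worst$code],
                               unname(.outcome_labels))

  tto <- time_to_onset(db, target_ids)

  out <- list(
    year = block_table(year, sort(unique(stats::na.omit(year)))),
    sex = block_table(fifelse(demo$sex == "F", "Female",
                              fifelse(demo$sex == "M", "Male",
                                      NA_character_)),
                      c("Female", "Male")),
    age = block_table(age_band, .age_labels),
    reporter = block_table(reporter, unname(.occp_labels)),
    country = block_table(country, c(top, "Other")),
    outcome = outcome_block,
    tto = block_table(tto$bin, .tto_labels))
  attr(out, "n_reports") <- nrow(demo)
  class(out) <- "descriptive_summary"
  out
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat("<descriptive_summary> ", attr(x, "n_reports"), " reports\n", sep = "")
  for (blk in names(x)) {
    cat("--", blk, "(denominator", attr(x[[blk]], "denominator"), ")\n")
    print(x[[blk]], row.names = FALSE)
  }
  invisible(x)
}

#' Flatten a descriptive summary to one table
#'
#' @param x a `descriptive_summary`.
#' @return `data.table` with columns `block`, `category`, `n`, `pct`,
#'   `denominator`.
#' @export
descriptives_table <- function(x) {
  stopifnot(inherits(x, "descriptive_summary"))
  rbindlist(lapply(names(x), function(blk)
    cbind(block = blk, x[[blk]],
          denominator = attr(x[[blk]], "denominator"))))
}
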