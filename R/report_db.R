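## The normalized multi-table report store shared by all modules.

.role_codes <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "LT", "HO", "DS", "RI", "OT")
## severity order used to collapse multiple outcome codes per report
.outcome_severity <- c(DE = 1L, LT = 2L, HO = 3L, DS = 4L, RI = 5L, OT = 6L)

#' Construct and validate a spontaneous-report database
#'
#' A `report_db` is the normalized in-memory form of one or more FAERS-style
#' quarterly file sets: five linked tables keyed by `primaryid` (one row per
#' report version in `demo`; child rows in `drug`, `reac`, `outc`, `ther`).
#'
#' @param demo `data.table` with columns `primaryid`, `caseid`,
#'   `caseversion`, `fda_dt` (receipt date, integer `YYYYMMDD`), `event_dt`,
#'   `age`, `age_cod`, `sex`, `occp_cod`, `reporter_country`, `quarter`.
#' @param drug columns `primaryid`, `drug_seq`, `drugname`, `role_cod`
#'   (one of `PS`, `SS`, `C`, `I`).
#' @param reac columns `primaryid`, `pt`.
#' @param outc columns `primaryid`, `outc_cod` (one of `DE`, `LT`, `HO`,
#'   `DS`, `RI`, `OT`).
#' @param ther columns `primaryid`, `drug_seq`, `start_dt`.
#' @return object of class `report_db` (a named list of `data.table`s).
#' @export
report_db <- function(demo, drug, reac, outc, ther) {
  db <- list(demo = as.data.table(demo), drug = as.data.table(drug),
             reac = as.data.table(reac), outc = as.data.table(outc),
             ther = as.data.table(ther))
  class(db) <- "report_db"
  validate_report_db(db)
  db
}

#' @rdname report_db
#' @param db object to validate.
#' @export
validate_report_db <- function(db) {
  stopifnot(inherits(db, "report_db"))
  need <- list(
    demo = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
             "age", "age_cod", "sex", "occp_cod", "reporter_country",
             "quarter"),
    drug = c("primaryid", "drug_seq", "drugname", "role_cod"),
    reac = c("primaryid", "pt"),
    outc = c("primaryid", "outc_cod"),
    ther = c("primaryid", "drug_seq", "start_dt"))
  for (tb in names(need)) {
    miss <- setdiff(need[[tb]], names(db[[tb]]))
    if (length(miss))
      stop(tb, " table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(db$demo$primaryid))
    stop("primaryid not unique within demo")
  for (tb in c("drug", "reac", "outc", "ther")) {
    orphan <- setdiff(db[[tb]]$primaryid, db$demo$primaryid)
    if (length(orphan))
      stop(tb, " rows reference unknown primaryid: ",
           paste(utils::head(orphan, 3), collapse = ", "))
  }
  bad_role <- setdiff(stats::na.omit(unique(db$drug$role_cod)), .role_codes)
  if (length(bad_role)) stop("unknown role code: ", paste(bad_role, collapse = ", "))
  bad_out <- setdiff(stats::na.omit(unique(db$outc$outc_cod)), .outcome_codes)
  if (length(bad_out)) stop("unknown outcome code: ", paste(bad_out, collapse = ", "))
  invisible(db)
}

#' @export
print.report_db <- function(x, ...) {
  cat("<report_db> ", nrow(x$demo), " report versions, ",
      data.table::uniqueN(x$demo$caseid), " cases, ",
      nrow(x$reac), " reaction rows, ",
      data.table::uniqueN(x$demo$quarter), " quarter(s)\n", sep = "")
  invisible(x)
}

## keep only the given primaryids, in all five tables
filter_db <- function(db, ids) {
  out <- lapply(unclass(db), function(tb) tb[primaryid %in% ids])
  class(out) <- "report_db"
  out
}

## row-bind two report_db objects (primaryids must be disjoint)
#' Combine report databases
#'
#' Concatenates the five tables of two or more `report_db` objects; the
#' `primaryid` sets must be disjoint.
#' @param ... `report_db` objects.
#' @return a `report_db`.
#' @export
rbind_db <- function(...) {
  dbs <- list(...)
  out <- lapply(c("demo", "drug", "reac", "outc", "ther"),
                function(tb) rbindlist(lapply(dbs, `[[`, tb)))
  names(out) <- c("demo", "drug", "reac", "outc", "ther")
  class(out) <- "report_db"
  validate_report_db(out)
  out
}
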