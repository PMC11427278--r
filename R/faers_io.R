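## Reading FAERS-style quarterly tables, case deduplication, drug-name
## matching and drug-event pair extraction.

.faers_files <- c(demo = "DEMO.txt", drug = "DRUG.txt", reac = "REAC.txt",
                  outc = "OUTC.txt", ther = "THER.txt")

.int_cols <- c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
               "drug_seq", "start_dt")

#' Read one FAERS-style quarter directory
#'
#' Expects the five `$`-delimited ASCII tables written by
#' [write_quarterly_files()] (or extracted FAERS quarterly files renamed
#' accordingly). Parsing is lenient: unparseable numeric fields (ages,
#' dates) become missing rather than raising.
#'
#' @param dir directory holding `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `OUTC.txt`, `THER.txt`.
#' @return a [report_db()].
#' @export
read_quarter <- function(dir) {
  paths <- file.path(dir, .faers_files)
  missing <- .faers_files[!file.exists(paths)]
  if (length(missing))
    stop("missing table file(s) in ", dir, ": ",
         paste(missing, collapse = ", "))
  tabs <- lapply(paths, function(p)
    fread(p, sep = "$", na.strings = "", colClasses = "character",
          header = TRUE))
  names(tabs) <- names(.faers_files)
  need <- list(demo = c("primaryid", "caseid", "caseversion", "fda_dt"),
               drug = c("primaryid", "drugname", "role_cod"),
               reac = c("primaryid", "pt"),
               outc = c("primaryid", "outc_cod"),
               ther = c("primaryid", "start_dt"))
  for (tb in names(need)) {
    miss <- setdiff(need[[tb]], names(tabs[[tb]]))
    if (length(miss))
      stop("malformed header in ", .faers_files[[tb]], ": missing ",
           paste(miss, collapse = ", "))
  }
  ## tolerated optional columns get defaults
  if (!"quarter" %in% names(tabs$demo))
    tabs$demo[, quarter := basename(normalizePath(dir, mustWork = FALSE))]
  for (col in c("event_dt", "age", "age_cod", "sex", "occp_cod",
                "reporter_country"))
    if (!col %in% names(tabs$demo)) tabs$demo[, (col) := NA_character_]
  if (!"drug_seq" %in% names(tabs$drug)) tabs$drug[, drug_seq := NA_character_]
  if (!"drug_seq" %in% names(tabs$ther)) tabs$ther[, drug_seq := NA_character_]

  lenient_int <- function(x) suppressWarnings(as.integer(x))
  for (tb in names(tabs)) {
    for (col in intersect(.int_cols, names(tabs[[tb]])))
      set(tabs[[tb]], j = col, value = lenient_int(tabs[[tb]][[col]]))
  }
  set(tabs$demo, j = "age", value = suppressWarnings(as.numeric(tabs$demo$age)))
  report_db(tabs$demo, tabs$drug, tabs$reac, tabs$outc, tabs$ther)
}

#' Read and concatenate several quarter directories
#'
#' @param dirs character vector of quarter directories (or one parent
#'   directory whose subdirectories are quarters).
#' @return a single [report_db()] union of all quarters.
#' @export
read_quarters <- function(dirs) {
  if (length(dirs) == 1L && dir.exists(dirs) &&
      !file.exists(file.path(dirs, "DEMO.txt"))) {
    sub <- list.dirs(dirs, recursive = FALSE)
    sub <- sub[file.exists(file.path(sub, "DEMO.txt"))]
    if (length(sub) == 0L)
      stop("no quarter directories (containing DEMO.txt) under ", dirs)
    dirs <- sub
  }
  do.call(rbind_db, lapply(dirs, read_quarter))
}

#' Deduplicate case versions
#'
#' FAERS cases accumulate versions as reports are amended; disproportionality
#' counts one row per case. Exactly one `primaryid` is retained per
#' `caseid`: the highest `caseversion`, ties broken by latest receipt date
#' (`fda_dt`) and then highest `primaryid`. Child-table rows of dropped
#' report versions are removed.
#'
#' @param db a [report_db()].
#' @return deduplicated [report_db()]; idempotent.
#' @export
deduplicate <- function(db) {
  validate_report_db(db)
  d <- db$demo[order(caseid, -caseversion, -fda_dt, -primaryid)]
  keep_ids <- d[!duplicated(caseid), primaryid]
  filter_db(db, keep_ids)
}

#' Load a drug synonym list
#'
#' Two-column TSV (`pattern`, `canonical`) with header. Patterns are matched
#' case-insensitively after whitespace/punctuation squashing.
#'
#' @param path TSV file.
#' @return object of class `drug_synonyms`.
#' @export
load_drug_synonyms <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("pattern", "canonical") %in% names(dt)))
    stop("synonym file needs columns 'pattern' and 'canonical'")
  drug_synonyms(canonical = dt$canonical[1], patterns = dt$pattern)
}

#' @rdname load_drug_synonyms
#' @param canonical canonical drug name.
#' @param patterns character vector of names to match (should include the
#'   canonical name).
#' @export
drug_synonyms <- function(canonical, patterns) {
  patterns <- unique(normalize_drug_name(patterns))
  canonical <- normalize_drug_name(canonical)
  if (length(patterns) == 0L || !any(nzchar(patterns)))
    stop("empty synonym list")
  if (!canonical %in% patterns) patterns <- c(canonical, patterns)
  structure(list(canonical = canonical, patterns = patterns),
            class = "drug_synonyms")
}

#' Default synonym list for the target drug neratinib
#' @return a `drug_synonyms` object loaded from the shipped list.
#' @export
neratinib_synonyms <- function() load_drug_synonyms(fs_extdata("neratinib_synonyms.tsv"))

#' Find reports mentioning the target drug
#'
#' @param db a [report_db()].
#' @param syn a [drug_synonyms()] object.
#' @param roles role codes to accept; the default `"PS"` restricts to
#'   primary-suspect mentions.
#' @return integer vector of matching `primaryid`s.
#' @export
match_target_drug <- function(db, syn, roles = "PS") {
  stopifnot(inherits(syn, "drug_synonyms"))
  validate_report_db(db)
  hit <- db$drug[normalize_drug_name(drugname) %in% syn$patterns &
                 role_cod %in% roles]
  sort(unique(hit$primaryid))
}

#' Distinct report-PT pairs
#'
#' The counting unit of the disproportionality tables: one record per
#' distinct (report, PT) pair; PTs repeated within a report collapse to one.
#'
#' @param db a [report_db()].
#' @param ids optional set of `primaryid`s to restrict to (e.g. the target
#'   drug's reports); default all reports.
#' @return `data.table` with columns `primaryid`, `pt`, `year` (report year,
#'   receipt date with event date as fallback).
#' @export
drug_event_pairs <- function(db, ids = NULL) {
  validate_report_db(db)
  if (!is.null(ids)) {
    unknown <- setdiff(ids, db$demo$primaryid)
    if (length(unknown))
      stop("ids not present in demo: ", paste(utils::head(unknown, 3),
                                              collapse = ", "))
  }
  yr <- db$demo[, .(primaryid,
                    year = fifelse(is.na(year_of(fda_dt)),
                                   year_of(event_dt), year_of(fda_dt)))]
  pairs <- unique(db$reac[!is.na(pt) & nzchar(pt), .(primaryid, pt)])
  if (!is.null(ids)) pairs <- pairs[primaryid %in% ids]
  pairs[yr, year := i.year, on = "primaryid"]
  pairs[]
}
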