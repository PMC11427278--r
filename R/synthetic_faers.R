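## Synthetic FAERS-like report-database generator with known ground truth.
##
## The generator emulates the structure a disproportionality pipeline
## consumes: multi-PT reports, one primary-suspect drug among co-reported
## drugs, planted drug-event association strengths (target relative
## reporting ratios), duplicate case versions, heavy demographic
## missingness, country/reporter/outcome mixes, and therapy-start vs event
## dates for time-to-onset.

#' Configuration for the synthetic report-database generator
#'
#' Defaults emulate a FAERS-scale screening setting for a single rare
#' target drug: 26 quarters (2017Q3-2023Q4), a power-law background PT
#' vocabulary, about 2.5 PTs per report, ~1% of reports listing the target
#' drug as primary suspect, and the demographic mixes of a heavily
#' under-specified spontaneous-report stream (>90% missing age and sex).
#'
#' @param n_reports number of distinct cases to simulate.
#' @param quarters character vector of year-quarter labels (see
#'   [quarter_seq()]).
#' @param n_background_pts size of the background PT vocabulary.
#' @param background_pt_weights probability vector over PTs; default is a
#'   Zipf (rank^-1) law, renormalized.
#' @param pts_per_report_mean mean PT count per report; counts are drawn as
#'   `1 + Poisson(mean - 1)`, truncated at the vocabulary size.
#' @param drug_exposure_prob probability a report lists the target drug as
#'   primary suspect.
#' @param planted_signals named numeric vector, PT name -> target relative
#'   reporting ratio (rrr >= 0). Unnamed PTs have rrr 1. For exposed reports
#'   the PT sampling weights are `w_j * rrr_j` renormalized, so recovery of
#'   a planted rrr is approximate (exact only in the small-weight limit).
#' @param duplicate_rate fraction of cases additionally emitted as a second,
#'   higher case version with a later receipt date.
#' @param missing_age_rate,missing_sex_rate probability the field is blank.
#' @param country_mix,reporter_mix named probability vectors for reporter
#'   country and reporter occupation code.
#' @param serious_prob probability a report carries a serious outcome code.
#' @param outcome_mix named probability vector over outcome codes
#'   (`DE`, `LT`, `HO`, `DS`, `RI`, `OT`) for serious reports.
#' @param tto_sampler function(m) returning m non-negative integer
#'   therapy-start-to-event day counts; the default draws from a mixture
#'   over the bins <7, 7-28, 28-60, >=60 days with weights 0.52/0.21/0.11/0.16
#'   (uniform within bin; the last bin extends to one year).
#' @param missing_ther_rate probability the therapy start date is blank
#'   (time-to-onset then unresolvable).
#' @param pt_names optional PT vocabulary; default `"synthetic pt 001"`, ...
#' @param target_drug name emitted for the target drug.
#' @param seed integer seed; the same config (including seed) yields a
#'   byte-identical database.
#' @return validated object of class `sim_config`.
#' @seealso [generate_database()]
#' @export
sim_config <- function(n_reports = 200000L,
                       quarters = quarter_seq("2017Q3", "2023Q4"),
                       n_background_pts = 200L,
                       background_pt_weights = NULL,
                       pts_per_report_mean = 2.5,
                       drug_exposure_prob = 0.01,
                       planted_signals = numeric(),
                       duplicate_rate = 0.05,
                       missing_age_rate = 0.972,
                       missing_sex_rate = 0.966,
                       country_mix = c("United States" = 0.8556,
                                       "Argentina" = 0.0330,
                                       "China" = 0.0400,
                                       "Japan" = 0.0300,
                                       "Germany" = 0.0414),
                       reporter_mix = c(PH = 0.5006, OT = 0.2895,
                                        CSM = 0.1289, MD = 0.0745,
                                        LW = 0.0019, UNK = 0.0046),
                       serious_prob = 0.547,
                       outcome_mix = c(HO = 0.3728, DE = 0.2260,
                                       LT = 0.0118, DS = 0.0047,
                                       RI = 0.0012, OT = 0.3835),
                       tto_sampler = NULL,
                       missing_ther_rate = 0.72,
                       pt_names = NULL,
                       target_drug = "NERATINIB",
                       seed = 1L) {
  if (length(quarters) == 0L) stop("empty quarter list")
  n_background_pts <- as.integer(n_background_pts)
  if (is.null(pt_names))
    pt_names <- sprintf("synthetic pt %03d", seq_len(n_background_pts))
  stopifnot(length(pt_names) == n_background_pts)
  if (is.null(background_pt_weights)) {
    background_pt_weights <- 1 / seq_len(n_background_pts)
    background_pt_weights <- background_pt_weights / sum(background_pt_weights)
  }
  if (length(background_pt_weights) != n_background_pts ||
      any(background_pt_weights < 0) ||
      abs(sum(background_pt_weights) - 1) > 1e-9)
    stop("background_pt_weights is not a probability vector")
  rates <- c(drug_exposure_prob, duplicate_rate, missing_age_rate,
             missing_sex_rate, serious_prob, missing_ther_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (length(planted_signals)) {
    if (is.null(names(planted_signals)) || any(!nzchar(names(planted_signals))))
      stop("planted_signals must be a named vector (PT -> rrr)")
    if (any(!is.finite(planted_signals)) || any(planted_signals < 0))
      stop("planted rrr values must be finite and >= 0")
    unknown <- setdiff(names(planted_signals), pt_names)
    if (length(unknown))
      stop("planted PT not in vocabulary: ", paste(unknown, collapse = ", "))
  }
  for (mx in list(country_mix, reporter_mix, outcome_mix))
    if (abs(sum(mx) - 1) > 1e-6 || any(mx < 0))
      stop("categorical mixes must be probability vectors")
  if (is.null(tto_sampler)) tto_sampler <- default_tto_sampler
  cfg <- list(n_reports = as.integer(n_reports), quarters = quarters,
              n_background_pts = n_background_pts,
              background_pt_weights = background_pt_weights,
              pts_per_report_mean = pts_per_report_mean,
              drug_exposure_prob = drug_exposure_prob,
              planted_signals = planted_signals,
              duplicate_rate = duplicate_rate,
              missing_age_rate = missing_age_rate,
              missing_sex_rate = missing_sex_rate,
              country_mix = country_mix, reporter_mix = reporter_mix,
              serious_prob = serious_prob, outcome_mix = outcome_mix,
              tto_sampler = tto_sampler,
              missing_ther_rate = missing_ther_rate,
              pt_names = pt_names, target_drug = target_drug,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

## Table-1-like time-to-onset mixture (days)
default_tto_sampler <- function(m) {
  bin <- sample.int(4L, m, replace = TRUE,
                    prob = c(0.5168, 0.2067, 0.1145, 0.1620))
  lo <- c(0L, 7L, 28L, 60L)[bin]
  hi <- c(7L, 28L, 60L, 365L)[bin]
  lo + floor(stats::runif(m) * (hi - lo))
}

#' SOC assignment for the synthetic PT vocabulary
#'
#' Each synthetic PT is deterministically assigned one of the 22 standard
#' system organ classes (round-robin by rank), so SOC-level aggregation is
#' exercised on synthetic data. The shipped toy MedDRA dictionary contains
#' these rows for the default 200-PT vocabulary.
#'
#' @param pt_names character vector of PT names.
#' @return `data.table` with columns `pt`, `soc`.
#' @export
synthetic_pt_soc <- function(pt_names) {
  data.table(pt = pt_names,
             soc = soc_names()[(seq_along(pt_names) - 1L) %% length(soc_names()) + 1L])
}

#' Generate a synthetic report database with known ground truth
#'
#' Draws `n_reports` cases under the configured mixes; exposed reports
#' (target drug as primary suspect) sample their PTs with weights
#' `w_j * rrr_j` renormalized, unexposed with `w_j`. PTs within a report are
#' distinct. A configurable fraction of cases is emitted twice (same
#' `caseid`, incremented `caseversion`, later receipt date) to exercise
#' deduplication.
#'
#' @param config a [sim_config()].
#' @return list with elements `db` (a [report_db()]) and `truth` (class
#'   `sim_truth`: named `rrr` vector over the full PT vocabulary, a
#'   `duplicates` table of emitted duplicate versions, and the `pt_soc`
#'   assignment).
#' @examples
#' out <- generate_database(sim_config(n_reports = 500, seed = 7))
#' out$db
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_database_impl(config))
}

generate_database_impl <- function(cfg) {
  n <- cfg$n_reports
  P <- cfg$n_background_pts
  w <- cfg$background_pt_weights
  rrr <- rep(1, P); names(rrr) <- cfg$pt_names
  rrr[names(cfg$planted_signals)] <- cfg$planted_signals
  we <- w * rrr
  if (sum(we) <= 0) stop("planted signals zero out all exposed weight")
  we <- we / sum(we)

  caseid <- seq_len(n)
  primaryid <- caseid * 10L + 1L
  exposed <- stats::runif(n) < cfg$drug_exposure_prob
  quarter <- sample(cfg$quarters, n, replace = TRUE)

  ## event / receipt dates within the assigned quarter
  qd <- lapply(cfg$quarters, quarter_days)
  names(qd) <- cfg$quarters
  qstart <- as.Date(vapply(qd, function(z) as.character(z$start), ""))[
    match(quarter, cfg$quarters)]
  qlen <- vapply(qd, function(z) as.integer(z$end - z$start) + 1L, 1L)[
    match(quarter, cfg$quarters)]
  event_date <- qstart + floor(stats::runif(n) * qlen)
  fda_date <- event_date + sample.int(61L, n, replace = TRUE) - 1L

  age <- ifelse(stats::runif(n) < cfg$missing_age_rate, NA_real_,
                pmin(pmax(round(stats::rnorm(n, 55, 13)), 18), 90))
  sex <- ifelse(stats::runif(n) < cfg$missing_sex_rate, NA_character_,
                sample(c("F", "M"), n, replace = TRUE, prob = c(0.96, 0.04)))
  occp <- sample(names(cfg$reporter_mix), n, replace = TRUE,
                 prob = cfg$reporter_mix)
  occp[occp == "UNK"] <- NA_character_
  country <- sample(names(cfg$country_mix), n, replace = TRUE,
                    prob = cfg$country_mix)

  demo <- data.table(primaryid = primaryid, caseid = caseid,
                     caseversion = 1L,
                     fda_dt = as_yyyymmdd(fda_date),
                     event_dt = as_yyyymmdd(event_date),
                     age = age,
                     age_cod = ifelse(is.na(age), NA_character_, "YR"),
                     sex = sex, occp_cod = occp,
                     reporter_country = country, quarter = quarter)

  ## --- reactions: k distinct PTs per report -------------------------------
  k <- pmin(1L + stats::rpois(n, max(cfg$pts_per_report_mean - 1, 0)), P)
  ri <- rep(seq_len(n), k)
  ex_slot <- exposed[ri]
  idx <- integer(length(ri))
  idx[ex_slot] <- sample.int(P, sum(ex_slot), replace = TRUE, prob = we)
  idx[!ex_slot] <- sample.int(P, sum(!ex_slot), replace = TRUE, prob = w)
  ## redraw whole reports whose slots collided until all PTs distinct
  for (iter in 1:100) {
    o <- order(ri, idx)
    dup <- c(FALSE, diff(ri[o]) == 0 & diff(idx[o]) == 0)
    if (!any(dup)) break
    bad_reports <- unique(ri[o][dup])
    redo <- ri %in% bad_reports
    re_ex <- redo & ex_slot
    re_un <- redo & !ex_slot
    if (any(re_ex)) idx[re_ex] <- sample.int(P, sum(re_ex), TRUE, prob = we)
    if (any(re_un)) idx[re_un] <- sample.int(P, sum(re_un), TRUE, prob = w)
  }
  reac <- data.table(primaryid = primaryid[ri], pt = cfg$pt_names[idx])

  ## --- drugs: target PS for exposed + background drugs --------------------
  bg_drugs <- sprintf("BACKGROUND DRUG %02d", 1:40)
  n_co <- stats::rpois(n, 0.8)
  n_drugs <- ifelse(exposed, 1L + n_co, pmax(1L, n_co))
  di <- rep(seq_len(n), n_drugs)
  seq_in_rep <- sequence(n_drugs)
  first <- seq_in_rep == 1L
  dname <- sample(bg_drugs, length(di), replace = TRUE)
  dname[first & exposed[di]] <- cfg$target_drug
  role <- sample(c("C", "SS", "I"), length(di), replace = TRUE,
                 prob = c(0.6, 0.3, 0.1))
  role[first] <- "PS"
  drug <- data.table(primaryid = primaryid[di], drug_seq = seq_in_rep,
                     drugname = dname, role_cod = role)

  ## --- outcomes ------------------------------------------------------------
  serious <- stats::runif(n) < cfg$serious_prob
  outc <- data.table(
    primaryid = primaryid[serious],
    outc_cod = sample(names(cfg$outcome_mix), sum(serious), replace = TRUE,
                      prob = cfg$outcome_mix))

  ## --- therapy start dates (drug_seq 1 = the PS drug) ----------------------
  has_ther <- stats::runif(n) >= cfg$missing_ther_rate
  tto <- cfg$tto_sampler(sum(has_ther))
  ther <- data.table(primaryid = primaryid[has_ther], drug_seq = 1L,
                     start_dt = as_yyyymmdd(event_date[has_ther] - tto))

  ## --- duplicate case versions ---------------------------------------------
  dup_case <- stats::runif(n) < cfg$duplicate_rate
  if (any(dup_case)) {
    lag <- sample.int(90L, sum(dup_case), replace = TRUE)
    demo2 <- demo[dup_case]
    demo2[, `:=`(primaryid = caseid * 10L + 2L, caseversion = 2L,
                 fda_dt = as_yyyymmdd(as.Date(as.character(fda_dt),
                                              "%Y%m%d") + lag))]
    remap <- function(tb) {
      tb2 <- tb[primaryid %in% demo$primaryid[dup_case]]
      tb2[, primaryid := (primaryid %/% 10L) * 10L + 2L]
      tb2
    }
    db <- report_db(rbind(demo, demo2), rbind(drug, remap(drug)),
                    rbind(reac, remap(reac)), rbind(outc, remap(outc)),
                    rbind(ther, remap(ther)))
    duplicates <- data.table(caseid = demo2$caseid,
                             primaryid = demo2$primaryid,
                             duplicate_of = demo$primaryid[dup_case])
  } else {
    db <- report_db(demo, drug, reac, outc, ther)
    duplicates <- data.table(caseid = integer(), primaryid = integer(),
                             duplicate_of = integer())
  }
  truth <- list(rrr = rrr, duplicates = duplicates,
                pt_soc = synthetic_pt_soc(cfg$pt_names))
  class(truth) <- "sim_truth"
  list(db = db, truth = truth)
}

#' Write a report database as FAERS-like quarterly file sets
#'
#' One subdirectory per quarter, each holding `DEMO.txt`, `DRUG.txt`,
#' `REAC.txt`, `OUTC.txt`, `THER.txt`: ASCII, `$`-delimited, header row,
#' missing values blank. Round-trippable by [read_quarter()].
#'
#' @param db a [report_db()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the quarter subdirectories written.
#' @export
write_quarterly_files <- function(db, out_dir) {
  validate_report_db(db)
  if (nrow(db$demo) == 0L) stop("empty report database")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  qmap <- db$demo[, .(primaryid, quarter)]
  dirs <- character()
  for (q in sort(unique(db$demo$quarter))) {
    qdir <- file.path(out_dir, q)
    dir.create(qdir, showWarnings = FALSE)
    ids <- qmap[quarter == q, primaryid]
    fwrite(db$demo[primaryid %in% ids], file.path(qdir, "DEMO.txt"),
           sep = "$", na = "", quote = FALSE)
    for (tb in c("drug", "reac", "outc", "ther"))
      fwrite(db[[tb]][primaryid %in% ids],
             file.path(qdir, paste0(toupper(tb), ".txt")),
             sep = "$", na = "", quote = FALSE)
    dirs <- c(dirs, qdir)
  }
  invisible(dirs)
}

#' Write generator ground truth as TSV files
#'
#' @param truth the `truth` element returned by [generate_database()].
#' @param out_dir directory for `rrr.tsv`, `duplicates.tsv`, `pt_soc.tsv`.
#' @return invisibly, the files written.
#' @export
write_ground_truth <- function(truth, out_dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(out_dir, "rrr.tsv")
  fwrite(data.table(pt = names(truth$rrr), rrr = truth$rrr), f1, sep = "\t")
  f2 <- file.path(out_dir, "duplicates.tsv")
  fwrite(truth$duplicates, f2, sep = "\t")
  f3 <- file.path(out_dir, "pt_soc.tsv")
  fwrite(truth$pt_soc, f3, sep = "\t")
  invisible(c(f1, f2, f3))
}
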