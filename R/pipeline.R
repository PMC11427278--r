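## End-to-end orchestration: ingest -> dedup -> target filter -> PT/SOC
## tables -> four algorithms -> consensus -> descriptives -> rankings ->
## time scans -> label-novelty flagging.

#' Pipeline configuration
#'
#' @param quarter_dirs character vector of quarter directories (or one
#'   parent directory of quarters).
#' @param synonym_file drug synonym TSV (default: the shipped neratinib
#'   list).
#' @param meddra_file PT -> SOC dictionary TSV (default: the shipped toy
#'   dictionary).
#' @param roles drug role codes accepted as target mentions.
#' @param criteria a [signal_criteria()].
#' @param label_file TSV with column `pt` listing label-documented PTs;
#'   consensus PTs absent from it are flagged as new signals (default: the
#'   shipped neratinib label list).
#' @param top_k number of PTs kept in the IC025 ranking output.
#' @param timescan_terms PTs to compute IC trajectories for (default: none).
#' @param out_dir output directory for the result CSVs and run log.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(quarter_dirs, out_dir,
                            synonym_file = NULL, meddra_file = NULL,
                            roles = "PS", criteria = signal_criteria(),
                            label_file = NULL, top_k = 25L,
                            timescan_terms = character()) {
  stopifnot(inherits(criteria, "signal_criteria"), top_k >= 1L)
  for (f in c(synonym_file, meddra_file, label_file))
    if (!is.null(f) && !file.exists(f)) stop("file does not exist: ", f)
  structure(list(quarter_dirs = quarter_dirs, out_dir = out_dir,
                 synonym_file = synonym_file, meddra_file = meddra_file,
                 roles = roles, criteria = criteria,
                 label_file = label_file, top_k = as.integer(top_k),
                 timescan_terms = timescan_terms),
            class = "pipeline_config")
}

#' Run the full signal-detection pipeline
#'
#' Stages: read quarters, deduplicate, match the target drug, build
#' report-PT pairs, compute PT- and SOC-level disproportionality with the
#' consensus rule, descriptive profile, IC025 ranking, optional IC time
#' scans, and label-novelty flags. Outputs are written to
#' `config$out_dir`: `descriptives.csv`, `soc_signals.csv` (ROR
#' descending), `pt_signals.csv` (case count descending, with `on_label`
#' and `new_signal` columns), `top_ic025.csv`, `timescan.csv` (when terms
#' are configured) and `run_log.txt`. A failing stage aborts with the stage
#' name and removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the deduplicated database, target ids,
#'   pair tables, result tables and the descriptive summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(out_dir, c("descriptives.csv", "soc_signals.csv",
                                  "pt_signals.csv", "top_ic025.csv",
                                  "timescan.csv", "run_log.txt"))
  stage <- "setup"
  res <- tryCatch({
    stage <- "ingest"
    db <- read_quarters(config$quarter_dirs)
    n_raw <- nrow(db$demo)

    stage <- "deduplicate"
    db <- deduplicate(db)
    n_dedup <- nrow(db$demo)

    stage <- "target-match"
    syn <- if (is.null(config$synonym_file)) neratinib_synonyms()
           else load_drug_synonyms(config$synonym_file)
    ids <- match_target_drug(db, syn, roles = config$roles)

    stage <- "dictionary"
    dict <- if (is.null(config$meddra_file)) meddra_toy()
            else load_meddra(config$meddra_file)

    stage <- "pairs"
    pairs_all <- drug_event_pairs(db)
    pairs_target <- pairs_all[primaryid %in% ids]

    stage <- "pt-signals"
    pt_res <- if (nrow(pairs_target)) {
      disproportionality(build_tables(pairs_target, pairs_all),
                         config$criteria, level = "PT")
    } else empty_results("PT")
    label_pts <- tolower(
      if (is.null(config$label_file)) neratinib_label_pts()
      else fread(config$label_file, sep = "\t", header = TRUE)$pt)
    pt_res[, on_label := tolower(term) %in% label_pts]
    pt_res[, new_signal := consensus & !on_label]
    setorder(pt_res, -a, term)

    stage <- "soc-signals"
    soc_res <- if (nrow(pairs_target)) {
      disproportionality(
        build_tables(pairs_to_soc(pairs_target, dict),
                     pairs_to_soc(pairs_all, dict)),
        config$criteria, level = "SOC")
    } else empty_results("SOC")
    setorder(soc_res, -ror, -a, term, na.last = TRUE)

    stage <- "descriptives"
    descr <- summarize_reports(db, ids)

    stage <- "ranking"
    top <- rank_by_ic025(pt_res, config$top_k)

    stage <- "timescan"
    scans <- if (length(config$timescan_terms)) {
      rbindlist(lapply(config$timescan_terms, function(tm)
        ic_over_time(pairs_all, pairs_target, tm)))
    } else NULL

    stage <- "write"
    fwrite(descriptives_table(descr), outputs[1])
    fwrite(soc_res, outputs[2])
    fwrite(pt_res, outputs[3])
    fwrite(top, outputs[4])
    if (!is.null(scans)) fwrite(scans, outputs[5])
    writeLines(c(
      sprintf("faersignal run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      sprintf("quarters: %s", paste(config$quarter_dirs, collapse = ", ")),
      sprintf("report versions read: %d; after deduplication: %d",
              n_raw, n_dedup),
      sprintf("target drug: %s (roles %s); matched reports: %d",
              syn$canonical, paste(config$roles, collapse = ","),
              length(ids)),
      sprintf("dictionary version: %s; unmapped PTs in target pairs: %d",
              attr(dict, "version"),
              sum(map_pt(dict, unique(pairs_target$pt)) == meddra_unmapped())),
      sprintf("criteria: min_a=%g ror_lo>%g prr>=%g chisq>=%g ic025>%g ebgm05>%g",
              config$criteria$min_a, config$criteria$ror_lo_gt,
              config$criteria$prr_ge, config$criteria$chisq_ge,
              config$criteria$ic025_gt, config$criteria$ebgm05_gt),
      sprintf("consensus PTs: %d (new signals: %d); consensus SOCs: %d",
              sum(pt_res$consensus), sum(pt_res$new_signal),
              sum(soc_res$consensus))),
      outputs[6])
    list(db = db, target_ids = ids, pairs_all = pairs_all,
         pairs_target = pairs_target, pt_signals = pt_res,
         soc_signals = soc_res, descriptives = descr, top_ic025 = top,
         timescan = scans)
  }, error = function(e) {
    unlink(outputs[file.exists(outputs)])
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

empty_results <- function(level) {
  data.table(term = character(), level = character(), a = integer(),
             b = integer(), c_ = integer(), d_ = integer(),
             ror = numeric(), ror_lo = numeric(), ror_hi = numeric(),
             prr = numeric(), prr_lo = numeric(), prr_hi = numeric(),
             chisq = numeric(), ic = numeric(), ic025 = numeric(),
             ic975 = numeric(), ebgm = numeric(), ebgm05 = numeric(),
             ror_pos = logical(), prr_pos = logical(),
             bcpnn_pos = logical(), ebgm_pos = logical(),
             consensus = logical())
}
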