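library(data.table)

## Minimal valid report_db built from per-table overrides. Every report gets
## one target-drug PS row unless a drug table is supplied.
make_db <- function(n = 3,
                    demo = NULL, drug = NULL, reac = NULL,
                    outc = NULL, ther = NULL) {
  ids <- seq_len(n) * 10L + 1L
  demo0 <- data.table(
    primaryid = ids, caseid = seq_len(n), caseversion = 1L,
    fda_dt = 20180215L, event_dt = 20180201L,
    age = NA_real_, age_cod = NA_character_, sex = NA_character_,
    occp_cod = NA_character_, reporter_country = "United States",
    quarter = "2018Q1")
  if (!is.null(demo)) for (nm in names(demo)) set(demo0, j = nm, value = demo[[nm]])
  ids <- demo0$primaryid
  drug0 <- drug %||% data.table(primaryid = ids, drug_seq = 1L,
                                drugname = "NERATINIB", role_cod = "PS")
  reac0 <- reac %||% data.table(primaryid = ids, pt = "diarrhoea")
  outc0 <- outc %||% data.table(primaryid = integer(), outc_cod = character())
  ther0 <- ther %||% data.table(primaryid = integer(), drug_seq = integer(),
                                start_dt = integer())
  report_db(demo0, drug0, reac0, outc0, ther0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## small simulated database shared by several tests (built once per run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_database(sim_config(
        n_reports = 20000, seed = 42, duplicate_rate = 0.1,
        planted_signals = c("synthetic pt 020" = 8)))
    cache
  }
})
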