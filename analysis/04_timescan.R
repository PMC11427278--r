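#!/usr/bin/env Rscript
## Information-component time scans: cumulative-by-year IC with 95%
## credibility bounds for a planted persistent signal and a null PT. The
## credibility interval narrows as reports accumulate; a year is flagged
## when IC025 > 0.

library(faersignal)
suppressMessages(library(data.table))

db_dir <- "scratch/synthetic_db"
if (!dir.exists(db_dir))
  stop("run analysis/01_simulate.R first (", db_dir, " missing)")

db <- deduplicate(read_quarters(db_dir))
ids <- match_target_drug(db, neratinib_synonyms())
pairs_all <- drug_event_pairs(db)
pairs_target <- pairs_all[primaryid %in% ids]

terms <- c(planted = "synthetic pt 015", null = "synthetic pt 016")
traj <- rbindlist(lapply(terms, function(tm)
  ic_over_time(pairs_all, pairs_target, tm)))
print(traj)

fwrite(traj, "results/timescan.csv")
cat("written results/timescan.csv\n")
if (requireNamespace("ggplot2", quietly = TRUE)) {
  p <- plot_ic_trajectory(traj)
  ggplot2::ggsave("scratch/timescan.pdf", p, width = 7, height = 4)
  cat("plot written to scratch/timescan.pdf\n")
}
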