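#!/usr/bin/env Rscript
## Build the synthetic study database: a FAERS-like quarterly report stream
## (2017Q3-2023Q4) with three planted drug-event associations for the
## target drug, duplicate case versions and heavy demographic missingness.
## The file set is written under scratch/ (it is bulky and fully
## regenerable from the seed); the ground truth and a small summary go to
## results/.

library(faersignal)
suppressMessages(library(data.table))

planted <- c("synthetic pt 015" = 8, "synthetic pt 030" = 10,
             "synthetic pt 050" = 12)
cfg <- sim_config(n_reports = 60000, seed = 99, duplicate_rate = 0.05,
                  planted_signals = planted)

out <- generate_database(cfg)
db_dir <- "scratch/synthetic_db"
truth_dir <- "results/ground_truth"
unlink(db_dir, recursive = TRUE)
write_quarterly_files(out$db, db_dir)
write_ground_truth(out$truth, truth_dir)

cat("Synthetic database written to", db_dir, "\n")
print(out$db)
cat(sprintf("planted signals: %s\n",
            paste(sprintf("%s (rrr %g)", names(planted), planted),
                  collapse = ", ")))
cat(sprintf("duplicate case versions emitted: %d\n",
            nrow(out$truth$duplicates)))
cat("Ground truth written to", truth_dir, "\n")
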