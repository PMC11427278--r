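#!/usr/bin/env Rscript
## Descriptive profile of the target drug's reports in the synthetic
## database: yearly counts, sex, age bands, reporter, country, serious
## outcomes (most-severe per report) and time-to-onset bins, each with its
## explicit denominator.

library(faersignal)
suppressMessages(library(data.table))

db_dir <- "scratch/synthetic_db"
if (!dir.exists(db_dir))
  stop("run analysis/01_simulate.R first (", db_dir, " missing)")

db <- deduplicate(read_quarters(db_dir))
ids <- match_target_drug(db, neratinib_synonyms())
s <- summarize_reports(db, ids)
print(s)

fwrite(descriptives_table(s), "results/descriptives.csv")
cat("written results/descriptives.csv\n")
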