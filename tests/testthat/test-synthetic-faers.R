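test_that("config validation rejects invalid generative parameters", {
  expect_error(sim_config(quarters = character()), "empty quarter")
  expect_error(sim_config(background_pt_weights = c(0.5, 0.6),
                          n_background_pts = 2), "probability vector")
  expect_error(sim_config(planted_signals = c("no such pt" = 2)),
               "not in vocabulary")
  expect_error(sim_config(planted_signals = c("synthetic pt 001" = -1)),
               "finite and >= 0")
  expect_error(sim_config(planted_signals = setNames(2, "")), "named")
  expect_error(sim_config(duplicate_rate = 1.2), "rates")
})

test_that("same config and seed give an identical database", {
  cfg <- sim_config(n_reports = 2000, seed = 11,
                    planted_signals = c("synthetic pt 005" = 4))
  out1 <- generate_database(cfg)
  out2 <- generate_database(cfg)
  for (tb in c("demo", "drug", "reac", "outc", "ther"))
    expect_identical(out1$db[[tb]], out2$db[[tb]])
  expect_identical(out1$truth$rrr, out2$truth$rrr)
  ## and generation does not disturb the global RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_database(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generated structure matches the configured mixes", {
  out <- small_sim()
  db <- out$db
  n_cases <- uniqueN(db$demo$caseid)
  expect_identical(n_cases, 20000L)

  ## PTs within a report are distinct
  expect_identical(anyDuplicated(db$reac, by = c("primaryid", "pt")), 0L)

  ## mean PTs per report near 2.5
  k <- db$reac[, .N, by = primaryid]$N
  expect_gt(mean(k), 2.3); expect_lt(mean(k), 2.7)

  ## duplicates: same caseid, version 2, later receipt date
  dups <- db$demo[caseversion == 2L]
  expect_gt(nrow(dups), 0.07 * n_cases)  # duplicate_rate 0.1
  expect_lt(nrow(dups), 0.13 * n_cases)
  orig <- db$demo[caseversion == 1L][dups, on = "caseid"]
  expect_true(all(orig$i.fda_dt > orig$fda_dt))
  expect_identical(sort(out$truth$duplicates$primaryid),
                   sort(dups$primaryid))

  ## demographic missingness near configured rates
  v1 <- db$demo[caseversion == 1L]
  expect_gt(mean(is.na(v1$age)), 0.96)
  expect_gt(mean(is.na(v1$sex)), 0.95)

  ## exposed reports carry the target drug as primary suspect
  ps <- db$drug[role_cod == "PS" & drugname == "NERATINIB"]
  expect_gt(nrow(ps), 0)
  expect_true(all(ps$primaryid %in% db$demo$primaryid))

  ## ground truth covers every PT and every planted one
  expect_identical(length(out$truth$rrr), 200L)
  expect_identical(unname(out$truth$rrr[["synthetic pt 020"]]), 8)
})

test_that("null generation is calibrated: RRR intervals cover 1", {
  out <- generate_database(sim_config(n_reports = 50000, seed = 7))
  db <- deduplicate(out$db)
  ids <- match_target_drug(db, neratinib_synonyms())
  pa <- drug_event_pairs(db)
  res <- disproportionality(build_tables(pa[primaryid %in% ids], pa))
  res <- res[a >= 3]
  ## IC credibility interval covering 0 <=> RRR interval covering 1
  cover <- mean(res$ic025 <= 0 & res$ic975 >= 0)
  expect_gte(cover, 0.9)
})

test_that("write_quarterly_files round-trips and handles degenerate input", {
  out <- generate_database(sim_config(n_reports = 300, seed = 5))
  td <- withr::local_tempdir()
  write_quarterly_files(out$db, td)
  db2 <- read_quarters(td)
  for (tb in c("demo", "drug", "reac", "outc", "ther")) {
    x <- setorder(copy(out$db[[tb]]), primaryid)
    y <- setorder(copy(db2[[tb]]), primaryid)
    setcolorder(y, names(x))
    expect_equal(x, y, ignore_attr = TRUE)
  }
  ## DEMO row conservation including duplicates
  expect_identical(nrow(db2$demo), nrow(out$db$demo))
  expect_error(write_quarterly_files(
    report_db(out$db$demo[0], out$db$drug[0], out$db$reac[0],
              out$db$outc[0], out$db$ther[0]), td), "empty")
})

test_that("ground truth writes as TSV", {
  out <- generate_database(sim_config(n_reports = 200, seed = 5,
                                      planted_signals = c("synthetic pt 002" = 3)))
  td <- withr::local_tempdir()
  files <- write_ground_truth(out$truth, td)
  expect_true(all(file.exists(files)))
  rrr <- fread(file.path(td, "rrr.tsv"))
  expect_identical(nrow(rrr), 200L)
  expect_identical(rrr[pt == "synthetic pt 002", as.numeric(rrr)], 3)
})
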