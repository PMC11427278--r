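test_that("read_quarter parses a quarter leniently", {
  db <- make_db(3, demo = list(age = c(54, NA, NA)))
  td <- withr::local_tempdir()
  write_quarterly_files(db, td)
  qdir <- file.path(td, "2018Q1")

  got <- read_quarter(qdir)
  expect_identical(nrow(got$demo), 3L)

  ## unparseable age and date fields become missing, never raise
  demo_txt <- readLines(file.path(qdir, "DEMO.txt"))
  demo_txt[2] <- sub("54", "XX", demo_txt[2])
  demo_txt[2] <- sub("20180201", "NOTADATE", demo_txt[2])
  writeLines(demo_txt, file.path(qdir, "DEMO.txt"))
  got <- read_quarter(qdir)
  expect_true(is.na(got$demo$age[1]))
  expect_true(is.na(got$demo$event_dt[1]))

  ## missing table file
  file.remove(file.path(qdir, "OUTC.txt"))
  expect_error(read_quarter(qdir), "missing table file")

  ## malformed header
  write_quarterly_files(db, td)
  reac_txt <- readLines(file.path(qdir, "REAC.txt"))
  reac_txt[1] <- "primaryid$wrongname"
  writeLines(reac_txt, file.path(qdir, "REAC.txt"))
  expect_error(read_quarter(qdir), "malformed header")
})

test_that("two disjoint quarters concatenate to their union", {
  db1 <- make_db(2)
  db2 <- make_db(2, demo = list(primaryid = c(910L, 920L),
                                caseid = c(91L, 92L), quarter = "2018Q2"))
  td <- withr::local_tempdir()
  write_quarterly_files(db1, td)
  write_quarterly_files(db2, td)
  all_db <- read_quarters(td)
  expect_identical(nrow(all_db$demo), 4L)
  expect_identical(uniqueN(all_db$demo$quarter), 2L)
})

test_that("deduplicate keeps highest version, then latest receipt, then highest id", {
  demo <- data.table(
    primaryid = c(101L, 102L, 201L, 202L, 301L, 302L, 401L),
    caseid    = c(1L,   1L,   2L,   2L,   3L,   3L,   4L),
    caseversion = c(1L, 2L,   1L,   1L,   2L,   2L,   1L),
    fda_dt = c(20180101L, 20180301L, 20180101L, 20180401L,
               20180501L, 20180501L, 20180101L),
    event_dt = NA_integer_, age = NA_real_, age_cod = NA_character_,
    sex = NA_character_, occp_cod = NA_character_,
    reporter_country = NA_character_, quarter = "2018Q1")
  db <- report_db(demo,
                  data.table(primaryid = demo$primaryid, drug_seq = 1L,
                             drugname = "x", role_cod = "PS"),
                  data.table(primaryid = demo$primaryid, pt = "nausea"),
                  data.table(primaryid = integer(), outc_cod = character()),
                  data.table(primaryid = integer(), drug_seq = integer(),
                             start_dt = integer()))
  dd <- deduplicate(db)
  expect_setequal(dd$demo$primaryid,
                  c(102L,  # higher caseversion
                    202L,  # version tie -> later fda_dt
                    302L,  # full tie -> higher primaryid
                    401L))
  ## child rows of dropped versions removed
  expect_setequal(dd$reac$primaryid, dd$demo$primaryid)
  ## idempotent, never increases row counts
  dd2 <- deduplicate(dd)
  expect_identical(dd2$demo, dd$demo)
  expect_lte(nrow(dd$demo), nrow(db$demo))
})

test_that("dedup of synthetic duplicates recovers the distinct case count", {
  out <- small_sim()  # duplicate_rate 0.1
  dd <- deduplicate(out$db)
  expect_identical(nrow(dd$demo), uniqueN(out$db$demo$caseid))
  ## the retained version of a duplicated case is version 2
  dup_cases <- out$truth$duplicates$caseid
  expect_true(all(dd$demo[caseid %in% dup_cases, caseversion] == 2L))
})

test_that("target-drug matching normalizes names and honours role filter", {
  db <- make_db(3, drug = data.table(
    primaryid = c(11L, 21L, 31L),
    drug_seq = 1L,
    drugname = c("NERLYNX", "  neratinib ", "Neratinib"),
    role_cod = c("PS", "PS", "SS")))
  syn <- neratinib_synonyms()
  expect_identical(match_target_drug(db, syn), c(11L, 21L))
  expect_identical(match_target_drug(db, syn, roles = c("PS", "SS")),
                   c(11L, 21L, 31L))
  expect_error(drug_synonyms("x", character()), "empty synonym list")
})

test_that("drug_event_pairs collapses within-report repeats", {
  db <- make_db(2, reac = data.table(
    primaryid = c(11L, 11L, 11L, 21L, 21L, 21L),
    pt = c("diarrhoea", "diarrhoea", "nausea", "a", "b", "c")))
  pairs <- drug_event_pairs(db)
  expect_identical(nrow(pairs), 5L)  # repeated diarrhoea collapsed
  expect_identical(nrow(pairs[primaryid == 21L]), 3L)
  expect_identical(nrow(drug_event_pairs(db, ids = integer())), 0L)
  expect_error(drug_event_pairs(db, ids = 999L), "not present")
  ## report year derived from receipt date
  expect_true(all(pairs$year == 2018L))
})
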