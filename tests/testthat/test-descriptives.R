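## fixture mirroring the published profile of 1,544 neratinib reports:
## 1,321 US / 51 Argentina / 172 elsewhere; serious outcomes
## HO 315, DE 191, LT 10, DS 4, RI 1, OT 324 (845 serious reports).
make_profile_db <- function() {
  n <- 1544L
  country <- c(rep("United States", 1321), rep("Argentina", 51),
               rep(c("China", "Japan", "Germany", "France"), length.out = 172))
  codes <- c(rep("HO", 315), rep("DE", 191), rep("LT", 10),
             rep("DS", 4), rep("RI", 1), rep("OT", 324))
  ids <- seq_len(n) * 10L + 1L
  make_db(n, demo = list(reporter_country = country),
          outc = data.table(primaryid = ids[seq_along(codes)],
                            outc_cod = codes))
}

test_that("percentages recompute exactly from the published counts", {
  db <- make_profile_db()
  s <- summarize_reports(db, db$demo$primaryid)
  expect_identical(attr(s$year, "denominator"), 1544L)
  expect_identical(s$country[category == "United States", n], 1321L)
  expect_identical(s$country[category == "United States", pct], 85.56)
  ## outcome denominator is reports with a serious outcome (845), not 1,544
  expect_identical(attr(s$outcome, "denominator"), 845L)
  expect_identical(s$outcome[category == "Hospitalization", pct], 37.28)
  expect_identical(s$outcome[category == "Death", pct], 22.60)
  expect_identical(s$outcome[category == "Other serious", pct], 38.34)
})

test_that("blocks sum to their denominators and percentages round-trip", {
  out <- small_sim()
  db <- deduplicate(out$db)
  ids <- match_target_drug(db, neratinib_synonyms())
  s <- summarize_reports(db, ids)
  for (blk in names(s)) {
    tab <- s[[blk]]
    denom <- attr(tab, "denominator")
    expect_identical(sum(tab$n), denom)
    expect_true(all(abs(tab$pct - 100 * tab$n / denom) <= 0.01))
  }
  ## year/sex/age/reporter/country blocks count every target report once
  for (blk in c("year", "sex", "age", "reporter", "country", "tto"))
    expect_identical(attr(s[[blk]], "denominator"), length(ids))
})

test_that("fully missing fields give 100% unknown blocks", {
  db <- make_db(5)
  s <- summarize_reports(db, db$demo$primaryid)
  for (blk in c("sex", "age", "reporter"))
    expect_identical(s[[blk]][category == "Unknown", pct], 100)
  expect_identical(s$tto[category == "Unknown", pct], 100)
})

test_that("a report's most severe outcome wins (DE > LT > HO > ...)", {
  db <- make_db(2, outc = data.table(primaryid = c(11L, 11L, 21L, 21L),
                                     outc_cod = c("HO", "DE", "OT", "LT")))
  s <- summarize_reports(db, db$demo$primaryid)
  expect_identical(attr(s$outcome, "denominator"), 2L)
  expect_identical(s$outcome[category == "Death", n], 1L)
  expect_identical(s$outcome[category == "Life threatening", n], 1L)
  expect_identical(sum(s$outcome$n), 2L)
})

test_that("time to onset uses half-open bins and flags unresolvable dates", {
  db <- make_db(5,
    demo = list(event_dt = c(20180105L, 20180108L, 20180101L,
                             20180401L, 201801L)),
    ther = data.table(primaryid = c(11L, 21L, 31L, 41L, 51L),
                      drug_seq = 1L,
                      start_dt = c(20180101L, 20180101L, 20180115L,
                                   201803L, 20180101L)))
  tto <- time_to_onset(db, db$demo$primaryid)
  setkey(tto, primaryid)
  expect_identical(tto[J(11L), days], 4L)
  expect_identical(tto[J(11L), bin], "<7")
  expect_identical(tto[J(21L), days], 7L)        # boundary: exactly 7
  expect_identical(tto[J(21L), bin], "7-28")
  expect_identical(tto[J(31L), bin], "Unknown")  # event before start
  expect_identical(tto[J(41L), bin], "Unknown")  # imprecise start date
  expect_identical(tto[J(51L), bin], "Unknown")  # imprecise event date
})
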