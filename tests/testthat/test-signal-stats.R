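test_that("build_tables enumerates 2x2 cells and conserves margins", {
  tgt <- data.table(primaryid = c(1L, 1L, 2L), pt = c("x", "y", "x"))
  all_ <- rbind(tgt, data.table(primaryid = c(3L, 3L), pt = c("x", "z")))
  tabs <- build_tables(tgt, all_)
  x <- tabs[term == "x"]
  expect_identical(unlist(x[, .(a, b, c_, d_)]),
                   c(a = 2L, b = 1L, c_ = 1L, d_ = 1L))
  ## conservation: sum of a equals total target pairs; a+b constant
  expect_identical(sum(tabs$a), nrow(tgt))
  expect_identical(unique(tabs$a + tabs$b), nrow(tgt))
  expect_error(build_tables(tgt, tgt[0]), "empty pairs_all")
  expect_error(build_tables(all_, tgt), "not contained")
})

test_that("closed-form values of the four statistics", {
  ## symmetric table
  expect_equal(ror_stat(10, 10, 10, 10)$ror, 1.0)
  ## ror = ad/bc
  expect_equal(ror_stat(3, 7, 30, 700)$ror, 10.0)
  ## independence: a/e = 1 for all statistics
  ind <- c(a = 1, b = 9, c = 99, d = 891)
  expect_equal(prr_stat(ind["a"], ind["b"], ind["c"], ind["d"])$prr,
               1.0, ignore_attr = TRUE)
  expect_equal(prr_stat(ind["a"], ind["b"], ind["c"], ind["d"])$chisq,
               0.0, ignore_attr = TRUE)
  expect_equal(bcpnn_stat(ind["a"], ind["b"], ind["c"], ind["d"])$ic,
               0.0, ignore_attr = TRUE)
  expect_equal(ebgm_stat(ind["a"], ind["b"], ind["c"], ind["d"])$ebgm,
               1.0, ignore_attr = TRUE)
  ## Yates correction shrinks the chi-square
  t2 <- list(a = 20, b = 80, c = 100, d = 900)
  expect_lt(prr_stat(t2$a, t2$b, t2$c, t2$d, yates = TRUE)$chisq,
            prr_stat(t2$a, t2$b, t2$c, t2$d)$chisq)
})

test_that("zero cells yield undefined markers, never flags", {
  r <- ror_stat(5, 0, 3, 10)
  expect_true(is.na(r$ror))
  p <- prr_stat(5, 5, 0, 10)
  expect_true(is.na(p$prr))
  b <- bcpnn_stat(0, 10, 5, 100)
  expect_identical(b$ic, -Inf)
  expect_true(is.finite(b$ic025) == FALSE)
  tab <- data.table(term = "t", a = 5L, b = 0L, c_ = 3L, d_ = 10L)
  res <- disproportionality(tab)
  expect_false(res$ror_pos); expect_false(res$consensus)
})

test_that("signal criteria: min_a gate and four-way AND", {
  mk <- function(a, b, c, d) data.table(term = "t", a = a, b = b,
                                        c_ = c, d_ = d)
  ## huge ror but a = 2 -> all false
  res <- disproportionality(mk(2, 10, 1, 10000))
  expect_false(any(res$ror_pos, res$prr_pos, res$bcpnn_pos, res$ebgm_pos,
                   res$consensus))
  ## clear signal flags everywhere
  res <- disproportionality(mk(50, 100, 100, 100000))
  expect_true(res$consensus)
  ## one failing algorithm kills the consensus
  res[, ic025 := -0.1]
  res2 <- evaluate_signals(res)
  expect_true(res2$ror_pos && res2$prr_pos && res2$ebgm_pos)
  expect_false(res2$bcpnn_pos)
  expect_false(res2$consensus)
  expect_error(signal_criteria(min_a = 0), "min_a")
  expect_error(signal_criteria(prr_ge = Inf), "finite")
})

test_that("ic equals log2(ebgm); positive associations order ror >= prr >= ebgm", {
  ## each consecutive ratio of the chain differs from 1 with the sign of
  ## ad - bc, so the ordering characterizes positively associated tables
  ## (the regime of every published signal row)
  set.seed(1)
  for (i in 1:200) {
    N <- sample(5000:50000, 1)
    ab <- sample(10:(N %/% 100), 1)      # a+b << N
    a <- sample(1:ab, 1); b <- ab - a
    cc <- sample(1:(N %/% 10), 1)
    d <- N - ab - cc
    if (b < 1 || d < 1) next
    ic <- bcpnn_stat(a, b, cc, d)$ic
    eb <- ebgm_stat(a, b, cc, d)$ebgm
    expect_equal(ic, log2(eb), tolerance = 1e-9)
    ror <- ror_stat(a, b, cc, d)$ror
    prr <- prr_stat(a, b, cc, d)$prr
    if (a * d >= b * cc) {
      expect_gte(ror, prr * (1 - 1e-12))
      expect_gte(prr, eb * (1 - 1e-12))
    } else {
      expect_lte(ror, prr * (1 + 1e-12))
      expect_lte(prr, eb * (1 + 1e-12))
    }
  }
})

test_that("point estimates increase strictly in a (screening regime)", {
  set.seed(2)
  for (i in 1:100) {
    b <- sample(500:5000, 1); cc <- sample(5000:50000, 1)
    d <- sample(1e5:1e6, 1)
    a1 <- sample(1:50, 1); a2 <- a1 + sample(1:20, 1)
    s1 <- c(ror_stat(a1, b, cc, d)$ror, prr_stat(a1, b, cc, d)$prr,
            bcpnn_stat(a1, b, cc, d)$ic, ebgm_stat(a1, b, cc, d)$ebgm)
    s2 <- c(ror_stat(a2, b, cc, d)$ror, prr_stat(a2, b, cc, d)$prr,
            bcpnn_stat(a2, b, cc, d)$ic, ebgm_stat(a2, b, cc, d)$ebgm)
    expect_true(all(s2 > s1))
  }
})

test_that("interval estimates bracket their point estimates", {
  set.seed(3)
  a <- sample(1:100, 50, TRUE); b <- sample(1:1000, 50, TRUE)
  cc <- sample(1:1000, 50, TRUE); d <- sample(1000:1e6, 50, TRUE)
  r <- ror_stat(a, b, cc, d); p <- prr_stat(a, b, cc, d)
  bc <- bcpnn_stat(a, b, cc, d); e <- ebgm_stat(a, b, cc, d)
  expect_true(all(r$ror_lo <= r$ror & r$ror <= r$ror_hi))
  expect_true(all(p$prr_lo <= p$prr & p$prr <= p$prr_hi))
  expect_true(all(bc$ic025 <= bc$ic & bc$ic <= bc$ic975))
  expect_true(all(e$ebgm05 <= e$ebgm))
})

test_that("ranking orders by ic025, then a, then term", {
  res <- data.table(term = c("b", "a", "c", "d"),
                    ic025 = c(2, 2, 3, NA), a = c(5L, 5L, 1L, 99L))
  ranked <- rank_by_ic025(res)
  expect_identical(ranked$term, c("c", "a", "b", "d"))
  expect_identical(nrow(rank_by_ic025(res, top_k = 2)), 2L)
})
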