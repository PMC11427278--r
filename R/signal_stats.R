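## 2x2 contingency tables and the four disproportionality statistics.
##
## Counting unit is the distinct report-PT (or report-SOC) PAIR. For a term
## t and a target drug:
##   a = target-drug pairs with t        b = target-drug pairs with other terms
##   c = other-drug pairs with t         d = other-drug pairs with other terms
## so a+b is constant across terms at a given level and N = a+b+c+d is the
## total number of pairs in the database.
##
## Adopted formulas (z = 1.96 two-sided, z = 1.64 one-sided 5%):
##   ROR  = ad/bc,      CI = exp(ln ROR -/+ 1.96 sqrt(1/a+1/b+1/c+1/d))
##   PRR  = [a/(a+b)]/[c/(c+d)],
##          CI = exp(ln PRR -/+ 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))
##   chi2 = Pearson (uncorrected), (ad-bc)^2 N / [(a+b)(c+d)(a+c)(b+d)]
##   IC   = log2(aN / ((a+b)(a+c)))   (log2 of the relative reporting ratio)
##   V_IC = (1/ln2)^2 [1/(a+1) + 1/(a+b+1) + 1/(a+c+1)]  (large-N
##          approximation of the BCPNN posterior variance)
##   IC025/IC975 = IC -/+ 1.96 sqrt(V_IC)
##   EBGM  = aN / ((a+b)(a+c))  (the unshrunken observed/expected ratio)
##   EBGM05 = exp(ln EBGM - 1.64 sqrt(1/a+1/b+1/c+1/d))
## Statistics with a zero cell in their denominator are returned as NA
## (undefined markers), never corrected; undefined statistics never flag.

#' Build 2x2 contingency tables per term
#'
#' @param pairs_target distinct (report, term) pairs of the target drug's
#'   reports, columns `primaryid`, term column.
#' @param pairs_all distinct (report, term) pairs of the whole database
#'   (must contain `pairs_target`).
#' @param term_col name of the term column (default `"pt"`).
#' @return `data.table` with one row per term occurring in `pairs_target`:
#'   `term`, `a`, `b`, `c_`, `d_`, `n_total`. (`c`/`d` carry a trailing
#'   underscore to avoid masking `base::c`.)
#' @examples
#' tgt <- data.table::data.table(primaryid = c(1, 1, 2),
#'                               pt = c("x", "y", "x"))
#' all <- rbind(tgt, data.table::data.table(primaryid = c(3, 3),
#'                                          pt = c("x", "z")))
#' build_tables(tgt, all)  # x: a=2 b=1 c=1 d=1
#' @export
build_tables <- function(pairs_target, pairs_all, term_col = "pt") {
  stopifnot(term_col %in% names(pairs_target), term_col %in% names(pairs_all))
  if (nrow(pairs_all) == 0L) stop("empty pairs_all")
  tgt <- unique(as.data.table(pairs_target)[, c("primaryid", term_col),
                                            with = FALSE])
  all_ <- unique(as.data.table(pairs_all)[, c("primaryid", term_col),
                                          with = FALSE])
  setnames(tgt, term_col, "term")
  setnames(all_, term_col, "term")
  n_target <- nrow(tgt)
  n_total <- nrow(all_)
  a_tab <- tgt[, .(a = .N), by = term]
  all_tab <- all_[, .(n_all = .N), by = term]
  out <- merge(a_tab, all_tab, by = "term", all.x = TRUE)
  out[, b := n_target - a]
  out[, c_ := n_all - a]
  out[, d_ := n_total - n_target - c_]
  out[, n_all := NULL]
  out[, n_total := n_total]
  if (any(out$c_ < 0) || any(out$d_ < 0))
    stop("pairs_target is not contained in pairs_all")
  setorder(out, -a, term)
  out[]
}

#' Reporting odds ratio with log-normal 95% CI
#'
#' @param a,b,c,d vectors of 2x2 cell counts.
#' @return `data.table` with `ror`, `ror_lo`, `ror_hi`; `NA` where
#'   `b*c == 0` (undefined) or `a == 0`.
#' @export
ror_stat <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  point <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  data.table(ror = point,
             ror_lo = exp(log(point) - 1.96 * se),
             ror_hi = exp(log(point) + 1.96 * se))
}

#' Proportional reporting ratio with 95% CI and Pearson chi-square
#'
#' @inheritParams ror_stat
#' @param yates apply the Yates continuity correction to the chi-square
#'   (default `FALSE`, plain Pearson).
#' @return `data.table` with `prr`, `prr_lo`, `prr_hi`, `chisq`.
#' @export
prr_stat <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  ok <- a > 0 & c > 0 & (a + b) > 0 & (c + d) > 0
  point <- ifelse(ok, (a / (a + b)) / (c / (c + d)), NA_real_)
  se <- ifelse(ok, sqrt(pmax(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d), 0)),
               NA_real_)
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(dev - N / 2, 0)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chisq <- ifelse(denom > 0, dev^2 * N / denom, NA_real_)
  data.table(prr = point,
             prr_lo = exp(log(point) - 1.96 * se),
             prr_hi = exp(log(point) + 1.96 * se),
             chisq = chisq)
}

#' BCPNN information component with 95% credibility bounds
#'
#' IC is the log2 observed/expected reporting ratio; its variance uses the
#' large-N approximation of the BCPNN posterior (the `+1` terms keep the
#' bounds finite at small `a`). `a == 0` yields `ic = -Inf`.
#'
#' @inheritParams ror_stat
#' @return `data.table` with `ic`, `ic025`, `ic975`.
#' @export
bcpnn_stat <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  e <- (a + b) * (a + c) / N
  ic <- ifelse(N > 0 & (a + b) > 0 & (a + c) > 0, log2(a / e), NA_real_)
  v <- (1 / log(2))^2 * (1 / (a + 1) + 1 / (a + b + 1) + 1 / (a + c + 1))
  hw <- 1.96 * sqrt(v)
  data.table(ic = ic, ic025 = ic - hw, ic975 = ic + hw)
}

#' Empirical Bayes geometric mean (unshrunken) with one-sided 5% bound
#'
#' The point estimate is the relative reporting ratio `aN/((a+b)(a+c))`;
#' the lower bound uses `z = 1.64` on the log scale.
#'
#' @inheritParams ror_stat
#' @return `data.table` with `ebgm`, `ebgm05`.
#' @export
ebgm_stat <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  ok <- a > 0 & (a + b) > 0 & (a + c) > 0 & b > 0 & c > 0 & d > 0
  point <- ifelse((a + b) > 0 & (a + c) > 0 & a > 0,
                  a * N / ((a + b) * (a + c)), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  data.table(ebgm = point, ebgm05 = exp(log(point) - 1.64 * se))
}

#' Positivity thresholds for the four algorithms
#'
#' Defaults are the field-standard set: at least 3 target pairs; ROR lower
#' 95% bound > 1; PRR >= 2 with chi-square >= 4; IC025 > 0; EBGM05 > 2.
#' A term is a consensus signal when it meets all four simultaneously.
#'
#' @param min_a minimum `a` below which no algorithm may flag.
#' @param ror_lo_gt ROR lower-bound threshold (exclusive).
#' @param prr_ge,chisq_ge PRR and chi-square thresholds (inclusive).
#' @param ic025_gt IC025 threshold (exclusive).
#' @param ebgm05_gt EBGM05 threshold (exclusive).
#' @return object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_a = 3, ror_lo_gt = 1, prr_ge = 2,
                            chisq_ge = 4, ic025_gt = 0, ebgm05_gt = 2) {
  vals <- c(min_a, ror_lo_gt, prr_ge, chisq_ge, ic025_gt, ebgm05_gt)
  if (any(!is.finite(vals))) stop("thresholds must be finite")
  if (min_a < 1) stop("min_a must be >= 1")
  structure(list(min_a = min_a, ror_lo_gt = ror_lo_gt, prr_ge = prr_ge,
                 chisq_ge = chisq_ge, ic025_gt = ic025_gt,
                 ebgm05_gt = ebgm05_gt),
            class = "signal_criteria")
}

#' Compute all four disproportionality statistics with signal flags
#'
#' @param tables `data.table` from [build_tables()] (columns `term`, `a`,
#'   `b`, `c_`, `d_`), or any table with those columns.
#' @param criteria a [signal_criteria()].
#' @param level label stored in the `level` column (`"PT"` or `"SOC"`).
#' @param yates passed to [prr_stat()].
#' @return `data.table`: term, level, counts, all statistics, per-algorithm
#'   logical flags (`ror_pos`, `prr_pos`, `bcpnn_pos`, `ebgm_pos`) and
#'   `consensus` (their AND). Undefined (NA) statistics never flag;
#'   `a < min_a` forces all flags false.
#' @export
disproportionality <- function(tables, criteria = signal_criteria(),
                               level = "PT", yates = FALSE) {
  stopifnot(inherits(criteria, "signal_criteria"))
  t <- as.data.table(tables)
  stopifnot(all(c("term", "a", "b", "c_", "d_") %in% names(t)))
  res <- cbind(
    t[, .(term, level = level, a, b, c_, d_)],
    ror_stat(t$a, t$b, t$c_, t$d_),
    prr_stat(t$a, t$b, t$c_, t$d_, yates = yates),
    bcpnn_stat(t$a, t$b, t$c_, t$d_),
    ebgm_stat(t$a, t$b, t$c_, t$d_))
  evaluate_signals(res, criteria)
}

#' Apply the per-algorithm and consensus signal rules
#'
#' @param res a results `data.table` holding at least `a`, `ror_lo`, `prr`,
#'   `chisq`, `ic025`, `ebgm05`.
#' @param criteria a [signal_criteria()].
#' @return `res` with flag columns added (replacing any present).
#' @export
evaluate_signals <- function(res, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  res <- as.data.table(res)
  flag <- function(x) !is.na(x) & x  # undefined -> FALSE
  enough <- res$a >= criteria$min_a
  res[, `:=`(
    ror_pos   = flag(ror_lo > criteria$ror_lo_gt) & enough,
    prr_pos   = flag(prr >= criteria$prr_ge & chisq >= criteria$chisq_ge) & enough,
    bcpnn_pos = flag(ic025 > criteria$ic025_gt) & enough,
    ebgm_pos  = flag(ebgm05 > criteria$ebgm05_gt) & enough)]
  res[, consensus := ror_pos & prr_pos & bcpnn_pos & ebgm_pos]
  res[]
}

#' Rank results by signal intensity
#'
#' Orders by IC025 descending, ties by `a` descending, then term.
#'
#' @param res results from [disproportionality()].
#' @param top_k optionally keep only the strongest `top_k` terms.
#' @return reordered `data.table`.
#' @export
rank_by_ic025 <- function(res, top_k = NULL) {
  res <- as.data.table(res)
  setorder(res, -ic025, -a, term, na.last = TRUE)
  if (!is.null(top_k)) res <- utils::head(res, top_k)
  res[]
}
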