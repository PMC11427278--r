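## Information-component trajectories over calendar time: for each year the
## 2x2 table is rebuilt from all pairs accumulated up to that year and the
## BCPNN IC with 95% credibility bounds is recomputed. As data accumulate
## the credibility interval narrows; a year is flagged when 0 is excluded
## from below (IC025 > 0).

#' IC trajectory of one term over calendar years
#'
#' @param pairs_all distinct (report, term) pairs of the whole database,
#'   with a `year` column (as produced by [drug_event_pairs()]).
#' @param pairs_target the target drug's pairs, same layout.
#' @param term the term to scan.
#' @param years integer years to evaluate; default all years present.
#' @param term_col name of the term column (default `"pt"`).
#' @param cumulative if `TRUE` (default) year `y` uses all pairs with
#'   report year `<= y`; if `FALSE`, only pairs of year `y`.
#' @return `data.table` of class `ic_trajectory`: `term`, `year`, `a`,
#'   `ic`, `ic025`, `ic975`, `flagged`. Years where the term is absent
#'   carry `a = 0` and undefined (NA/-Inf) statistics, never a flag.
#' @export
ic_over_time <- function(pairs_all, pairs_target, term, years = NULL,
                         term_col = "pt", cumulative = TRUE) {
  pa <- as.data.table(pairs_all)
  pt_ <- as.data.table(pairs_target)
  stopifnot("year" %in% names(pa), "year" %in% names(pt_))
  if (is.null(years))
    years <- sort(unique(stats::na.omit(pa$year)))
  years <- sort(as.integer(years))
  one_year <- function(y) {
    sel <- if (cumulative) quote(year <= y) else quote(year == y)
    all_y <- pa[eval(sel)]
    tgt_y <- pt_[eval(sel)]
    n_total <- nrow(all_y)
    n_target <- nrow(tgt_y)
    a <- sum(tgt_y[[term_col]] == term, na.rm = TRUE)
    c_ <- sum(all_y[[term_col]] == term, na.rm = TRUE) - a
    b <- n_target - a
    d_ <- n_total - a - b - c_
    if (n_total == 0L)
      return(data.table(term = term, year = y, a = 0L, ic = NA_real_,
                        ic025 = NA_real_, ic975 = NA_real_, flagged = FALSE))
    s <- bcpnn_stat(a, b, c_, d_)
    data.table(term = term, year = y, a = a, ic = s$ic, ic025 = s$ic025,
               ic975 = s$ic975,
               flagged = !is.na(s$ic025) & is.finite(s$ic025) & s$ic025 > 0)
  }
  out <- rbindlist(lapply(years, one_year))
  class(out) <- c("ic_trajectory", class(out))
  out[]
}

#' Plot IC trajectories
#'
#' One panel per term: IC with its 95% credibility band and a horizontal
#' reference at 0. Requires ggplot2.
#'
#' @param x one or more row-bound [ic_over_time()] results.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_ic_trajectory <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ic_trajectory requires ggplot2")
  dt <- as.data.table(x)[is.finite(ic)]
  ggplot2::ggplot(dt, ggplot2::aes(x = year, y = ic)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ic025, ymax = ic975),
                           width = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~term) +
    ggplot2::labs(x = "year", y = "information component (bits)")
}
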