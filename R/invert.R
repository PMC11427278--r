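## Numeric inversion oracle: reconstruct the unobserved background cells
## (c, d) of a 2x2 table from the published PRR and Pearson chi-square,
## given the target-drug margin (a, b). Used to validate formula choices
## against published statistics when the underlying database is not
## redistributable.
##
## With q = (a/(a+b))/PRR (= c/(c+d)) fixed by the PRR equation, the
## chi-square is an increasing function of the background scale s = c + d
## that saturates at the supremum (a - (a+b) q)^2 / ((a+b) q (1-q)) as
## s -> Inf. A published chi-square can exceed that supremum by printed
## rounding alone; within a small tolerance the oracle then returns a
## boundary solution at a large finite scale, where all derived statistics
## have converged to their large-background limits.

#' Reconstruct background cells from published PRR and chi-square
#'
#' Solves for real `c, d > 0` such that `PRR(a,b,c,d) = prr_target` and the
#' uncorrected Pearson chi-square equals `chisq_target`.
#'
#' @param a,b target-drug cells (pairs with / without the term).
#' @param prr_target,chisq_target published values.
#' @param max_scale upper bound on the background scale `c + d` searched.
#' @param boundary_tol if no root exists but the target chi-square is
#'   within this relative distance of its supremum (a printed-rounding
#'   artifact), return the boundary solution at `max_scale` with
#'   `boundary = TRUE` instead of erroring.
#' @return list with `c`, `d`, `n` (implied database size `a+b+c+d`),
#'   `boundary`, and forward-check relative errors `prr_rel_err`,
#'   `chisq_rel_err`.
#' @examples
#' r <- invert_table(991, 5497, prr_target = 13.64, chisq_target = 11703.35)
#' r$n  # implied background size ~ 2.8e7
#' @export
invert_table <- function(a, b, prr_target, chisq_target,
                         max_scale = 1e12, boundary_tol = 0.005) {
  if (a < 1 || b < 1) stop("need a >= 1 and b >= 1")
  if (!is.finite(prr_target) || prr_target <= 0)
    stop("PRR equation unsolvable: prr_target must be positive")
  if (!is.finite(chisq_target) || chisq_target <= 0)
    stop("chi-square equation unsolvable: chisq_target must be positive",
         " (prr = 1, chisq = 0 is unidentifiable)")
  q <- (a / (a + b)) / prr_target
  if (q >= 1)
    stop("PRR equation unsolvable: prr_target below the target margin ",
         "a/(a+b) implies c/(c+d) >= 1")
  chisq_of <- function(s) {
    cc <- q * s; dd <- (1 - q) * s
    N <- a + b + s
    (a * dd - b * cc)^2 * N / ((a + b) * s * (a + cc) * (b + dd))
  }
  f <- function(logs) chisq_of(exp(logs)) - chisq_target
  lo <- log(1e-9); hi <- log(max_scale)
  boundary <- FALSE
  if (f(lo) > 0)
    stop("chi-square equation unsolvable: target below attainable range")
  if (f(hi) < 0) {
    sup <- (a - (a + b) * q)^2 / ((a + b) * q * (1 - q))
    if (chisq_target <= sup * (1 + boundary_tol)) {
      s <- max_scale
      boundary <- TRUE
    } else {
      stop("chi-square equation unsolvable: target ", chisq_target,
           " exceeds the supremum ", signif(sup, 6),
           " attainable under the PRR constraint")
    }
  } else {
    s <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-13)$root)
  }
  cc <- q * s; dd <- (1 - q) * s
  fwd <- prr_stat(a, b, cc, dd)
  list(c = cc, d = dd, n = a + b + cc + dd, boundary = boundary,
       prr_rel_err = abs(fwd$prr - prr_target) / prr_target,
       chisq_rel_err = abs(fwd$chisq - chisq_target) / chisq_target)
}

#' Forward statistics from a published row via inversion
#'
#' Reconstructs the 2x2 table for one published (a, PRR, chi-square) row
#' (with `b` = event margin minus `a`) and recomputes all four statistics
#' with the package's formulas.
#'
#' @param a published case-report count for the term.
#' @param prr,chisq published PRR point estimate and chi-square.
#' @param event_total the target drug's total pair margin `a + b`.
#' @param ... passed to [invert_table()].
#' @return one-row `data.table` with the reconstructed cells, implied `n`,
#'   `boundary` flag and all recomputed statistics.
#' @export
reconstruct_stats <- function(a, prr, chisq, event_total, ...) {
  b <- event_total - a
  inv <- invert_table(a, b, prr, chisq, ...)
  cbind(data.table(a = a, b = b, c_ = inv$c, d_ = inv$d, n_implied = inv$n,
                   boundary = inv$boundary),
        ror_stat(a, b, inv$c, inv$d),
        prr_stat(a, b, inv$c, inv$d),
        bcpnn_stat(a, b, inv$c, inv$d),
        ebgm_stat(a, b, inv$c, inv$d))
}

#' Implied background size with printed-rounding conditioning interval
#'
#' For each published row, inverts at the printed (PRR, chi-square) center
#' and at the corners of their half-ulp rounding box; the relative width of
#' the resulting implied-N interval measures how well the background size
#' is identified. Rows whose chi-square sits near its supremum are
#' ill-conditioned (tiny printed rounding moves N by orders of magnitude)
#' and should be excluded from consistency checks.
#'
#' @param rows `data.table` with columns `term`, `a`, `prr`, `chisq` (as
#'   printed; trailing precision is inferred from the printed strings).
#' @param event_total the target margin `a + b`.
#' @return `data.table` with `term`, `a`, `n_implied`, `n_lo`, `n_hi`,
#'   `rel_width` (NA where any corner is infeasible or the center is a
#'   boundary solution).
#' @export
implied_background_size <- function(rows, event_total) {
  rows <- as.data.table(rows)
  half_ulp <- function(x) {
    s <- format(x, trim = TRUE, scientific = FALSE)
    dec <- ifelse(grepl("\\.", s), nchar(sub(".*\\.", "", s)), 0L)
    0.5 * 10^(-dec)
  }
  one <- function(a, p, x) {
    centre <- tryCatch(invert_table(a, event_total - a, p, x),
                       error = function(e) NULL)
    n0 <- if (is.null(centre) || centre$boundary) NA_real_ else centre$n
    hp <- half_ulp(p); hx <- half_ulp(x)
    corners <- expand.grid(p = c(p - hp, p + hp), x = c(x - hx, x + hx))
    ns <- mapply(function(pp, xx) {
      r <- tryCatch(invert_table(a, event_total - a, pp, xx),
                    error = function(e) NULL)
      if (is.null(r) || r$boundary) NA_real_ else r$n
    }, corners$p, corners$x)
    if (is.na(n0) || anyNA(ns))
      data.table(n_implied = n0, n_lo = NA_real_, n_hi = NA_real_,
                 rel_width = NA_real_)
    else
      data.table(n_implied = n0, n_lo = min(ns), n_hi = max(ns),
                 rel_width = (max(ns) - min(ns)) / n0)
  }
  cbind(rows[, .(term, a)],
        rbindlist(Map(one, rows$a, rows$prr, rows$chisq)))
}

## ---- shipped reference statistics (neratinib, FAERS 2017Q3-2023Q4) -------

#' Reference disproportionality statistics for neratinib
#'
#' The published PT-level (48 rows) and SOC-level (22 rows) signal tables
#' for neratinib as primary suspect in FAERS 2017Q3-2023Q4, and the
#' published descriptive profile of the 1,544 reports. These are the
#' validation inputs for the inversion oracle; the package never uses them
#' as computation results.
#'
#' @return `data.table` of the shipped reference table. For
#'   `reference_pt_stats()` the column `on_label` marks PTs documented in
#'   the drug's label (the complement are the "new signal" PTs).
#' @export
reference_pt_stats <- function() {
  fread(fs_extdata("reference_pt_stats.tsv"), sep = "\t", header = TRUE)
}

#' @rdname reference_pt_stats
#' @export
reference_soc_stats <- function() {
  fread(fs_extdata("reference_soc_stats.tsv"), sep = "\t", header = TRUE)
}

#' @rdname reference_pt_stats
#' @export
reference_descriptives <- function() {
  fread(fs_extdata("reference_descriptives.tsv"), sep = "\t", header = TRUE)
}

#' PTs documented in the neratinib label (shipped default list)
#' @return character vector of on-label PTs.
#' @export
neratinib_label_pts <- function() {
  fread(fs_extdata("neratinib_label_pts.tsv"), sep = "\t", header = TRUE)$pt
}
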