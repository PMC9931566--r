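#' G-test (log-likelihood ratio test) of independence
#'
#' G = 2 * sum O * ln(O/E) over cells with O > 0 (zero cells contribute 0,
#' the x*ln(x) -> 0 limit), with expected counts from the row/column
#' margins and df = (r-1)(c-1). No continuity or Williams correction is
#' applied. G is chi-square distributed under independence and is exactly
#' linear in the counts at fixed proportions. All-zero rows and columns
#' are dropped before testing.
#'
#' @param x 2-D non-negative count matrix (at least 2x2 after dropping
#'   all-zero rows/columns).
#' @return an object of class `htest` with the G statistic, df, and the
#'   chi-square upper-tail p-value.
#' @export
g_test <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0) || any(is.na(x))) {
    stop("g_test: counts must be non-negative and non-missing", call. = FALSE)
  }
  dn <- deparse(substitute(x))
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("g_test: need at least a 2x2 table after dropping all-zero rows/columns",
         call. = FALSE)
  }
  n <- sum(x)
  E <- outer(rowSums(x), colSums(x)) / n
  pos <- x > 0
  G <- 2 * sum(x[pos] * log(x[pos] / E[pos]))
  df <- (nrow(x) - 1) * (ncol(x) - 1)
  structure(list(statistic = c(G = G),
                 parameter = c(df = df),
                 p.value = pchisq(G, df, lower.tail = FALSE),
                 method = "G-test of independence",
                 data.name = dn),
            class = "htest")
}

#' Post hoc per-category comparison of two cohorts
#'
#' For each category, tests cohort membership against in/out of the
#' category with a 2x2 [g_test()], Bonferroni-adjusting p-values across
#' the categories of the variable. Categories with zero counts in both
#' cohorts are skipped with a warning. Tests run on raw counts;
#' disclosure-shifted counts are for display only.
#'
#' @param counts_a,counts_b named integer vectors of per-category counts
#'   for the two cohorts; names must match.
#' @return data.frame with columns `category`, `n_a`, `pct_a`, `n_b`,
#'   `pct_b`, `G`, `df`, `p`, `p_adj`.
#' @export
posthoc_compare <- function(counts_a, counts_b) {
  if (!setequal(names(counts_a), names(counts_b))) {
    stop("category structures differ between the two tables", call. = FALSE)
  }
  counts_b <- counts_b[names(counts_a)]
  tot_a <- sum(counts_a)
  tot_b <- sum(counts_b)
  keep <- counts_a + counts_b > 0
  if (any(!keep)) {
    warning(sprintf("categories with zero counts in both cohorts skipped: %s",
                    paste(names(counts_a)[!keep], collapse = ", ")))
  }
  cats <- names(counts_a)[keep]
  rows <- lapply(cats, function(cat) {
    tab <- rbind(a = c(counts_a[[cat]], tot_a - counts_a[[cat]]),
                 b = c(counts_b[[cat]], tot_b - counts_b[[cat]]))
    if ((counts_a[[cat]] + counts_b[[cat]]) %in% c(0, tot_a + tot_b)) {
      g <- NA_real_; df <- NA_real_; p <- NA_real_
    } else {
      ht <- g_test(tab)
      g <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
    }
    data.frame(category = cat,
               n_a = counts_a[[cat]], pct_a = pct(counts_a[[cat]], tot_a),
               n_b = counts_b[[cat]], pct_b = pct(counts_b[[cat]], tot_b),
               G = g, df = df, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * length(cats))
  out
}
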