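#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items:
#' 1 for identical partitions (up to relabelling), about 0 for independent
#' ones, and possibly negative for partitions that agree less than chance.
#'
#' @param a,b community label vectors of equal length (any atomic type);
#'   if both are named, `b` is aligned to `a`'s names first.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("named partitions cover different item sets", call. = FALSE)
    }
    b <- b[names(a)]
  }
  if (length(a) != length(b)) {
    stop("partitions must cover the same number of items", call. = FALSE)
  }
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_cells <- sum(choose2(tab))
  sum_rows <- sum(choose2(rowSums(tab)))
  sum_cols <- sum(choose2(colSums(tab)))
  n_pairs <- choose2(length(a))
  expected <- sum_rows * sum_cols / n_pairs
  denom <- (sum_rows + sum_cols) / 2 - expected
  if (abs(denom) < 1e-12) return(1)   # both partitions trivial and equal
  (sum_cells - expected) / denom
}
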