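#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves rounded up (away from zero
#' for positive input), the convention used for all printed percentages in
#' this package. Base [round()] rounds halves to even, which disagrees with
#' how clinical tables are typically typeset.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.25, 0.35), 1) # 0.3 0.4
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  # tiny epsilon guards halves that land just below .5 in binary
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

#' Percentage with one-decimal half-up rounding
#'
#' Returns `NA` (not 0) when the denominator is zero, so an undefined rate
#' is never displayed as an observed zero.
#'
#' @param count numerator count.
#' @param denom denominator count.
#' @param digits decimal places (default 1, matching printed tables).
#' @return numeric percentage in \[0, 100\] or `NA_real_`.
#' @export
pct <- function(count, denom, digits = 1) {
  out <- round_half_up(suppressWarnings(100 * count / denom), digits)
  out[rep_len(!is.na(denom) & denom == 0, length(out))] <- NA_real_
  out
}

# Polynomial rolling hash of a character scalar over the Mersenne prime
# 2^31 - 1; used for named RNG sub-streams and config fingerprints.
# Returns a non-negative double < 2^31 - 1.
str_hash <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

# Derive a deterministic child seed from (seed, stream name). Named
# sub-streams keep each generated table independent of how many draws the
# previous tables consumed, so adding a table never perturbs earlier ones.
substream_seed <- function(seed, name) {
  as.integer((as.double(seed) * 48271 + str_hash(name)) %% 2147483647)
}

# Evaluate `expr` under a named RNG sub-stream, restoring the caller's RNG
# state afterwards.
with_substream <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Parse ISO-8601 dates strictly; error names the offending rows.
parse_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad) > 0) {
    stop(sprintf("unparseable %s at row(s) %s (first value: '%s')",
                 what, paste(head(bad, 5), collapse = ", "), x[bad[1]]),
         call. = FALSE)
  }
  d
}

# Exactly-k selection: deterministic seeded choice of round(frac * n)
# indices out of n. Used by the generator so configured fractions hold
# exactly, which also satisfies "in expectation".
pick_exact <- function(n, frac) {
  k <- round(frac * n)
  flag <- rep(FALSE, n)
  if (k > 0) flag[sample.int(n, min(k, n))] <- TRUE
  flag
}

`%||%` <- function(a, b) if (is.null(a)) b else a
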