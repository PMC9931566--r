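#' Categorize an area-level SDoH variable into high/medium/low
#'
#' Cutpoints are percentiles (default tertiles, linear-interpolation
#' quantiles) of the variable across ALL areas in the reference table —
#' not just areas represented in a cohort — so a cohort's category mix is
#' interpretable against the full area distribution. The boundary rule is:
#' low strictly below the lower cutpoint, high strictly above the upper
#' cutpoint, medium in the closed interval between them (so a degenerate
#' distribution labels every area medium). Missing values label as
#' `"missing"`. Labels are invariant to rescaling the variable by any
#' positive constant.
#'
#' @param sdoh_table data.frame with a `zip` column and numeric variables.
#' @param variable name of the variable to categorize.
#' @param probs percentile pair for the cutpoints (default `c(1/3, 2/3)`).
#' @return an `sdoh_categorization`: list with `variable`, `cutpoints`,
#'   and `labels` (data.frame `zip`, `category`).
#' @export
categorize_sdoh <- function(sdoh_table, variable, probs = c(1/3, 2/3)) {
  if (!variable %in% names(sdoh_table)) {
    stop(sprintf("variable '%s' not present in SDoH table", variable),
         call. = FALSE)
  }
  x <- as.numeric(sdoh_table[[variable]])
  if (all(is.na(x))) {
    stop(sprintf("variable '%s' has no non-missing values", variable),
         call. = FALSE)
  }
  cut_lo <- quantile(x, probs[1], na.rm = TRUE, names = FALSE, type = 7)
  cut_hi <- quantile(x, probs[2], na.rm = TRUE, names = FALSE, type = 7)
  category <- ifelse(is.na(x), "missing",
                     ifelse(x < cut_lo, "low",
                            ifelse(x > cut_hi, "high", "medium")))
  structure(list(variable = variable,
                 cutpoints = c(lower = cut_lo, upper = cut_hi),
                 labels = data.frame(zip = as.character(sdoh_table$zip),
                                     category = category,
                                     stringsAsFactors = FALSE)),
            class = "sdoh_categorization")
}

#' Look up SDoH category labels for patient ZIP codes
#'
#' @param categorization an [categorize_sdoh()] result.
#' @param zips character vector of patient ZIP codes.
#' @return character vector of labels; ZIPs absent from the reference
#'   table (or `NA`) label as `"missing"`.
#' @export
lookup_sdoh <- function(categorization, zips) {
  lab <- categorization$labels
  out <- lab$category[match(as.character(zips), lab$zip)]
  out[is.na(out)] <- "missing"
  out
}
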