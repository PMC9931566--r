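required_columns <- list(
  persons = c("person_id", "birth_date", "sex", "race", "ethnicity", "zip",
              "deceased", "site_id"),
  coded_events = c("person_id", "code", "vocabulary", "date", "event_class",
                   "inpatient"),
  visits = c("person_id", "start_date", "end_date", "inpatient"),
  tests = c("person_id", "date", "result"),
  site_metadata = c("site_id", "lab_coverage", "valid_end_frac",
                    "date_shift_days", "index_code_use"),
  sdoh_by_zip = c("zip"),
  truth = c("person_id", "subtype")
)

#' Write raw tables as delimited text
#'
#' One UTF-8 comma-delimited file per table with a header row, plus a
#' `manifest.csv` listing table names, row counts, the seed (when known),
#' and a config fingerprint. Reading the directory back with
#' [read_tables()] round-trips the tables.
#'
#' @param tables a `raw_tables` list (see [generate_population()]).
#' @param dir output directory (created if absent).
#' @param seed,config_hash optional provenance recorded in the manifest.
#' @return invisibly, the written file paths.
#' @export
write_tables <- function(tables, dir, seed = NA, config_hash = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  manifest <- data.frame(key = character(0), value = character(0))
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], path, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, path)
    manifest <- rbind(manifest,
                      data.frame(key = paste0("rows/", nm),
                                 value = as.character(nrow(tables[[nm]]))))
  }
  manifest <- rbind(manifest,
                    data.frame(key = c("seed", "config_hash"),
                               value = as.character(c(seed, config_hash))))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(paths)
}

#' Read raw tables from a directory of delimited files
#'
#' Validates that each present table carries its required columns (error
#' messages name the table and the missing column); unknown extra columns
#' are preserved. ZIP codes and person ids are read as character so
#' leading zeros survive the round trip.
#'
#' @param dir directory written by [write_tables()] (or any directory of
#'   `<table>.csv` files in the same dialect).
#' @return a `raw_tables` list of data.frames.
#' @export
read_tables <- function(dir) {
  out <- list()
  for (nm in names(required_columns)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) next
    classes <- c(person_id = "character", zip = "character",
                 code = "character", site_id = "character")
    hdr <- names(read.csv(path, nrows = 1, fileEncoding = "UTF-8"))
    classes <- classes[names(classes) %in% hdr]
    tab <- read.csv(path, stringsAsFactors = FALSE,
                    colClasses = if (length(classes)) classes else NA,
                    fileEncoding = "UTF-8")
    miss <- setdiff(required_columns[[nm]], names(tab))
    if (length(miss) > 0) {
      stop(sprintf("%s: %s required", nm, paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    out[[nm]] <- tab
  }
  if (length(out) == 0) {
    stop(sprintf("no recognized tables found in '%s'", dir), call. = FALSE)
  }
  structure(out, class = "raw_tables")
}

# Stable fingerprint of an R object (deparse + rolling hash); used to
# record the generating configuration in output manifests.
config_fingerprint <- function(x) {
  sprintf("%08x", as.integer(str_hash(paste(deparse(x), collapse = ""))))
}
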