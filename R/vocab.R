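#' Bundled condition vocabulary
#'
#' A fixed list of ~40 SNOMED-style condition display names spanning the
#' symptom families reported around the long COVID index code
#' (neurological, cardiopulmonary, gastrointestinal, upper respiratory,
#' and age-associated comorbid conditions), with a static ICD-10-CM
#' crosswalk. Bundling a fixed vocabulary avoids any terminology-service
#' dependency; condition identity throughout the package is the SNOMED
#' display name, and duplicate ICD codes mapping to one name collapse
#' before counting.
#'
#' @return data.frame with columns `snomed_name`, `icd10cm`.
#' @export
condition_crosswalk <- function() {
  read_fixture("condition_crosswalk.csv")
}

#' Bundled procedure-category map
#'
#' Maps procedure codes (CPT-style) to the high-level categories used for
#' practice-pattern summaries (radiography, electrocardiography, physical
#' therapy, ...). The map is an editable fixture; it does not claim to be
#' the full mapping used on any restricted dataset.
#'
#' @return data.frame with columns `code`, `category`.
#' @export
procedure_categories <- function() {
  read_fixture("procedure_categories.csv")
}

#' Bundled encounter-code exclusion list
#'
#' Evaluation-and-management style codes (e.g. CPT 99212) that merely
#' record that an encounter took place and carry no diagnostic or
#' therapeutic information; excluded before procedure categorization.
#'
#' @return data.frame with columns `code`, `description`.
#' @export
em_exclusions <- function() {
  read_fixture("em_exclusions.csv")
}

#' Bundled ingredient-to-ATC map
#'
#' Maps drug ingredient names to 7-character WHO ATC codes, from which the
#' level-3 pharmacological subgroup (first four characters) is derived.
#'
#' @return data.frame with columns `ingredient`, `atc7`.
#' @export
atc_ingredients <- function() {
  read_fixture("atc_ingredients.csv")
}

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "lcnet")
  if (!nzchar(path)) {
    # during development (pkgload) system.file resolves inst/ itself
    stop(sprintf("bundled fixture '%s' not found", name), call. = FALSE)
  }
  read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
}
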