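#' End-to-end run configuration
#'
#' Bundles the stage parameters for [run_all()]. Defaults reproduce the
#' headline study conditions: index window 2021-10-01..2022-05-26, 60-day
#' analysis window, top 30 conditions, Louvain at resolution 1, tertile
#' SDoH cutpoints, suppression below 20 with shifts up to 5.
#'
#' @param generator a [generator_config()], or `NULL` to read
#'   pre-generated tables from `input_dir`.
#' @param input_dir directory of tables (used when `generator` is NULL).
#' @param output_dir directory for stage outputs, or `NULL` to skip
#'   writing.
#' @param rule an [index_rule()].
#' @param criteria a [site_criteria()].
#' @param K top-condition count.
#' @param algorithm community-detection algorithm.
#' @param resolution Louvain resolution.
#' @param sdoh_vars SDoH variables to categorize.
#' @param sdoh_probs percentile pair for SDoH cutpoints.
#' @param policy a [disclosure_policy()].
#' @param analysis_seed seed for detection and bootstrap streams.
#' @return a `run_config` object.
#' @export
run_config <- function(generator = generator_config(),
                       input_dir = NULL,
                       output_dir = NULL,
                       rule = index_rule(),
                       criteria = site_criteria(),
                       K = 30,
                       algorithm = "louvain",
                       resolution = 1,
                       sdoh_vars = names(default_sdoh_gradient()),
                       sdoh_probs = c(1/3, 2/3),
                       policy = disclosure_policy(),
                       analysis_seed = 1L) {
  if (is.null(generator) && is.null(input_dir)) {
    stop("run_config: provide a generator config or an input_dir",
         call. = FALSE)
  }
  structure(list(generator = generator, input_dir = input_dir,
                 output_dir = output_dir, rule = rule, criteria = criteria,
                 K = K, algorithm = algorithm, resolution = resolution,
                 sdoh_vars = sdoh_vars, sdoh_probs = sdoh_probs,
                 policy = policy, analysis_seed = as.integer(analysis_seed)),
            class = "run_config")
}

#' Run the full characterization pipeline
#'
#' Chains the stages end to end — synthesize (or read) tables, build the
#' cohort, detect co-occurrence communities (overall and age-stratified),
#' compute the SDoH/demographic disclosure table, and produce the
#' procedure/medication/uptake summaries — collecting per-stage status
#' and row counts in a manifest. A failing stage aborts with the stage
#' named. Reruns with the same config and seeds are bit-identical.
#'
#' @param config a [run_config()].
#' @return list with `results` (per-stage outputs), `manifest`
#'   (data.frame stage/status/detail), and `config_hash`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- data.frame(stage = character(0), status = character(0),
                         detail = character(0), stringsAsFactors = FALSE)
  results <- list()
  note <- function(stage, detail) {
    manifest <<- rbind(manifest, data.frame(stage = stage, status = "ok",
                                            detail = detail))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  tables <- run_stage("synth", {
    if (!is.null(config$generator)) generate_population(config$generator)
    else read_tables(config$input_dir)
  })
  note("synth", sprintf("%d persons, %d events", nrow(tables$persons),
                        nrow(tables$coded_events)))

  cohort_res <- run_stage("cohort", {
    eligible <- filter_sites(tables$site_metadata, config$criteria)
    idx <- derive_index(tables$coded_events, config$rule)
    keep <- tables$persons$person_id[tables$persons$site_id %in% eligible]
    idx <- idx[idx$person_id %in% keep, , drop = FALSE]
    cohort <- apply_exclusions(tables$persons, tables$visits, idx)
    windowed <- window_events(cohort, tables$coded_events,
                              config$rule$window_days)
    list(cohort = cohort, windowed = windowed,
         summary = summarize_cohort(cohort), eligible_sites = eligible)
  })
  results$cohort <- cohort_res
  note("cohort", sprintf("%d included of %d indexed (in: %d persons)",
                         nrow(included(cohort_res$cohort)),
                         nrow(cohort_res$cohort), nrow(tables$persons)))

  conet_res <- run_stage("conet", {
    conds <- top_conditions(cohort_res$windowed, K = config$K)
    net <- cooccurrence(cohort_res$windowed, conds)
    part <- detect_communities(net, algorithm = config$algorithm,
                               resolution = config$resolution,
                               seed = config$analysis_seed)
    strat <- stratified_networks(cohort_res$cohort, cohort_res$windowed,
                                 K = config$K, algorithm = config$algorithm,
                                 seed = config$analysis_seed)
    list(conditions = conds, network = net, partition = part,
         stratified = strat)
  })
  results$conet <- conet_res
  note("conet", sprintf("%d nodes, Q = %.4f, %d strata",
                        length(conet_res$conditions), conet_res$partition$Q,
                        length(conet_res$stratified)))

  sdoh_res <- run_stage("sdoh_demo", {
    cats <- lapply(setNames(config$sdoh_vars, config$sdoh_vars),
                   function(v) categorize_sdoh(tables$sdoh_by_zip, v,
                                               probs = config$sdoh_probs))
    demo <- demographic_table(cohort_res$cohort, tables$persons, cats,
                              policy = config$policy)
    list(categorizations = cats, table = demo)
  })
  results$sdoh <- sdoh_res
  note("sdoh_demo", sprintf("%d variables, %d rows",
                            length(sdoh_res$categorizations),
                            nrow(sdoh_res$table)))

  summaries_res <- run_stage("summaries", {
    procs <- filter_informative_procedures(cohort_res$windowed)
    proc_table <- categorize_procedures(procs, cohort_res$cohort)
    idx <- included(cohort_res$cohort)[, c("person_id", "index_date")]
    new_rx <- new_medications(tables$coded_events, idx,
                              window_days = config$rule$window_days)
    atc <- atc_rollup(new_rx, cohort_res$cohort)
    uptake <- uptake_series(tables$coded_events)
    list(procedures = proc_table, new_medications = new_rx, atc = atc,
         uptake = uptake)
  })
  results$summaries <- summaries_res
  note("summaries", sprintf("%d procedure rows, %d ATC rows, %d uptake rows",
                            nrow(summaries_res$procedures),
                            nrow(summaries_res$atc),
                            nrow(summaries_res$uptake)))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(results$cohort$cohort),
              file.path(config$output_dir, "cohort.csv"), row.names = FALSE)
    write.csv(as_edge_list(conet_res$network),
              file.path(config$output_dir, "network_edges.csv"),
              row.names = FALSE)
    write.csv(data.frame(node = names(conet_res$partition$assignment),
                         community = conet_res$partition$assignment),
              file.path(config$output_dir, "partition.csv"),
              row.names = FALSE)
    write.csv(sdoh_res$table,
              file.path(config$output_dir, "demographics.csv"),
              row.names = FALSE)
    write.csv(summaries_res$procedures,
              file.path(config$output_dir, "procedures.csv"),
              row.names = FALSE)
    write.csv(summaries_res$atc,
              file.path(config$output_dir, "atc_classes.csv"),
              row.names = FALSE)
    write.csv(summaries_res$uptake,
              file.path(config$output_dir, "uptake.csv"), row.names = FALSE)
    write.csv(manifest, file.path(config$output_dir, "manifest.csv"),
              row.names = FALSE)
  }

  list(results = results, manifest = manifest,
       config_hash = config_fingerprint(config))
}
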