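#' Bootstrap stability of a community partition
#'
#' Resamples patients with replacement, rebuilds the co-occurrence
#' network over the same node set, re-runs the detection algorithm, and
#' records the adjusted Rand index of each replicate partition against
#' the full-data reference partition. Patients drawn twice contribute
#' twice to the resampled edge weights.
#'
#' @param windowed_events output of [window_events()].
#' @param conditions fixed node set (typically [top_conditions()]).
#' @param algorithm detection algorithm (see [detect_communities()]).
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed; each replicate uses a named sub-stream.
#' @param ... passed to [detect_communities()].
#' @return a `stability_report`: list with `B`, `ari_values`,
#'   `mean_ari`, `min_ari`, and the `reference` partition.
#' @export
stability <- function(windowed_events, conditions, algorithm = "louvain",
                      B = 50, seed = 1L, ...) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (nrow(windowed_events) == 0) {
    stop("empty cohort: no windowed events", call. = FALSE)
  }
  X <- incidence_matrix(windowed_events, conditions)
  reference <- detect_communities(cooccurrence_from_incidence(X),
                                  algorithm = algorithm, seed = seed, ...)
  ari <- vapply(seq_len(B), function(b) {
    rows <- with_substream(seed, sprintf("boot-%d", b),
                           sample.int(nrow(X), replace = TRUE))
    net_b <- cooccurrence_from_incidence(X[rows, , drop = FALSE])
    part_b <- detect_communities(net_b, algorithm = algorithm, seed = seed,
                                 ...)
    adjusted_rand_index(reference$assignment, part_b$assignment)
  }, numeric(1))
  structure(list(B = B, ari_values = ari, mean_ari = mean(ari),
                 min_ari = min(ari), reference = reference),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Bootstrap stability: B = %d, mean ARI = %.3f, min ARI = %.3f\n",
              x$B, x$mean_ari, x$min_ari))
  invisible(x)
}

#' Age-stratified co-occurrence networks and partitions
#'
#' Runs the full pipeline (top conditions, co-occurrence network,
#' community detection) independently within each age group, so the
#' top-K condition lists and the detected communities may differ by
#' stratum. Strata with fewer than 2 distinct conditions are skipped with
#' a warning; other strata are unaffected.
#'
#' @param cohort output of [apply_exclusions()].
#' @param windowed_events output of [window_events()].
#' @param K top-condition count per stratum (default 30).
#' @param algorithm detection algorithm.
#' @param seed integer seed.
#' @param ... passed to [detect_communities()].
#' @return named list (one element per non-empty age group) of lists with
#'   `conditions`, `network`, `partition`, `n_patients`.
#' @export
stratified_networks <- function(cohort, windowed_events, K = 30,
                                algorithm = "louvain", seed = 1L, ...) {
  inc <- included(cohort)
  out <- list()
  for (g in age_bins()$labels) {
    ids <- inc$person_id[inc$age_group == g]
    ev <- windowed_events[windowed_events$person_id %in% ids, , drop = FALSE]
    if (nrow(ev) == 0) {
      warning(sprintf("age group %s: no events; stratum skipped", g))
      next
    }
    conds <- suppressWarnings(top_conditions(ev, K = K))
    if (length(conds) < 2) {
      warning(sprintf("age group %s: fewer than 2 conditions; stratum skipped",
                      g))
      next
    }
    net <- cooccurrence(ev, conds)
    if (sum(net$weights) <= 0) {
      warning(sprintf("age group %s: no co-occurring pairs; stratum skipped",
                      g))
      next
    }
    part <- detect_communities(net, algorithm = algorithm, seed = seed, ...)
    out[[g]] <- list(conditions = conds, network = net, partition = part,
                     n_patients = length(ids))
  }
  out
}
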