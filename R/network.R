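#' Most frequent in-window conditions
#'
#' Ranks conditions by the number of distinct patients whose analysis
#' window contains the condition at least once (duplicate events within a
#' patient collapse). The index code itself is never a candidate. Ties
#' break lexicographically by condition identifier, so the ranking is
#' invariant to input row order.
#'
#' @param windowed_events output of [window_events()] (a `code` column;
#'   rows with `event_class != "condition"` are ignored when the column is
#'   present).
#' @param K number of conditions to keep (default 30).
#' @param exclude codes excluded from candidacy (default the index code).
#' @return character vector of at most `K` condition identifiers, most
#'   frequent first; warns if fewer than `K` distinct conditions exist.
#' @export
top_conditions <- function(windowed_events, K = 30, exclude = "U09.9") {
  ev <- as.data.table(windowed_events)
  if ("event_class" %in% names(ev)) ev <- ev[event_class == "condition"]
  ev <- ev[!code %in% exclude]
  counts <- unique(ev[, .(person_id, code)])[, .N, by = code]
  setorder(counts, -N, code)
  if (nrow(counts) < K) {
    warning(sprintf("only %d distinct conditions available (requested %d)",
                    nrow(counts), K))
  }
  head(counts$code, K)
}

# persons x conditions logical incidence matrix (condition present at
# least once in the person's window)
incidence_matrix <- function(windowed_events, conditions) {
  ev <- as.data.table(windowed_events)
  if ("event_class" %in% names(ev)) ev <- ev[event_class == "condition"]
  ev <- unique(ev[code %in% conditions, .(person_id, code)])
  persons <- sort(unique(as.data.table(windowed_events)$person_id))
  X <- matrix(FALSE, length(persons), length(conditions),
              dimnames = list(persons, conditions))
  if (nrow(ev) > 0) {
    X[cbind(match(ev$person_id, persons), match(ev$code, conditions))] <- TRUE
  }
  X
}

cooccurrence_from_incidence <- function(X) {
  Xn <- matrix(as.numeric(X), nrow(X), dimnames = dimnames(X))
  W <- crossprod(Xn)
  diag(W) <- 0
  structure(list(nodes = colnames(X), weights = W, node_freq = colSums(Xn)),
            class = "cooccurrence_network")
}

#' Condition co-occurrence network
#'
#' Symmetric weighted graph over the supplied conditions; the weight of
#' edge (i, j) is the number of distinct patients whose analysis window
#' contains both conditions at least once. The diagonal is zero, and
#' every weight is bounded by the smaller of the two per-condition
#' patient counts. Conditions absent from the events are retained as
#' isolated nodes with frequency 0.
#'
#' @param windowed_events output of [window_events()].
#' @param conditions ordered character vector of node identifiers
#'   (typically [top_conditions()]).
#' @return a `cooccurrence_network`: list with `nodes`, `weights`
#'   (symmetric numeric matrix), `node_freq`.
#' @export
cooccurrence <- function(windowed_events, conditions) {
  if (length(conditions) == 0) {
    stop("conditions must be non-empty", call. = FALSE)
  }
  cooccurrence_from_incidence(incidence_matrix(windowed_events, conditions))
}

net_weights <- function(x) {
  W <- if (inherits(x, "cooccurrence_network")) x$weights else as.matrix(x)
  if (nrow(W) != ncol(W) || any(abs(W - t(W)) > 1e-9)) {
    stop("weights must be a symmetric square matrix", call. = FALSE)
  }
  if (any(W < 0)) stop("weights must be non-negative", call. = FALSE)
  W
}

net_nodes <- function(x, W) {
  if (inherits(x, "cooccurrence_network")) x$nodes
  else rownames(W) %||% as.character(seq_len(nrow(W)))
}

#' Weighted edge list of a network
#'
#' @param net a `cooccurrence_network` or symmetric weight matrix.
#' @return data.frame `node_a`, `node_b`, `weight` with zero-weight pairs
#'   dropped (they carry no modularity contribution).
#' @export
as_edge_list <- function(net) {
  W <- net_weights(net)
  nodes <- net_nodes(net, W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  data.frame(node_a = nodes[idx[, 1]], node_b = nodes[idx[, 2]],
             weight = W[idx], stringsAsFactors = FALSE)
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  el <- as_edge_list(x)
  cat(sprintf("Co-occurrence network: %d nodes, %d positive-weight edges, total weight %g\n",
              length(x$nodes), nrow(el), sum(el$weight)))
  invisible(x)
}
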