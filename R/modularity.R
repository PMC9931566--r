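#' Weighted Newman-Girvan modularity
#'
#' Q = (1/2m) * sum_ij \[A_ij - gamma * k_i k_j / (2m)\] * delta(c_i, c_j),
#' with weighted degrees k, total edge weight m, and resolution gamma.
#' At gamma = 1 the single-community partition scores exactly 0 and Q is
#' bounded by \[-1, 1\]. The score is invariant to community relabelling
#' and to node reordering.
#'
#' @param net a `cooccurrence_network` or symmetric non-negative weight
#'   matrix (zero diagonal for simple graphs).
#' @param assignment community labels, one per node (any atomic type).
#' @param resolution resolution parameter gamma (default 1).
#' @return modularity Q (numeric scalar).
#' @export
modularity_q <- function(net, assignment, resolution = 1) {
  W <- net_weights(net)
  n <- nrow(W)
  if (length(assignment) != n) {
    stop("assignment must cover all nodes", call. = FALSE)
  }
  k <- rowSums(W)
  m2 <- sum(k)
  if (m2 <= 0) stop("modularity undefined: total edge weight is zero",
                    call. = FALSE)
  labs <- as.character(assignment)
  q <- 0
  for (c in unique(labs)) {
    idx <- which(labs == c)
    w_in <- sum(W[idx, idx])          # ordered-pair sum within community
    k_c <- sum(k[idx])
    q <- q + w_in / m2 - resolution * (k_c / m2)^2
  }
  q
}

new_partition <- function(nodes, labels, net, algorithm, resolution = 1,
                          seed = NA_integer_) {
  # renumber communities consecutively in order of first appearance so the
  # labelling is deterministic
  f <- match(labels, unique(labels))
  assignment <- setNames(f, nodes)
  structure(list(assignment = assignment,
                 Q = modularity_q(net, f, resolution = resolution),
                 algorithm = algorithm, resolution = resolution, seed = seed),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  k <- length(unique(x$assignment))
  cat(sprintf("Community partition (%s): %d nodes in %d communities, Q = %.4f\n",
              x$algorithm, length(x$assignment), k, x$Q))
  for (c in sort(unique(x$assignment))) {
    cat(sprintf("  [%d] %s\n", c,
                paste(names(x$assignment)[x$assignment == c], collapse = ", ")))
  }
  invisible(x)
}
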