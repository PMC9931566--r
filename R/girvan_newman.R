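#' Girvan-Newman divisive community detection
#'
#' Repeatedly removes the edge with the highest shortest-path edge
#' betweenness (weights enter as distances 1/weight, so heavier
#' co-occurrence means a shorter path) and scores the resulting connected
#' components as a partition with modularity computed on the ORIGINAL
#' graph. Returns the partition along the removal dendrogram with maximum
#' modularity. Ties in betweenness break deterministically on the first
#' edge in (row, column) order.
#'
#' @param net a `cooccurrence_network` or symmetric weight matrix with
#'   positive total weight.
#' @param resolution resolution gamma used when scoring partitions.
#' @return a `community_partition`.
#' @export
girvan_newman <- function(net, resolution = 1) {
  W <- net_weights(net)
  nodes <- net_nodes(net, W)
  if (sum(W) <= 0) stop("graph has zero total edge weight", call. = FALSE)

  cur <- W
  best_labels <- graph_components(cur)
  best_q <- modularity_q(W, best_labels, resolution)
  while (sum(cur) > 0) {
    eb <- edge_betweenness(cur)
    eb[lower.tri(eb, diag = TRUE)] <- -Inf
    mx <- max(eb)
    hit <- which(eb >= mx - 1e-9, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    cur[hit[1], hit[2]] <- 0
    cur[hit[2], hit[1]] <- 0
    labels <- graph_components(cur)
    q <- modularity_q(W, labels, resolution)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_labels <- labels
    }
  }
  new_partition(nodes, best_labels, net, "girvan_newman",
                resolution = resolution)
}

# Connected-component labels of a weighted adjacency matrix.
graph_components <- function(W) {
  n <- nrow(W)
  labels <- rep(0L, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (labels[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    labels[s] <- comp
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- which(W[u, ] > 0 & labels == 0L)
      labels[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Shortest-path edge betweenness (weighted)
#'
#' Brandes' accumulation with Dijkstra shortest paths; edge weights are
#' converted to distances 1/weight. Each undirected edge's score is the
#' sum over all node pairs of the fraction of shortest paths through it.
#'
#' @param W symmetric non-negative weight matrix.
#' @return symmetric matrix of betweenness scores (zero where no edge).
#' @export
edge_betweenness <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  eb <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- rep(0, n); sigma[s] <- 1
    preds <- vector("list", n)
    done <- rep(FALSE, n)
    order_popped <- integer(0)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (length(cand) == 0) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      order_popped <- c(order_popped, u)
      for (v in which(is.finite(D[u, ]) & !done)) {
        alt <- dist[u] + D[u, v]
        if (alt < dist[v] - 1e-12) {
          dist[v] <- alt
          sigma[v] <- sigma[u]
          preds[[v]] <- u
        } else if (abs(alt - dist[v]) <= 1e-12) {
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    delta <- rep(0, n)
    for (u in rev(order_popped)) {
      for (p in preds[[u]]) {
        c_ <- sigma[p] / sigma[u] * (1 + delta[u])
        eb[p, u] <- eb[p, u] + c_
        eb[u, p] <- eb[u, p] + c_
        delta[p] <- delta[p] + c_
      }
    }
  }
  eb / 2   # each unordered pair contributes from both endpoints
}
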