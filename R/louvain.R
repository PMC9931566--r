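#' Louvain community detection
#'
#' Greedy modularity maximization in two repeated phases: local node
#' moves (each node joins the neighbouring community with the largest
#' positive modularity gain) until no move improves Q, then aggregation
#' of communities into supernodes, repeating until a full level makes no
#' move. Node visitation order within each level is shuffled by `seed`,
#' making the run deterministic; modularity-gain ties go to the
#' lowest-index community. The returned Q is always at least the Q of the
#' all-singleton start.
#'
#' @param net a `cooccurrence_network` or symmetric weight matrix with
#'   positive total weight.
#' @param resolution resolution gamma (default 1; larger values favour
#'   more, smaller communities).
#' @param seed integer seed controlling node visitation order.
#' @return a `community_partition` (assignment, Q, algorithm metadata).
#' @export
louvain <- function(net, resolution = 1, seed = 1L) {
  W <- net_weights(net)
  nodes <- net_nodes(net, W)
  if (sum(W) <= 0) stop("graph has zero total edge weight", call. = FALSE)

  comm <- seq_len(nrow(W))   # original node -> current community
  M <- W
  level <- 0
  repeat {
    level <- level + 1
    ord <- with_substream(seed, sprintf("louvain-level-%d", level),
                          sample.int(nrow(M)))
    lev <- louvain_level(M, resolution, ord)
    if (lev$moves == 0) break
    comm <- lev$membership[comm]
    M <- aggregate_communities(M, lev$membership)
    if (nrow(M) == 1) break
  }
  new_partition(nodes, comm, net, "louvain", resolution = resolution,
                seed = seed)
}

# One Louvain level: local moves from a singleton start until a full pass
# makes no move. Returns membership (renumbered 1..k) and the move count.
louvain_level <- function(M, resolution, ord) {
  n <- nrow(M)
  k <- rowSums(M)
  m2 <- sum(k)
  memb <- seq_len(n)
  Kc <- k                    # community degree totals
  total_moves <- 0
  repeat {
    moves <- 0
    for (i in ord) {
      a <- memb[i]
      w_i <- M[i, ]
      nb <- which(w_i > 0)
      nb <- nb[nb != i]
      cand <- unique(c(a, memb[nb]))
      # links from i into each candidate community (excluding self-loop)
      l <- vapply(cand, function(c) sum(w_i[memb == c & seq_len(n) != i]),
                  numeric(1))
      # community totals with i removed
      K_wo <- Kc[cand] - ifelse(cand == a, k[i], 0)
      # gain proportional to: links share minus degree-product penalty
      gain <- 2 * l / m2 - resolution * 2 * k[i] * K_wo / m2^2
      best <- cand[order(-gain, cand)][1]   # ties -> lowest community index
      if (best != a && gain[cand == best] > gain[cand == a] + 1e-12) {
        memb[i] <- best
        Kc[a] <- Kc[a] - k[i]
        Kc[best] <- Kc[best] + k[i]
        moves <- moves + 1
      }
    }
    total_moves <- total_moves + moves
    if (moves == 0) break
  }
  list(membership = match(memb, unique(memb)), moves = total_moves)
}

# Collapse communities into supernodes; the diagonal accumulates the
# ordered-pair intra-community weight so supernode degrees are preserved.
aggregate_communities <- function(M, membership) {
  k <- max(membership)
  S <- matrix(0, nrow(M), k)
  S[cbind(seq_len(nrow(M)), membership)] <- 1
  t(S) %*% M %*% S
}
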