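#' Walktrap community detection
#'
#' Agglomerative clustering on short-random-walk distances (Pons &
#' Latapy): each node's signature is its t-step walk probability vector;
#' the squared distance between communities is the degree-weighted squared
#' difference of their (member-averaged) signatures; at every step the
#' pair of ADJACENT communities with the smallest Ward-style merge cost is
#' merged; the merge tree is cut at the partition with maximum modularity.
#' Nodes with zero degree never enter the walk and stay as their own
#' communities.
#'
#' @param net a `cooccurrence_network` or symmetric weight matrix with
#'   positive total weight.
#' @param t walk length (default 4); must be >= 1.
#' @param resolution resolution gamma used when scoring partitions.
#' @return a `community_partition`.
#' @export
walktrap <- function(net, t = 4, resolution = 1) {
  if (t < 1) stop("walk length t must be >= 1", call. = FALSE)
  W <- net_weights(net)
  nodes <- net_nodes(net, W)
  n <- nrow(W)
  d <- rowSums(W)
  if (sum(d) <= 0) stop("graph has zero total edge weight", call. = FALSE)

  active <- which(d > 0)
  na <- length(active)
  # t-step transition probabilities restricted to walk-reachable nodes
  P <- W[active, active, drop = FALSE] / d[active]
  Pt <- P
  if (t > 1) for (s in seq_len(t - 1)) Pt <- Pt %*% P
  dw <- d[active]

  # community state over active nodes
  memb <- seq_len(na)
  vecs <- Pt                       # one signature row per community
  sizes <- rep(1, na)
  adj <- (W[active, active, drop = FALSE] > 0); diag(adj) <- FALSE
  alive <- rep(TRUE, na)

  r2 <- function(c1, c2) sum((vecs[c1, ] - vecs[c2, ])^2 / dw)

  best_labels <- memb
  best_q <- modularity_q(W, expand_labels(memb, active, n), resolution)
  repeat {
    pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
    pairs <- pairs[alive[pairs[, 1]] & alive[pairs[, 2]], , drop = FALSE]
    if (nrow(pairs) == 0) break
    cost <- apply(pairs, 1, function(pr) {
      s1 <- sizes[pr[1]]; s2 <- sizes[pr[2]]
      s1 * s2 / (s1 + s2) * r2(pr[1], pr[2]) / na
    })
    bi <- order(cost, pairs[, 1], pairs[, 2])[1]
    c1 <- pairs[bi, 1]; c2 <- pairs[bi, 2]
    # merge c2 into c1
    vecs[c1, ] <- (sizes[c1] * vecs[c1, ] + sizes[c2] * vecs[c2, ]) /
      (sizes[c1] + sizes[c2])
    sizes[c1] <- sizes[c1] + sizes[c2]
    adj[c1, ] <- adj[c1, ] | adj[c2, ]
    adj[, c1] <- adj[, c1] | adj[, c2]
    adj[c1, c1] <- FALSE
    adj[c2, ] <- FALSE; adj[, c2] <- FALSE
    alive[c2] <- FALSE
    memb[memb == c2] <- c1

    q <- modularity_q(W, expand_labels(memb, active, n), resolution)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_labels <- memb
    }
  }
  new_partition(nodes, expand_labels(best_labels, active, n), net,
                "walktrap", resolution = resolution)
}

# Lift labels on the active-node subset to all n nodes, leaving inactive
# (zero-degree) nodes as their own singleton communities.
expand_labels <- function(labels, active, n) {
  full <- paste0("iso", seq_len(n))
  full[active] <- paste0("c", labels)
  full
}

#' Dispatch to a community-detection algorithm
#'
#' @param net a `cooccurrence_network` or symmetric weight matrix.
#' @param algorithm one of `"louvain"`, `"girvan_newman"`, `"walktrap"`.
#' @param resolution resolution gamma.
#' @param seed seed (used by Louvain's node-order shuffle).
#' @param t Walktrap walk length.
#' @return a `community_partition`.
#' @export
detect_communities <- function(net,
                               algorithm = c("louvain", "girvan_newman",
                                             "walktrap"),
                               resolution = 1, seed = 1L, t = 4) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         louvain = louvain(net, resolution = resolution, seed = seed),
         girvan_newman = girvan_newman(net, resolution = resolution),
         walktrap = walktrap(net, t = t, resolution = resolution))
}
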