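# Independent oracles used to freeze expected values. These deliberately
# re-derive quantities by brute force (direct formula evaluation, full
# enumeration) and never call the package functions they are used to check.

# Modularity by direct evaluation of the defining double sum.
oracle_modularity <- function(W, memb, gamma = 1) {
  k <- rowSums(W)
  m2 <- sum(k)
  q <- 0
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(ncol(W))) {
      if (memb[i] == memb[j]) {
        q <- q + W[i, j] - gamma * k[i] * k[j] / m2
      }
    }
  }
  unname(q / m2)
}

# All set partitions of n items as restricted-growth label vectors.
# n = 6 yields the 203 partitions of a 6-element set (Bell number B6).
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, maxlab) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible(NULL))
    }
    for (l in seq_len(maxlab + 1)) {
      recurse(c(labels, l), max(maxlab, l))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive-search modularity maximum over all partitions.
oracle_best_partition <- function(W, gamma = 1) {
  parts <- enumerate_partitions(nrow(W))
  qs <- vapply(parts, function(p) oracle_modularity(W, p, gamma), numeric(1))
  list(q = max(qs), partition = parts[[which.max(qs)]], n_partitions = length(parts))
}

# Pairwise co-occurrence by explicit enumeration over patients.
brute_cooccurrence <- function(windowed_events, conditions) {
  ev <- windowed_events
  if ("event_class" %in% names(ev)) {
    ev <- ev[ev$event_class == "condition", , drop = FALSE]
  }
  persons <- unique(windowed_events$person_id)
  W <- matrix(0, length(conditions), length(conditions),
              dimnames = list(conditions, conditions))
  for (p in persons) {
    has <- conditions %in% ev$code[ev$person_id == p]
    for (i in seq_along(conditions)) {
      for (j in seq_along(conditions)) {
        if (i != j && has[i] && has[j]) W[i, j] <- W[i, j] + 1
      }
    }
  }
  W
}

# Exact shortest-path edge betweenness by enumerating all simple paths
# between every node pair (feasible only for small graphs).
oracle_edge_betweenness <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(to))
    nbrs <- which(is.finite(D[from, ]) & !(seq_len(n) %in% visited))
    paths <- list()
    for (v in nbrs) {
      for (p in all_paths(v, to, c(visited, v))) {
        paths[[length(paths) + 1]] <- c(from, p)
      }
    }
    paths
  }
  path_len <- function(p) {
    sum(vapply(seq_len(length(p) - 1), function(i) D[p[i], p[i + 1]],
               numeric(1)))
  }
  eb <- matrix(0, n, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t, s)
      if (length(paths) == 0) next
      lens <- vapply(paths, path_len, numeric(1))
      shortest <- paths[lens <= min(lens) + 1e-12]
      for (p in shortest) {
        for (i in seq_len(length(p) - 1)) {
          a <- p[i]; b <- p[i + 1]
          eb[a, b] <- eb[a, b] + 1 / length(shortest)
          eb[b, a] <- eb[b, a] + 1 / length(shortest)
        }
      }
    }
  }
  eb
}
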