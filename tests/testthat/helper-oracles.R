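# Shared fixtures and independent brute-force oracles. The oracles use
# deliberately naive double loops / exhaustive enumeration so they share no
# code path with the package implementations they check.

library(igraph)

# weighted undirected graph from an edge data.frame (a, b, w)
el_graph <- function(a, b, w = NULL) {
  df <- data.frame(a = as.character(a), b = as.character(b))
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::E(g)$weight <- if (is.null(w)) rep(1, nrow(df)) else w
  g
}

clique_edges <- function(ids) {
  cmb <- utils::combn(ids, 2)
  data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
}

# two cliques of sizes k1, k2 joined by a single unit bridge
two_clique_graph <- function(k1, k2, bridge = TRUE) {
  ids1 <- paste0("x", seq_len(k1))
  ids2 <- paste0("y", seq_len(k2))
  e <- rbind(clique_edges(ids1), clique_edges(ids2))
  if (bridge) e <- rbind(e, data.frame(a = ids1[1], b = ids2[1]))
  el_graph(e$a, e$b)
}

random_weighted_graph <- function(n, p = 0.3, seed = 1, wmax = 5) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  # ensure at least one edge so statistics are defined
  if (igraph::ecount(g) == 0) {
    g <- igraph::add_edges(g, c(1, 2))
  }
  igraph::V(g)$name <- paste0("n", seq_len(n))
  igraph::E(g)$weight <- sample(seq_len(wmax), igraph::ecount(g),
                                replace = TRUE)
  g
}

# ---- oracle: weighted modularity by explicit double loop over node pairs
modularity_oracle <- function(graph, membership) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight",
                                             sparse = TRUE))
  nodes <- igraph::V(graph)$name
  A <- A[nodes, nodes]
  m2 <- sum(A)                      # 2m
  s <- rowSums(A)
  q <- 0
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (!is.na(membership[nodes[i]]) && !is.na(membership[nodes[j]]) &&
          membership[nodes[i]] == membership[nodes[j]]) {
        q <- q + A[i, j] - s[i] * s[j] / m2
      }
    }
  }
  unname(q / m2)
}

# ---- oracle: categorical assortativity via an explicitly built mixing matrix
assortativity_oracle <- function(graph, labels) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  w <- igraph::E(graph)$weight
  cats <- sort(unique(as.character(labels[igraph::V(graph)$name])))
  e <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (k in seq_len(nrow(el))) {
    li <- as.character(labels[el[k, 1]])
    lj <- as.character(labels[el[k, 2]])
    e[li, lj] <- e[li, lj] + w[k]
    e[lj, li] <- e[lj, li] + w[k]
  }
  e <- e / sum(e)
  a <- rowSums(e)
  unname((sum(diag(e)) - sum(a * a)) / (1 - sum(a * a)))
}

# categories actually present on edge endpoints (isolated nodes carry no
# edge mass, so they cannot make the mixing matrix non-degenerate)
edge_categories <- function(graph, labels) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  unique(as.character(labels[unique(c(el[, 1], el[, 2]))]))
}

# ---- oracle: best-modularity partition by exhaustive set-partition search
all_set_partitions <- function(items) {
  if (length(items) == 1) return(list(list(items)))
  rest <- all_set_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(items[1], q[[i]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(items[1]), p)
  }
  out
}

best_partition_oracle <- function(graph) {
  nodes <- igraph::V(graph)$name
  best_q <- -Inf
  best <- NULL
  for (p in all_set_partitions(nodes)) {
    m <- setNames(rep(seq_along(p), lengths(p)), unlist(p))
    q <- modularity_oracle(graph, m)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- m
    }
  }
  list(membership = best, q = best_q)
}

# canonical form of a partition for comparisons that ignore community ids
canon_partition <- function(membership) {
  membership <- membership[!is.na(membership)]
  sets <- lapply(split(names(membership), as.character(membership)), sort)
  unname(sets[order(vapply(sets, `[`, character(1), 1))])
}

same_partition <- function(m1, m2) {
  identical(canon_partition(m1), canon_partition(m2))
}

tiny_society <- function(n = 120, seed = 1, ...) {
  generate_society(society_config(n_agents = n, seed = seed, ...))
}

lang_labels <- function(society) {
  setNames(society$agents$language, society$agents$agent_id)
}
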