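#' Weighted Newman modularity of a partition
#'
#' `Q = (1/2m) * sum_ij [w_ij - s_i s_j / (2m)] * delta(c_i, c_j)` with
#' `s` the weighted node strengths and `m` the total edge weight. High `Q`
#' means agents engage predominantly within their community. Nodes left
#' unassigned (`NA`) by community filtering are dropped from both graph and
#' partition before computation.
#'
#' @param graph a weighted undirected engagement graph.
#' @param partition a [new_partition()] or a named membership vector.
#' @param weighted use edge weights (default); `FALSE` treats all edges as
#'   unit weight.
#' @return Modularity in `[-1, 1]`.
#' @export
modularity_weighted <- function(graph, partition, weighted = TRUE) {
  m <- as_membership_vector(partition)
  sub <- restrict_to_assigned(graph, m)
  g <- sub$graph; m <- sub$membership
  if (ecount(g) == 0 || vcount(g) == 0) {
    stop("modularity is undefined on a graph with zero total weight",
         call. = FALSE)
  }
  w <- if (weighted) E(g)$weight %||% rep(1, ecount(g)) else
    rep(1, ecount(g))
  tot <- sum(w)
  el <- as_edgelist(g, names = TRUE)
  ci <- m[el[, 1]]; cj <- m[el[, 2]]
  within <- tapply(w[ci == cj], ci[ci == cj], sum)
  s <- setNames(numeric(vcount(g)), V(g)$name)
  str_by_end <- tapply(c(w, w), c(el[, 1], el[, 2]), sum)
  s[names(str_by_end)] <- str_by_end
  s_comm <- tapply(s, m[names(s)], sum)
  e_c <- setNames(rep(0, length(s_comm)), names(s_comm))
  if (length(within)) e_c[names(within)] <- within / tot
  a_c <- s_comm / (2 * tot)
  sum(e_c - a_c^2)
}

as_membership_vector <- function(partition) {
  if (inherits(partition, "partition")) partition$membership else partition
}

ensure_named <- function(graph) {
  if (is.null(V(graph)$name)) {
    graph <- set_vertex_attr(graph, "name",
                             value = as.character(seq_len(vcount(graph))))
  }
  graph
}

restrict_to_assigned <- function(graph, membership) {
  graph <- ensure_named(graph)
  nodes <- V(graph)$name
  missing <- setdiff(nodes, names(membership))
  if (length(missing)) {
    stop("partition does not cover graph nodes: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  }
  assigned <- nodes[!is.na(membership[nodes])]
  g <- induced_subgraph(graph, assigned)
  list(graph = g, membership = membership[V(g)$name])
}

#' Categorical (attribute) assortativity
#'
#' Weighted mixing-matrix assortativity
#' `r = (sum_i e_ii - sum_i a_i^2) / (1 - sum_i a_i^2)` where `e` is the
#' symmetric edge-weight mixing matrix over categories and `a` its margins.
#' `r = 1` means all engagement stays within categories (perfect
#' segregation); negative values mean disassortative mixing.
#'
#' @param graph a weighted undirected engagement graph.
#' @param labels named vector mapping every graph node to a category, or the
#'   name of a vertex attribute holding the categories.
#' @param weighted use edge weights (default).
#' @return Assortativity coefficient in `[-1, 1]`.
#' @export
attribute_assortativity <- function(graph, labels, weighted = TRUE) {
  graph <- ensure_named(graph)
  if (is.character(labels) && length(labels) == 1 && is.null(names(labels))) {
    labels <- setNames(vertex_attr(graph, labels), V(graph)$name)
  }
  labels <- as_membership_vector(labels)
  nodes <- V(graph)$name
  if (any(!(nodes %in% names(labels))) || anyNA(labels[nodes])) {
    stop("every node must be labelled", call. = FALSE)
  }
  if (ecount(graph) == 0) {
    stop("assortativity is undefined on a graph with no edges", call. = FALSE)
  }
  w <- if (weighted) E(graph)$weight %||% rep(1, ecount(graph)) else
    rep(1, ecount(graph))
  el <- as_edgelist(graph, names = TRUE)
  li <- as.character(labels[el[, 1]])
  lj <- as.character(labels[el[, 2]])
  cats <- sort(unique(c(li, lj)))
  if (length(cats) < 2) {
    stop("degenerate attribute: only one category present", call. = FALSE)
  }
  assort_fast(match(li, cats), match(lj, cats), w, length(cats))
}

# Mixing-matrix assortativity from integer category codes; vectorized so the
# rewiring null can call it tens of thousands of times.
assort_fast <- function(ci, cj, w, n_cats) {
  tot <- 2 * sum(w)
  diag_mass <- 2 * sum(w[ci == cj]) / tot
  strength <- rowsum(c(w, w), c(ci, cj))
  a <- numeric(n_cats)
  a[as.integer(rownames(strength))] <- strength[, 1] / tot
  denom <- 1 - sum(a^2)
  if (denom == 0) {
    stop("degenerate attribute: only one category carries edge mass",
         call. = FALSE)
  }
  (diag_mass - sum(a^2)) / denom
}

#' Pairwise assortativity between two categories
#'
#' [attribute_assortativity()] on the subgraph induced by the nodes of two
#' categories, measuring whether engagement concentrates within rather than
#' between that pair (e.g. a pair of languages).
#'
#' @inheritParams attribute_assortativity
#' @param cat_a,cat_b the two category values.
#' @return Assortativity coefficient for the pair.
#' @export
pairwise_assortativity <- function(graph, labels, cat_a, cat_b,
                                   weighted = TRUE) {
  graph <- ensure_named(graph)
  if (is.character(labels) && length(labels) == 1 && is.null(names(labels))) {
    labels <- setNames(vertex_attr(graph, labels), V(graph)$name)
  }
  nodes <- V(graph)$name
  lab <- labels[nodes]
  keep <- nodes[!is.na(lab) & lab %in% c(cat_a, cat_b)]
  if (!any(lab == cat_a, na.rm = TRUE) || !any(lab == cat_b, na.rm = TRUE)) {
    stop("both categories must be present in the graph", call. = FALSE)
  }
  sub <- induced_subgraph(graph, keep)
  if (ecount(sub) == 0) {
    stop("induced subgraph for the category pair has no edges",
         call. = FALSE)
  }
  attribute_assortativity(sub, labels, weighted = weighted)
}

#' Structural statistics of a partitioned graph
#'
#' @param graph a weighted undirected engagement graph.
#' @param partition a [new_partition()].
#' @param weighted use edge weights (default).
#' @return A list of class `partition_stats`: `modularity`, `assortativity`
#'   (on the community labelling; `NA` when only one community remains, as
#'   the mixing-matrix denominator vanishes), `n_nodes`, `n_edges`,
#'   `total_weight`.
#' @export
partition_stats <- function(graph, partition, weighted = TRUE) {
  m <- as_membership_vector(partition)
  sub <- restrict_to_assigned(graph, m)
  structure(
    list(
      modularity = modularity_weighted(graph, partition, weighted),
      assortativity = tryCatch(
        attribute_assortativity(sub$graph, sub$membership, weighted),
        error = function(e) NA_real_
      ),
      n_nodes = vcount(sub$graph),
      n_edges = ecount(sub$graph),
      total_weight = sum(E(sub$graph)$weight %||% rep(1, ecount(sub$graph)))
    ),
    class = "partition_stats"
  )
}

#' @export
print.partition_stats <- function(x, ...) {
  cat(sprintf("<partition_stats> Q = %.4f, r = %.4f (%d nodes, %d edges, weight %g)\n",
              x$modularity, x$assortativity, x$n_nodes, x$n_edges,
              x$total_weight))
  invisible(x)
}
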