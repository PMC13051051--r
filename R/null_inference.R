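#' Degree-preserving random rewiring
#'
#' Randomises an engagement graph by repeated double-edge swaps
#' (`{a,b},{c,d} -> {a,d},{c,b}`), rejecting any swap that would create a
#' self-loop or a duplicate pair. Each node's set-degree (number of distinct
#' neighbours) is preserved exactly, edge count and total weight are
#' unchanged, and every weight travels with its edge. The target is
#' `round(swap_factor * |E|)` successful swaps, the usual mixing heuristic
#' for configuration-model nulls.
#'
#' @param graph a simple weighted undirected graph with at least 2 edges;
#'   graphs admitting no valid swap (e.g. a triangle) are returned unchanged
#'   with a warning.
#' @param swap_factor successful swaps per edge (default 10).
#' @param seed RNG seed; deterministic given the seed.
#' @return The rewired graph (same vertices, attributes preserved on
#'   vertices; edge weights permuted with their edges).
#' @export
rewire_preserving_degrees <- function(graph, swap_factor = 10, seed = NULL) {
  graph <- ensure_named(graph)
  m <- ecount(graph)
  if (m < 2) {
    warning("graph has fewer than 2 edges; returning it unchanged")
    return(graph)
  }
  el <- as_edgelist(graph, names = FALSE)
  storage.mode(el) <- "integer"
  w <- E(graph)$weight %||% rep(1, m)
  n_swaps <- max(1L, as.integer(round(swap_factor * m)))
  seed_int <- (seed %||% derive_seeds(NULL, 1)) %% .Machine$integer.max
  out <- rewire_edges_cpp(el, vcount(graph), n_swaps, as.integer(seed_int),
                          max_try_factor = 100)
  if (attr(out, "swaps") == 0) {
    warning("no valid degree-preserving swap exists; graph unchanged")
    return(graph)
  }
  g2 <- graph_from_edgelist(out, directed = FALSE)
  # carry over vertex count mismatches (isolated vertices keep their slot)
  if (vcount(g2) < vcount(graph)) {
    g2 <- add_vertices(g2, vcount(graph) - vcount(g2))
  }
  V(g2)$name <- V(graph)$name
  for (attr_name in setdiff(vertex_attr_names(graph), "name")) {
    g2 <- set_vertex_attr(g2, attr_name,
                          value = vertex_attr(graph, attr_name))
  }
  E(g2)$weight <- w
  for (ga in graph_attr_names(graph)) {
    g2 <- set_graph_attr(g2, ga, graph_attr(graph, ga))
  }
  g2
}

# Bootstrapped one-sided upper-tail p: share of null scores at least as
# extreme as the observed value. Resolution floor is 1/n (a zero count is
# displayed as "< 1/n" by the print method but stored as 0 per the counting
# definition).
boot_p <- function(observed, null_scores, alternative = "greater") {
  if (alternative == "two.sided") {
    mean(abs(null_scores - mean(null_scores)) >=
           abs(observed - mean(null_scores)))
  } else {
    mean(null_scores >= observed)
  }
}

#' Null distribution of a graph statistic under degree-preserving rewiring
#'
#' Implements the bootstrap significance machinery: per iteration the graph
#' is rewired with [rewire_preserving_degrees()] under a fresh derived seed
#' and the statistic is evaluated on the rewired graph. For fixed node
#' attributes (e.g. language labels) pass `labels`; the labels stay attached
#' to the nodes while edges are randomised. For community statistics pass
#' `clustering`, and each rewired graph is re-clustered before the statistic
#' is computed. An iteration that fails to produce communities (or errors)
#' contributes the statistic's minimum, `failure_value`, rather than
#' aborting.
#'
#' @param graph observed engagement graph.
#' @param statistic `"assortativity"`, `"modularity"`, or a function
#'   `f(graph, membership)` returning a scalar.
#' @param labels named category vector for fixed-attribute statistics.
#' @param clustering clustering function `f(graph, seed)` returning a
#'   [new_partition()]; used when `labels` is `NULL`.
#' @param base_partition partition defining the observed value in clustering
#'   mode (defaults to `clustering(graph, seed)`).
#' @param n_iterations number of rewired graphs (default 1000).
#' @param swap_factor swaps per edge for each rewire.
#' @param seed RNG seed; all per-iteration seeds derive from it.
#' @param alternative `"greater"` (default; alternative = more structure
#'   than chance) or `"two.sided"`.
#' @param failure_value null score recorded for a failed iteration
#'   (default -1, the minimum of modularity and assortativity).
#' @param statistic_name label stored on the result.
#' @return An object of class `null_result`: `observed`, `null_scores`,
#'   `p_boot`, `ci_low`, `ci_high` (observed +/- 1.96 sd of the null),
#'   `statistic_name`, `n_iterations`, `seed`.
#' @export
null_distribution <- function(graph, statistic = "assortativity",
                              labels = NULL, clustering = NULL,
                              base_partition = NULL,
                              n_iterations = 1000, swap_factor = 10,
                              seed = NULL, alternative = "greater",
                              failure_value = -1,
                              statistic_name = NULL) {
  if (!is_count(n_iterations)) {
    stop("n_iterations must be >= 1", call. = FALSE)
  }
  graph <- ensure_named(graph)
  seeds <- derive_seeds(seed %||% 1L, n_iterations + 1L)

  fixed_mode <- !is.null(labels)
  if (fixed_mode) {
    nodes <- V(graph)$name
    lab <- as.character(labels[nodes])
    if (anyNA(lab)) stop("every node must be labelled", call. = FALSE)
    cats <- sort(unique(lab))
    code <- match(lab, cats)
    names(code) <- nodes
    w <- E(graph)$weight %||% rep(1, ecount(graph))
    el <- as_edgelist(graph, names = FALSE)
    storage.mode(el) <- "integer"
    stat_from_el <- function(edge_mat) {
      if (is.function(statistic)) {
        g2 <- graph_from_edgelist(edge_mat, directed = FALSE)
        if (vcount(g2) < vcount(graph)) {
          g2 <- add_vertices(g2, vcount(graph) - vcount(g2))
        }
        V(g2)$name <- nodes
        E(g2)$weight <- w
        statistic(g2, setNames(lab, nodes))
      } else {
        assort_fast(code[edge_mat[, 1]], code[edge_mat[, 2]], w,
                    length(cats))
      }
    }
    observed <- stat_from_el(el)
    n_swaps <- max(1L, as.integer(round(swap_factor * nrow(el))))
    null_scores <- vapply(seq_len(n_iterations), function(i) {
      el_i <- rewire_edges_cpp(el, vcount(graph), n_swaps,
                               as.integer(seeds[i]), max_try_factor = 100)
      tryCatch(stat_from_el(el_i), error = function(e) failure_value)
    }, numeric(1))
    name <- statistic_name %||% "attribute_assortativity"
  } else {
    if (is.null(clustering)) {
      clustering <- function(g, s) label_propagation(g, seed = s)
    }
    stat_fun <- if (is.function(statistic)) statistic else switch(
      statistic,
      modularity = function(g, p) modularity_weighted(g, p),
      assortativity = function(g, p) {
        sub <- restrict_to_assigned(g, as_membership_vector(p))
        attribute_assortativity(sub$graph, sub$membership)
      },
      stop("unknown statistic: ", statistic, call. = FALSE)
    )
    base_partition <- base_partition %||% clustering(graph, seeds[n_iterations + 1L])
    observed <- stat_fun(graph, base_partition)
    null_scores <- vapply(seq_len(n_iterations), function(i) {
      tryCatch({
        g_i <- rewire_preserving_degrees(graph, swap_factor,
                                         seed = seeds[i])
        p_i <- clustering(g_i, seeds[i])
        if (n_communities(p_i) == 0) return(failure_value)
        stat_fun(g_i, p_i)
      }, error = function(e) failure_value)
    }, numeric(1))
    name <- statistic_name %||%
      (if (is.character(statistic)) statistic else "statistic")
  }

  s <- sd(null_scores)
  structure(
    list(
      observed = observed,
      null_scores = null_scores,
      p_boot = boot_p(observed, null_scores, alternative),
      ci_low = observed - 1.96 * s,
      ci_high = observed + 1.96 * s,
      statistic_name = name,
      n_iterations = n_iterations,
      alternative = alternative,
      seed = seed
    ),
    class = "null_result"
  )
}

#' @export
print.null_result <- function(x, ...) {
  p_str <- if (x$p_boot == 0) sprintf("< %.4g", 1 / x$n_iterations) else
    sprintf("= %.4g", x$p_boot)
  cat(sprintf(
    "<null_result> %s = %.4f, 95%% CI [%.4f, %.4f], bootstrapped p %s (%d rewires)\n",
    x$statistic_name, x$observed, x$ci_low, x$ci_high, p_str, x$n_iterations
  ))
  invisible(x)
}

#' Serialize a null result to JSON (and optionally its null sample to CSV)
#'
#' @param result a [null_distribution()] result.
#' @param path JSON output path.
#' @param null_csv optional CSV path for the full null sample (audit trail).
#' @export
write_null_result <- function(result, path, null_csv = NULL) {
  obj <- result[c("observed", "p_boot", "ci_low", "ci_high",
                  "statistic_name", "n_iterations", "alternative")]
  obj$seed <- result$seed
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(null_csv)) {
    write.csv(data.frame(null_score = result$null_scores), null_csv,
              row.names = FALSE)
  }
  invisible(path)
}
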