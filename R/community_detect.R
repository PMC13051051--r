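#' Weighted label-propagation clustering
#'
#' Asynchronous label propagation on the weighted graph: nodes repeatedly
#' adopt the label with the largest total incident edge weight among their
#' neighbours, in random order with random tie-breaks, until every label is
#' locally maximal. Suited to finding the coarse community structure of very
#' large graphs. Deterministic given `seed`.
#'
#' @param graph a weighted undirected engagement graph.
#' @param seed RNG seed controlling sweep order and tie-breaks.
#' @return A [new_partition()] with algorithm `"label_propagation"`.
#' @export
label_propagation <- function(graph, seed = NULL) {
  if (vcount(graph) == 0) {
    return(new_partition(setNames(integer(0), character(0)),
                         "label_propagation", seed))
  }
  w <- E(graph)$weight %||% rep(1, ecount(graph))
  cl <- with_seed(seed, cluster_label_prop(graph, weights = w))
  m <- membership(cl)
  new_partition(setNames(as.integer(m), V(graph)$name),
                "label_propagation", seed)
}

#' Fast-greedy (agglomerative) modularity clustering
#'
#' Weighted Clauset-Newman-Moore agglomeration: starting from singletons,
#' repeatedly merge the community pair with the largest modularity gain and
#' return the dendrogram cut with maximal modularity. More sensitive than
#' label propagation, hence suited to sub-community detection. Deterministic
#' (no RNG); ties are resolved by the agglomeration order of the underlying
#' igraph implementation.
#'
#' The maximal-modularity cut is located by scanning the merge history
#' directly, because the cut igraph itself reports is not always the
#' argmax of its own modularity trace.
#'
#' @param graph a weighted undirected engagement graph.
#' @return A [new_partition()] with algorithm `"greedy_modularity"`.
#' @export
greedy_modularity <- function(graph) {
  n <- vcount(graph)
  if (n == 0) {
    return(new_partition(setNames(integer(0), character(0)),
                         "greedy_modularity"))
  }
  if (ecount(graph) == 0) {
    return(new_partition(setNames(seq_len(n), V(graph)$name),
                         "greedy_modularity"))
  }
  w <- E(graph)$weight %||% rep(1, ecount(graph))
  fg <- cluster_fast_greedy(graph, weights = w)
  best <- which.max(fg$modularity)
  m <- cut_at(fg, no = n - best + 1)
  new_partition(setNames(as.integer(m), V(graph)$name), "greedy_modularity")
}

#' Remove communities below a population fraction
#'
#' Communities holding strictly fewer than `min_frac` of the graph's nodes
#' are dropped; their members become unassigned (`NA`) and are excluded from
#' downstream community statistics. The boundary is strict: a community of
#' exactly `min_frac * n` nodes is kept.
#'
#' @param partition a [new_partition()] covering the graph's nodes.
#' @param graph the graph the partition was detected on.
#' @param min_frac minimum population fraction (default 0.01).
#' @return The filtered partition; dropped community ids in attribute
#'   `dropped`.
#' @export
filter_small_communities <- function(partition, graph, min_frac = 0.01) {
  stopifnot(inherits(partition, "partition"))
  if (!is_scalar_num(min_frac) || min_frac < 0 || min_frac > 1) {
    stop("min_frac must lie in [0, 1]", call. = FALSE)
  }
  sizes <- community_sizes(partition)
  cutoff <- min_frac * vcount(graph)
  drop <- names(sizes)[sizes < cutoff]
  m <- partition$membership
  m[as.character(m) %in% drop] <- NA
  out <- new_partition(m, partition$algorithm, partition$seed)
  attr(out, "dropped") <- drop
  out
}

#' Overlap rate of a reference community against a partition
#'
#' `o(A)` measures how well a reference member set `A` is recovered by a
#' partition: the average of (1) the largest fraction of `A` captured by any
#' single community and (2) the largest fraction of any single community
#' lying inside `A`. The two maxima are taken independently and may be
#' achieved by different communities. `o(A) = 1` exactly when some community
#' equals `A`.
#'
#' @param reference non-empty character vector of member agent ids.
#' @param partition a [new_partition()].
#' @return Overlap rate in `[0, 1]`.
#' @export
overlap_rate <- function(reference, partition) {
  if (!length(reference)) stop("reference community is empty", call. = FALSE)
  comms <- community_members(partition)
  if (!length(comms)) return(0)
  inter <- vapply(comms, function(B) length(intersect(reference, B)),
                  numeric(1))
  term1 <- max(inter / length(reference))
  term2 <- max(inter / lengths(comms))
  (term1 + term2) / 2
}

#' Community consistency check by repeated re-clustering
#'
#' Re-runs the clustering algorithm `n_iterations` times with fresh seeds
#' and scores every base community `A` by its mean [overlap_rate()] against
#' the (unfiltered) partition of each iteration. Communities with mean
#' overlap at or above `threshold` are flagged consistent; the rest are
#' treated as artefacts of the clustering algorithm.
#'
#' @param graph the graph the base partition was detected on.
#' @param base_partition the partition whose communities are scored.
#' @param algorithm `"label_propagation"` or `"greedy_modularity"`.
#' @param n_iterations number of re-clustering runs (default 1000).
#' @param threshold minimum mean overlap to keep a community (default 0.80).
#' @param seed RNG seed from which per-iteration seeds are derived.
#' @return An object of class `consistency_report`: data.frame
#'   (`community`, `size`, `mean_overlap`, `kept`) plus fields
#'   `n_iterations`, `threshold`, `kept` (ids).
#' @export
consistency_check <- function(graph, base_partition,
                              algorithm = c("label_propagation",
                                            "greedy_modularity"),
                              n_iterations = 1000, threshold = 0.80,
                              seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (!is_count(n_iterations)) {
    stop("n_iterations must be >= 1", call. = FALSE)
  }
  base <- community_members(base_partition)
  if (!length(base)) {
    rep0 <- structure(
      list(table = data.frame(community = character(0), size = integer(0),
                              mean_overlap = numeric(0), kept = logical(0)),
           n_iterations = n_iterations, threshold = threshold,
           kept = character(0)),
      class = "consistency_report"
    )
    return(rep0)
  }
  seeds <- derive_seeds(seed %||% 1L, n_iterations)
  acc <- setNames(numeric(length(base)), names(base))
  for (i in seq_len(n_iterations)) {
    p_i <- switch(algorithm,
      label_propagation = label_propagation(graph, seed = seeds[i]),
      greedy_modularity = greedy_modularity(graph)
    )
    for (a in names(base)) {
      acc[a] <- acc[a] + overlap_rate(base[[a]], p_i)
    }
  }
  mean_overlap <- acc / n_iterations
  tab <- data.frame(
    community = names(base),
    size = lengths(base)[names(base)],
    mean_overlap = as.vector(mean_overlap),
    kept = as.vector(mean_overlap >= threshold),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(
    list(table = tab, n_iterations = n_iterations, threshold = threshold,
         kept = tab$community[tab$kept]),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> %d communities, %d kept (o >= %.2f over %d iterations)\n",
              nrow(x$table), length(x$kept), x$threshold, x$n_iterations))
  print(x$table)
  invisible(x)
}

#' Restrict a partition to its consistent communities
#'
#' @param partition a [new_partition()].
#' @param report the matching [consistency_check()] report.
#' @return Partition with members of non-kept communities unassigned.
#' @export
keep_consistent <- function(partition, report) {
  stopifnot(inherits(report, "consistency_report"))
  m <- partition$membership
  m[!(as.character(m) %in% report$kept)] <- NA
  new_partition(m, partition$algorithm, partition$seed)
}

#' Write a consistency report as CSV
#'
#' @param report a [consistency_check()] report.
#' @param path output file.
#' @export
write_consistency <- function(report, path) {
  write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
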