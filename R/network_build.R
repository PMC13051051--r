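#' Build a cumulative weighted undirected engagement graph
#'
#' Collapses all engagement events up to (and including) `day_cutoff` into an
#' undirected graph where the weight of edge `{a, b}` is the total number of
#' events between `a` and `b` in either direction and of any type
#' (engagement frequency). Per-type counts are retained as edge attributes
#' `n_follow`, `n_like`, `n_dislike`, `n_mention` for diagnostics. Agents
#' with no event up to the cutoff do not appear.
#'
#' @param events data.frame with columns `day` (integer >= 1), `source`,
#'   `target` (agent ids), `type` (follow / like / dislike / mention).
#' @param day_cutoff inclusive last day (>= 1).
#' @param agents optional agents data.frame (`agent_id`, `language`, ...);
#'   matched attributes are attached to vertices.
#' @return An `igraph` graph with edge attribute `weight` and graph
#'   attribute `day_cutoff`.
#' @export
build_graph <- function(events, day_cutoff, agents = NULL) {
  if (!is_count(day_cutoff)) {
    stop("day_cutoff must be an integer >= 1", call. = FALSE)
  }
  validate_events(events)
  ev <- events[events$day <= day_cutoff, , drop = FALSE]
  if (!nrow(ev)) {
    g <- make_empty_graph(0, directed = FALSE)
    return(set_graph_attr(g, "day_cutoff", as.integer(day_cutoff)))
  }
  dt <- data.table::data.table(
    a = pmin(ev$source, ev$target),
    b = pmax(ev$source, ev$target),
    type = ev$type
  )
  agg <- dt[, list(
    weight = .N,
    n_follow = sum(type == "follow"),
    n_like = sum(type == "like"),
    n_dislike = sum(type == "dislike"),
    n_mention = sum(type == "mention")
  ), by = c("a", "b")]
  data.table::setorder(agg, a, b)
  g <- graph_from_data_frame(as.data.frame(agg), directed = FALSE)
  g <- set_graph_attr(g, "day_cutoff", as.integer(day_cutoff))
  if (!is.null(agents)) {
    idx <- match(V(g)$name, agents$agent_id)
    for (col in setdiff(names(agents), "agent_id")) {
      g <- set_vertex_attr(g, col, value = agents[[col]][idx])
    }
  }
  g
}

validate_events <- function(events) {
  need <- c("day", "source", "target", "type")
  missing <- setdiff(need, names(events))
  if (length(missing)) {
    stop("events lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(
    is.na(events$day) | events$day < 1 |
      is.na(events$source) | is.na(events$target) |
      events$source == events$target |
      !(events$type %in% c("follow", "like", "dislike", "mention"))
  )
  if (length(bad)) {
    stop(sprintf("malformed event record at line %d", bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Remove weakly engaged agents
#'
#' Drops every node engaged with fewer than `min_neighbors` distinct other
#' agents, in a single pass over the input graph: degrees are evaluated on
#' the input, survivors keep only edges among themselves, and the (possibly
#' lower) resulting degrees are not re-tested. Set `iterate = TRUE` to
#' repeat until a fixpoint (the `min_neighbors`-core).
#'
#' @param graph an engagement graph.
#' @param min_neighbors minimum number of distinct neighbours (default 2).
#' @param iterate repeat the pass until no node is removed.
#' @return The induced subgraph on surviving nodes.
#' @export
prune_low_degree <- function(graph, min_neighbors = 2, iterate = FALSE) {
  if (!is_count(min_neighbors, min = 0L)) {
    stop("min_neighbors must be a non-negative integer", call. = FALSE)
  }
  repeat {
    keep <- degree(graph) >= min_neighbors
    out <- induced_subgraph(graph, which(keep))
    if (!iterate || all(keep)) return(out)
    graph <- out
  }
}

#' Write / read engagement graphs
#'
#' Edge lists as TSV (`source`, `target`, `weight`); full graphs as GraphML
#' via igraph.
#'
#' @param graph an engagement graph.
#' @param path output file.
#' @export
write_edgelist <- function(graph, path) {
  el <- as_edgelist(graph)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   weight = E(graph)$weight %||% rep(1, ecount(graph)),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  graph_from_data_frame(df, directed = FALSE)
}

#' @rdname write_edgelist
#' @export
write_graphml <- function(graph, path) {
  write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_graphml <- function(path) {
  read_graph(path, format = "graphml")
}
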