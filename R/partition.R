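#' Community partitions
#'
#' A `partition` stores a node-to-community assignment produced by one of the
#' clustering routines ([label_propagation()], [greedy_modularity()]), by the
#' synthetic ground truth ([planted_partition()]), or by
#' [filter_small_communities()]. Members of communities removed by size
#' filtering are marked unassigned (`NA`) rather than dropped, so the original
#' node universe is preserved.
#'
#' @param membership named vector; names are agent ids, values community ids
#'   (`NA` = unassigned).
#' @param algorithm character scalar, one of `"label_propagation"`,
#'   `"greedy_modularity"`, `"planted"`, or `"fixed"`.
#' @param seed RNG seed the partition was produced under, or `NULL`.
#' @return An object of class `partition`.
#' @export
new_partition <- function(membership, algorithm, seed = NULL) {
  if (length(membership) && is.null(names(membership))) {
    stop("membership must be a named vector (names = agent ids)", call. = FALSE)
  }
  if (anyDuplicated(names(membership))) {
    stop("membership names must be unique agent ids", call. = FALSE)
  }
  structure(
    list(membership = membership, algorithm = algorithm, seed = seed),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  comms <- community_members(x)
  cat(sprintf(
    "<partition> %d nodes, %d communities (%d unassigned), algorithm = %s\n",
    length(x$membership), length(comms),
    sum(is.na(x$membership)), x$algorithm
  ))
  invisible(x)
}

#' List community member sets
#'
#' @param partition a [new_partition()] object.
#' @return Named list mapping community id to a character vector of member
#'   agent ids. Unassigned nodes are excluded.
#' @export
community_members <- function(partition) {
  stopifnot(inherits(partition, "partition"))
  m <- partition$membership
  m <- m[!is.na(m)]
  if (!length(m)) return(structure(list(), names = character(0)))
  split(names(m), as.character(m))
}

#' Community sizes
#'
#' @inheritParams community_members
#' @return Named integer vector of community sizes.
#' @export
community_sizes <- function(partition) {
  lengths(community_members(partition))
}

#' Number of detected communities
#'
#' @inheritParams community_members
#' @return Integer count of communities with at least one assigned member.
#' @export
n_communities <- function(partition) {
  length(community_members(partition))
}

#' Read/write a partition as two-column CSV (agent_id, community_id)
#'
#' @param partition a `partition` object.
#' @param path file path.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "partition"))
  df <- data.frame(
    agent_id = names(partition$membership),
    community_id = as.vector(partition$membership),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @param algorithm algorithm label recorded on the read partition.
#' @export
read_partition <- function(path, algorithm = "fixed") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  new_partition(setNames(df$community_id, df$agent_id), algorithm)
}
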