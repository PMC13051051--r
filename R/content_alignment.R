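#' Clean post text
#'
#' Removes every character outside roman letters, digits and whitespace
#' (punctuation and non-roman scripts are deleted, not replaced), collapses
#' runs of whitespace to single spaces, and trims.
#'
#' @param raw character vector of raw text (possibly empty).
#' @return Cleaned character vector.
#' @export
clean_text <- function(raw) {
  x <- gsub("[^A-Za-z0-9 \t\r\n]", "", raw, perl = TRUE)
  x <- gsub("[ \t\r\n]+", " ", x)
  trimws(x)
}

#' Offline hashing text encoder
#'
#' A deterministic, dependency-free stand-in for a pretrained sentence
#' encoder: tokens are hashed into `vocab` count buckets and projected to
#' `dim` dimensions by a seeded Gaussian random matrix
#' (Johnson-Lindenstrauss style), then L2-normalised. Adequate for testing
#' every downstream geometric analysis; it captures token overlap, not
#' meaning. A production adapter can be any function with the same
#' `f(texts) -> matrix` contract (one row per text, fixed width).
#'
#' @param dim embedding dimension.
#' @param vocab number of hash buckets; keep it prime so the
#'   multiplicative hash does not alias structured token sets.
#' @param seed seed for the projection matrix.
#' @return A function mapping a character vector to a `length(x) x dim`
#'   matrix with unit-norm rows (zero rows for empty texts).
#' @export
hash_encoder <- function(dim = 64, vocab = 509L, seed = 1L) {
  proj <- with_seed(seed,
                    matrix(rnorm(vocab * dim), nrow = vocab, ncol = dim))
  force(dim); force(vocab)
  function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      toks <- strsplit(texts[i], " ", fixed = TRUE)[[1]]
      toks <- toks[nzchar(toks)]
      if (!length(toks)) next
      h <- vapply(toks, hash_token, integer(1), vocab = vocab)
      counts <- tabulate(h, nbins = vocab)
      v <- as.vector(counts %*% proj)
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) out[i, ] <- v / nrm
    }
    out
  }
}

hash_token <- function(token, vocab) {
  h <- 0
  for (code in utf8ToInt(token)) h <- (h * 31 + code) %% vocab
  as.integer(h) + 1L
}

#' Embed agents' posts
#'
#' Cleans and concatenates each agent's posts and encodes them into one
#' unit-norm embedding per agent. Agents whose cleaned text is empty are
#' excluded (with a warning) since they carry no semantic signal.
#'
#' @param posts named list (by agent id) of character vectors of posts.
#' @param encoder a `f(texts) -> matrix` text encoder; default
#'   [hash_encoder()].
#' @return Matrix of embeddings, rows named by agent id, unit L2 norm.
#' @export
embed_agents <- function(posts, encoder = hash_encoder()) {
  if (is.null(names(posts))) stop("posts must be named by agent id",
                                  call. = FALSE)
  text <- vapply(posts, function(p) clean_text(paste(p, collapse = " ")),
                 character(1))
  empty <- !nzchar(text)
  if (any(empty)) {
    warning(sprintf("%d agent(s) with empty cleaned text excluded",
                    sum(empty)))
  }
  text <- text[!empty]
  emb <- encoder(unname(text))
  nrm <- sqrt(rowSums(emb^2))
  emb <- emb / ifelse(nrm > 0, nrm, 1)
  rownames(emb) <- names(text)
  emb
}

#' Cosine distance between two vectors
#'
#' `1 - u.v / (|u||v|)`, in `[0, 2]`; the standard semantic dissimilarity
#' between embeddings.
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return Cosine distance.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for zero vectors",
                               call. = FALSE)
  1 - sum(u * v) / (nu * nv)
}

#' Community-attribute contingency test
#'
#' Pearson chi-squared test of independence on the community x category
#' count table over assigned agents, with Cramer's V
#' (`sqrt(chi2 / (N (min(R,C) - 1)))`) as effect size. Zero-margin rows or
#' columns are dropped with a warning before testing.
#'
#' @param partition a [new_partition()]; unassigned agents are excluded.
#' @param labels named vector mapping agent id to category.
#' @return Object of class `contingency_result`: `chi2`, `df`, `p`,
#'   `cramers_v`, `n`, `table`.
#' @export
contingency_alignment <- function(partition, labels) {
  m <- as_membership_vector(partition)
  m <- m[!is.na(m)]
  ids <- intersect(names(m), names(labels))
  if (!length(ids)) stop("no assigned, labelled agents", call. = FALSE)
  tab <- table(community = as.character(m[ids]),
               category = as.character(labels[ids]))
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero-margin rows/columns from the contingency table")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("contingency test needs >= 2 communities and >= 2 categories",
         call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  chi2 <- unname(ct$statistic)
  structure(
    list(
      chi2 = chi2,
      df = unname(ct$parameter),
      p = ct$p.value,
      cramers_v = sqrt(chi2 / (n * (min(dim(tab)) - 1))),
      n = n,
      table = tab
    ),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf(
    "<contingency_result> chi2(%d, N = %d) = %.2f, Cramer's V = %.2f, p %s\n",
    x$df, x$n, x$chi2, x$cramers_v,
    if (x$p < .001) "< .001" else sprintf("= %.3g", x$p)
  ))
  invisible(x)
}

#' Centroid-distance paired test
#'
#' For every agent in a kept community, compares its cosine distance to its
#' community's mean embedding (`d_comm`) with its distance to the mean
#' embedding of all agents in scope (`d_glob`) by a paired t-test on
#' `d_comm - d_glob`; negative `t` means agents post more similarly to
#' their community than to the population. Cohen's `d = t / sqrt(n)`
#' (paired design). Centroids include the focal agent; `leave_one_out =
#' TRUE` excludes it. Communities of size 1 are excluded with a warning
#' (their centroid is the agent itself).
#'
#' @param embeddings matrix of unit-norm embeddings, rows named by agent id;
#'   its rows define the population scope for the global centroid.
#' @param partition a [new_partition()] restricted to consistent
#'   communities (unassigned agents are not tested but do contribute to the
#'   global centroid).
#' @param leave_one_out exclude the focal agent from its community centroid.
#' @return Object of class `centroid_test_result`: `t`, `df`, `p`,
#'   `cohens_d`, `ci_d`, `n`, `mean_d_comm`, `mean_d_glob`, `degenerate`.
#' @export
centroid_distance_test <- function(embeddings, partition,
                                   leave_one_out = FALSE) {
  m <- as_membership_vector(partition)
  m <- m[!is.na(m)]
  ids <- intersect(names(m), rownames(embeddings))
  comms <- split(ids, as.character(m[ids]))
  singles <- lengths(comms) < 2
  if (any(singles)) {
    warning(sprintf("%d community(ies) of size 1 excluded", sum(singles)))
    comms <- comms[!singles]
  }
  if (!length(comms)) stop("no testable communities", call. = FALSE)
  glob <- colMeans(embeddings)
  d_comm <- numeric(0); d_glob <- numeric(0)
  for (members in comms) {
    sub <- embeddings[members, , drop = FALSE]
    cen <- colMeans(sub)
    for (i in seq_along(members)) {
      u <- sub[i, ]
      c_i <- if (leave_one_out) {
        (cen * length(members) - u) / (length(members) - 1)
      } else cen
      d_comm <- c(d_comm, cosine_distance(u, c_i))
      d_glob <- c(d_glob, cosine_distance(u, glob))
    }
  }
  n <- length(d_comm)
  diffs <- d_comm - d_glob
  if (sd(diffs) == 0) {
    return(structure(
      list(t = NA_real_, df = n - 1L, p = NA_real_, cohens_d = 0,
           ci_d = c(0, 0), n = n, mean_d_comm = mean(d_comm),
           mean_d_glob = mean(d_glob), degenerate = TRUE),
      class = "centroid_test_result"
    ))
  }
  tt <- t.test(d_comm, d_glob, paired = TRUE)
  t_val <- unname(tt$statistic)
  d <- t_val / sqrt(n)
  structure(
    list(t = t_val, df = unname(tt$parameter), p = tt$p.value,
         cohens_d = d, ci_d = c(d - 1.96 / sqrt(n), d + 1.96 / sqrt(n)),
         n = n, mean_d_comm = mean(d_comm), mean_d_glob = mean(d_glob),
         degenerate = FALSE),
    class = "centroid_test_result"
  )
}

#' @export
print.centroid_test_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<centroid_test_result> degenerate (zero variance), d = 0\n")
  } else {
    cat(sprintf(
      "<centroid_test_result> t(%d) = %.2f, p %s, Cohen's d = %.2f\n",
      x$df, x$t, if (x$p < .001) "< .001" else sprintf("= %.3g", x$p),
      x$cohens_d
    ))
  }
  invisible(x)
}

#' Pairwise cosine distances grouped by engagement count
#'
#' Groups agent pairs by their engagement frequency (edge weight; absent
#' edge = 0 engagements) into bins 0, 1, 2, 3, 4 and 5-or-more, and reports
#' the mean pairwise cosine distance per bin with a normal-approximation
#' 95% CI (`+/- 1.96 SE`). The 0-engagement bin is uniformly subsampled to
#' `max_zero_pairs` pairs when larger (seeded), since it grows
#' quadratically with population size.
#'
#' @param graph engagement graph (edge weight = engagement count).
#' @param embeddings unit-norm embedding matrix, rows named by agent id;
#'   every graph node must be embedded.
#' @param max_zero_pairs cap on sampled 0-engagement pairs (default 1e6).
#' @param seed seed for the 0-bin subsample.
#' @return data.frame with columns `bin`, `n_pairs`, `mean_distance`,
#'   `ci_low`, `ci_high`.
#' @export
distance_by_engagement_bins <- function(graph, embeddings,
                                        max_zero_pairs = 1e6, seed = NULL) {
  graph <- ensure_named(graph)
  nodes <- V(graph)$name
  if (!all(nodes %in% rownames(embeddings))) {
    stop("every graph node must have an embedding", call. = FALSE)
  }
  emb <- embeddings[nodes, , drop = FALSE]
  n <- length(nodes)
  el <- as_edgelist(graph, names = FALSE)
  w <- E(graph)$weight %||% rep(1, ecount(graph))

  pair_dist <- function(i, j) {
    1 - rowSums(emb[i, , drop = FALSE] * emb[j, , drop = FALSE])
  }

  bins <- c("0", "1", "2", "3", "4", "5+")
  bin_of <- function(wt) ifelse(wt >= 5, "5+", as.character(wt))

  # engaged pairs straight from the edge list
  d_edge <- pair_dist(el[, 1], el[, 2])
  b_edge <- bin_of(w)

  # 0-engagement pairs: enumerate when tractable, else rejection-sample
  n_total_pairs <- n * (n - 1) / 2
  n_zero <- n_total_pairs - nrow(el)
  d_zero <- numeric(0)
  if (n_zero > 0) {
    edge_key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    target <- min(n_zero, max_zero_pairs)
    d_zero <- with_seed(seed, {
      if (n_total_pairs <= 4e6) {
        idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
        key <- paste(idx[, 1], idx[, 2])
        zero_idx <- idx[!(key %in% edge_key), , drop = FALSE]
        if (nrow(zero_idx) > target) {
          zero_idx <- zero_idx[sample.int(nrow(zero_idx), target), ,
                               drop = FALSE]
        }
        pair_dist(zero_idx[, 1], zero_idx[, 2])
      } else {
        got <- numeric(0)
        while (length(got) < target) {
          i <- sample.int(n, 2 * target, replace = TRUE)
          j <- sample.int(n, 2 * target, replace = TRUE)
          ok <- i != j
          key <- paste(pmin(i, j), pmax(i, j))
          ok <- ok & !(key %in% edge_key) & !duplicated(key)
          got <- c(got, pair_dist(i[ok], j[ok]))
        }
        got[seq_len(target)]
      }
    })
  }

  all_d <- c(d_zero, d_edge)
  all_b <- c(rep("0", length(d_zero)), b_edge)
  out <- do.call(rbind, lapply(bins, function(b) {
    d <- all_d[all_b == b]
    if (!length(d)) {
      data.frame(bin = b, n_pairs = 0L, mean_distance = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_)
    } else {
      se <- if (length(d) > 1) sd(d) / sqrt(length(d)) else 0
      data.frame(bin = b, n_pairs = length(d), mean_distance = mean(d),
                 ci_low = mean(d) - 1.96 * se,
                 ci_high = mean(d) + 1.96 * se)
    }
  }))
  rownames(out) <- NULL
  out
}

#' MRQAP correlation between two dyadic matrices
#'
#' Pearson correlation between the off-diagonal dyads of an engagement
#' frequency matrix and a distance matrix, with significance by the
#' quadratic assignment procedure: rows and columns of the distance matrix
#' are permuted by the same random node relabelling, and the two-sided p is
#' the share of permutations with `|r_perm| >= |r|` (floored at
#' `1/n_permutations`). The confidence interval is a dyadic-bootstrap
#' percentile interval (dyads resampled with replacement), recorded as
#' `ci_method` in the result.
#'
#' @param weight_matrix,distance_matrix square symmetric numeric matrices in
#'   identical node order, `n >= 4`.
#' @param n_permutations QAP permutations (default 1000).
#' @param n_boot dyadic bootstrap replicates for the CI (default 500).
#' @param seed RNG seed.
#' @return Object of class `qap_result`: `r`, `p`, `ci`, `n_permutations`,
#'   `n_nodes`, `ci_method`.
#' @export
mrqap_correlation <- function(weight_matrix, distance_matrix,
                              n_permutations = 1000, n_boot = 500,
                              seed = NULL) {
  n <- nrow(weight_matrix)
  if (n < 4 || ncol(weight_matrix) != n ||
      !all(dim(distance_matrix) == c(n, n))) {
    stop("matrices must be square, same order, n >= 4", call. = FALSE)
  }
  if (max(abs(weight_matrix - t(weight_matrix))) > 1e-9 ||
      max(abs(distance_matrix - t(distance_matrix))) > 1e-9) {
    stop("matrices must be symmetric", call. = FALSE)
  }
  off <- upper.tri(weight_matrix)
  x <- weight_matrix[off]
  if (sd(x) == 0 || sd(distance_matrix[off]) == 0) {
    stop("correlation undefined for a constant matrix", call. = FALSE)
  }
  r <- cor(x, distance_matrix[off])
  with_seed(seed, {
    perm_r <- vapply(seq_len(n_permutations), function(k) {
      p <- sample.int(n)
      cor(x, distance_matrix[p, p][off])
    }, numeric(1))
    count <- sum(abs(perm_r) >= abs(r))
    p_val <- max(count / n_permutations, 1 / n_permutations)
    ci <- if (n_boot > 0) {
      y <- distance_matrix[off]
      boot_r <- vapply(seq_len(n_boot), function(k) {
        idx <- sample.int(length(x), replace = TRUE)
        if (sd(x[idx]) == 0 || sd(y[idx]) == 0) return(NA_real_)
        cor(x[idx], y[idx])
      }, numeric(1))
      unname(quantile(boot_r, c(0.025, 0.975), na.rm = TRUE))
    } else c(NA_real_, NA_real_)
    structure(
      list(r = r, p = p_val, ci = ci, n_permutations = n_permutations,
           n_nodes = n, ci_method = "dyadic_bootstrap_percentile"),
      class = "qap_result"
    )
  })
}

#' @export
print.qap_result <- function(x, ...) {
  cat(sprintf(
    "<qap_result> r = %.4f, 95%% CI [%.4f, %.4f], QAP p %s (%d permutations)\n",
    x$r, x$ci[1], x$ci[2],
    if (x$p <= 1 / x$n_permutations) sprintf("<= %.4g", x$p) else
      sprintf("= %.4g", x$p),
    x$n_permutations
  ))
  invisible(x)
}

#' Engagement weight matrix of a graph
#'
#' Dense symmetric matrix of pairwise engagement counts, for MRQAP.
#'
#' @param graph engagement graph.
#' @param ids optional node order (default graph order).
#' @return Symmetric numeric matrix with dimnames.
#' @export
engagement_matrix <- function(graph, ids = NULL) {
  graph <- ensure_named(graph)
  ids <- ids %||% V(graph)$name
  if (!("weight" %in% edge_attr_names(graph))) {
    E(graph)$weight <- rep(1, ecount(graph))
  }
  m <- as.matrix(as_adjacency_matrix(graph, attr = "weight", sparse = TRUE))
  m[ids, ids]
}

#' Pairwise cosine-distance matrix of embeddings
#'
#' @param embeddings unit-norm embedding matrix with row names.
#' @param ids optional row order.
#' @return Symmetric distance matrix.
#' @export
cosine_distance_matrix <- function(embeddings, ids = NULL) {
  ids <- ids %||% rownames(embeddings)
  e <- embeddings[ids, , drop = FALSE]
  d <- 1 - tcrossprod(e)
  diag(d) <- 0
  d
}
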