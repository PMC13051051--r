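test_that("label propagation respects components and cliques", {
  g <- two_clique_graph(5, 5, bridge = FALSE)
  p <- label_propagation(g, seed = 1)
  expect_equal(n_communities(p), 2)
  expect_true(same_partition(
    p$membership,
    setNames(rep(1:2, each = 5), c(paste0("x", 1:5), paste0("y", 1:5)))
  ))
  single <- two_clique_graph(6, 2, bridge = FALSE)
  p1 <- label_propagation(igraph::induced_subgraph(single, paste0("x", 1:6)),
                          seed = 1)
  expect_equal(n_communities(p1), 1)
})

test_that("label propagation is seed-deterministic and finds bridged cliques", {
  g <- two_clique_graph(6, 6)
  expect_identical(label_propagation(g, seed = 7)$membership,
                   label_propagation(g, seed = 7)$membership)
  expected <- setNames(rep(1:2, each = 6),
                       c(paste0("x", 1:6), paste0("y", 1:6)))
  hits <- sum(vapply(1:100, function(s) {
    same_partition(label_propagation(g, seed = s)$membership, expected)
  }, logical(1)))
  expect_gte(hits, 95)
})

test_that("greedy modularity matches exhaustive search on small graphs", {
  # two 4-cliques + bridge: oracle enumerates all partitions of 8 nodes
  g <- two_clique_graph(4, 4)
  oracle <- best_partition_oracle(g)
  p <- greedy_modularity(g)
  expect_true(same_partition(p$membership, oracle$membership))
  expect_equal(modularity_weighted(g, p), oracle$q, tolerance = 1e-12)

  # K5: the best achievable modularity is 0 (single community)
  k5 <- el_graph(utils::combn(paste0("v", 1:5), 2)[1, ],
                 utils::combn(paste0("v", 1:5), 2)[2, ])
  ok5 <- best_partition_oracle(k5)
  pk5 <- greedy_modularity(k5)
  expect_equal(modularity_weighted(k5, pk5), ok5$q, tolerance = 1e-12)
  expect_equal(n_communities(pk5), 1)
})

test_that("greedy modularity handles degenerate graphs", {
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- c("a", "b", "c")
  p <- greedy_modularity(g0)
  expect_equal(n_communities(p), 3)
  expect_equal(n_communities(greedy_modularity(
    igraph::make_empty_graph(0, directed = FALSE))), 0)
})

test_that("clustering partitions are disjoint covers and Q cross-checks", {
  for (s in 1:5) {
    g <- random_weighted_graph(30, 0.15, seed = s)
    for (p in list(label_propagation(g, seed = s), greedy_modularity(g))) {
      expect_setequal(names(p$membership), igraph::V(g)$name)
      expect_false(anyNA(p$membership))
      # ids partition the node set
      expect_equal(sum(community_sizes(p)), igraph::vcount(g))
      # package modularity agrees with the brute-force oracle
      expect_equal(modularity_weighted(g, p),
                   modularity_oracle(g, p$membership), tolerance = 1e-12)
    }
  }
})

test_that("filter_small_communities applies a strict < threshold", {
  mk <- function(sizes) {
    ids <- paste0("a", seq_len(sum(sizes)))
    g <- igraph::make_ring(sum(sizes))
    igraph::V(g)$name <- ids
    igraph::E(g)$weight <- 1
    p <- new_partition(setNames(rep(seq_along(sizes), sizes), ids), "planted")
    list(g = g, p = p)
  }
  x <- mk(c(600, 390, 10))
  f <- filter_small_communities(x$p, x$g, 0.01)
  expect_equal(sort(unname(community_sizes(f))), c(10, 390, 600)) # 10 >= 10 kept
  y <- mk(c(600, 391, 9))
  f2 <- filter_small_communities(y$p, y$g, 0.01)
  expect_equal(sort(unname(community_sizes(f2))), c(391, 600))
  expect_equal(attr(f2, "dropped"), "3")
  expect_equal(sum(is.na(f2$membership)), 9)
  # min_frac = 0 keeps everything
  f3 <- filter_small_communities(y$p, y$g, 0)
  expect_identical(f3$membership, y$p$membership)
  # everything below threshold -> "no communities found"
  f4 <- filter_small_communities(y$p, y$g, 0.9)
  expect_equal(n_communities(f4), 0)
  expect_error(filter_small_communities(y$p, y$g, 1.5), "min_frac")
})

test_that("overlap_rate implements the two independent maxima", {
  A <- as.character(1:10)
  exact <- new_partition(setNames(c(rep("c1", 10), rep("c2", 5)),
                                  as.character(1:15)), "planted")
  expect_equal(overlap_rate(A, exact), 1)
  # A split into two clean halves: term1 = 0.5, term2 = 1 -> 0.75
  split2 <- new_partition(setNames(c(rep("l", 5), rep("r", 5)), A), "planted")
  expect_equal(overlap_rate(A, split2), 0.75)
  # A inside a community twice its size: term1 = 1, term2 = 0.5 -> 0.75
  big <- new_partition(setNames(rep("b", 20), as.character(1:20)), "planted")
  expect_equal(overlap_rate(A, big), 0.75)
  # relabelling invariance
  relab <- new_partition(setNames(c(rep("z9", 5), rep("q", 5)), A), "planted")
  expect_equal(overlap_rate(A, relab), overlap_rate(A, split2))
  # o = 1 iff the reference appears verbatim
  almost <- new_partition(setNames(c(rep("c", 9), "d", rep("c", 0)),
                                   as.character(1:10)), "planted")
  expect_lt(overlap_rate(A, almost), 1)
  expect_error(overlap_rate(character(0), exact), "empty")
})

test_that("consistency_check keeps stable communities and flags unstable ones", {
  # deterministic greedy: every overlap is exactly 1
  g <- two_clique_graph(5, 5)
  base <- greedy_modularity(g)
  rep1 <- consistency_check(g, base, "greedy_modularity", n_iterations = 5,
                            seed = 1)
  expect_true(all(rep1$table$mean_overlap == 1))
  expect_setequal(rep1$kept, names(community_members(base)))

  # strongly separated planted blocks survive label propagation reruns
  soc <- generate_society(society_config(
    n_agents = 200, language_props = c(en = 0.5, zh = 0.5),
    lang_homophily = 0.95, events_per_day = 1, seed = 8
  ))
  gs <- prune_low_degree(build_graph(soc$events, 28))
  bp <- label_propagation(gs, seed = 1)
  rep2 <- consistency_check(gs, bp, "label_propagation",
                            n_iterations = 50, threshold = 0.8, seed = 2)
  expect_gte(length(rep2$kept), 2)

  # a dense random graph clustered by LP is unstable: some o(A) < 1
  gr <- random_weighted_graph(60, 0.15, seed = 3)
  bpr <- label_propagation(gr, seed = 4)
  rep3 <- consistency_check(gr, bpr, "label_propagation",
                            n_iterations = 100, seed = 5)
  expect_true(any(rep3$table$mean_overlap < 1))
  expect_error(consistency_check(gr, bpr, n_iterations = 0), "n_iterations")
})

test_that("keep_consistent unassigns members of non-kept communities", {
  g <- two_clique_graph(5, 5)
  p <- greedy_modularity(g)
  rep1 <- consistency_check(g, p, "greedy_modularity", n_iterations = 2,
                            seed = 1)
  rep1$kept <- rep1$kept[1]
  k <- keep_consistent(p, rep1)
  expect_equal(n_communities(k), 1)
  expect_equal(sum(is.na(k$membership)), 5)
})
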