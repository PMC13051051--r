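test_that("clean_text strips non-roman characters and squeezes whitespace", {
  expect_equal(clean_text("Hello, world! 你好"), "Hello world")
  expect_equal(clean_text("a.b,c;d"), "abcd")
  expect_equal(clean_text("  x   y  "), "x y")
  expect_equal(clean_text(""), "")
  expect_equal(clean_text("Tabs\tand\nnewlines"), "Tabs and newlines")
  expect_equal(clean_text(c("a!", "b?")), c("a", "b"))
})

test_that("hash encoder is deterministic with unit-norm output", {
  enc <- hash_encoder(dim = 32, seed = 4)
  m1 <- enc(c("alpha beta gamma", "alpha beta gamma", "delta"))
  expect_identical(m1[1, ], m1[2, ])
  expect_false(identical(m1[1, ], m1[3, ]))
  expect_equal(unname(sqrt(rowSums(m1^2))), c(1, 1, 1), tolerance = 1e-9)
  # empty text -> zero row
  expect_equal(sum(enc("")^2), 0)
})

test_that("disjoint-token texts are near-orthogonal on average", {
  sims <- vapply(1:50, function(s) {
    enc <- hash_encoder(dim = 64, seed = s)
    m <- enc(c("aa bb cc dd ee ff gg hh", "ii jj kk ll mm nn oo pp"))
    sum(m[1, ] * m[2, ])
  }, numeric(1))
  expect_lt(abs(mean(sims)), 0.05)
})

test_that("embed_agents concatenates, cleans and excludes empty agents", {
  posts <- list(a1 = c("Hello, world!", "more words"),
                a2 = "你好吗",       # cleans to empty
                a3 = "plain text")
  expect_warning(emb <- embed_agents(posts), "excluded")
  expect_setequal(rownames(emb), c("a1", "a3"))
  expect_equal(unname(sqrt(rowSums(emb^2))), c(1, 1), tolerance = 1e-9)
  expect_error(embed_agents(unname(posts)), "named")
})

test_that("cosine_distance covers the exact geometry", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1), -c(1, 1)), 2)
  expect_equal(cosine_distance(c(2, 0), c(5, 0)), 0) # scale invariant
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero")
  expect_error(cosine_distance(c(1, 0), c(1, 0, 0)), "length")
})

test_that("contingency test matches closed-form Pearson arithmetic", {
  # diagonal 2x2 table [[10,0],[0,10]]: chi2 = 20, V = 1
  p <- new_partition(setNames(rep(c("c1", "c2"), each = 10),
                              paste0("a", 1:20)), "planted")
  labs <- setNames(rep(c("en", "zh"), each = 10), paste0("a", 1:20))
  res <- contingency_alignment(p, labs)
  expect_equal(res$chi2, 20, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$cramers_v, 1, tolerance = 1e-12)
  # uniform table: no association
  labs2 <- setNames(rep(c("en", "zh"), 10), paste0("a", 1:20))
  res2 <- contingency_alignment(p, labs2)
  expect_equal(res2$chi2, 0, tolerance = 1e-12)
  expect_equal(res2$cramers_v, 0, tolerance = 1e-12)
  expect_true(res2$p > 0.99)
})

test_that("contingency test is calibrated under independence", {
  set.seed(12)
  vs <- vapply(1:10, function(s) {
    ids <- paste0("a", 1:2000)
    p <- new_partition(setNames(sample(1:3, 2000, TRUE), ids), "planted")
    labs <- setNames(sample(c("en", "zh", "ja", "ot"), 2000, TRUE), ids)
    contingency_alignment(p, labs)$cramers_v
  }, numeric(1))
  expect_true(all(vs < 0.1))
})

test_that("degenerate contingency margins are dropped with a warning", {
  ids <- paste0("a", 1:30)
  p <- new_partition(setNames(rep(c("c1", "c2", "c3"), each = 10), ids),
                     "planted")
  labs <- setNames(c(rep("en", 10), rep("zh", 10), rep("en", 10)), ids)
  res <- contingency_alignment(p, labs) # fine: 3x2
  expect_equal(res$df, 2)
  # a community with no labelled members disappears from the table
  labs2 <- labs[1:20]
  res2 <- contingency_alignment(p, labs2)
  expect_equal(res2$n, 20)
  expect_error(
    contingency_alignment(p, setNames(rep("en", 30), ids)),
    ">= 2"
  )
})

test_that("centroid test: degenerate, planted and leave-one-out cases", {
  ids <- paste0("a", 1:12)
  same <- matrix(rep(c(1, 0, 0), each = 12), nrow = 12,
                 dimnames = list(ids, NULL))
  p <- new_partition(setNames(rep(c("c1", "c2"), each = 6), ids), "planted")
  res <- centroid_distance_test(same, p)
  expect_true(res$degenerate)
  expect_equal(res$cohens_d, 0)

  soc <- generate_society(society_config(
    n_agents = 300, language_props = c(en = 1), n_topics_per_language = 4,
    content_homophily = 4, noise_sd = 0.2, events_per_day = 0.8, seed = 14
  ))
  pt <- planted_partition(soc, "topic")
  res2 <- centroid_distance_test(soc$embeddings, pt)
  expect_lt(res2$t, 0)
  expect_lt(res2$cohens_d, 0)
  expect_equal(res2$cohens_d, res2$t / sqrt(res2$n), tolerance = 1e-12)
  expect_equal(res2$df, res2$n - 1)
  res3 <- centroid_distance_test(soc$embeddings, pt, leave_one_out = TRUE)
  # excluding the focal agent weakens (raises) the community-distance edge
  expect_gt(res3$t, res2$t)

  # singleton community members are excluded with a warning
  set.seed(77)
  emb12 <- matrix(rnorm(12 * 8), nrow = 12, dimnames = list(ids, NULL))
  emb12 <- emb12 / sqrt(rowSums(emb12^2))
  m <- setNames(c(rep("c1", 6), rep("c2", 5), "lone"), ids)
  expect_warning(
    res4 <- centroid_distance_test(emb12, new_partition(m, "planted")),
    "size 1"
  )
  expect_equal(res4$n, 11)
})

test_that("engagement bins follow the edge weights", {
  ids <- c("a", "b")
  emb <- matrix(c(1, 0, 0, 1), nrow = 2, byrow = TRUE,
                dimnames = list(ids, NULL))
  g <- el_graph("a", "b", w = 7)
  tab <- distance_by_engagement_bins(g, emb)
  expect_equal(tab$n_pairs[tab$bin == "5+"], 1)
  expect_equal(tab$mean_distance[tab$bin == "5+"], 1)
  expect_equal(sum(tab$n_pairs), 1) # no zero pairs with only 2 nodes
  expect_true(all(tab$n_pairs[tab$bin %in% c("0", "1", "2", "3", "4")] == 0))

  # weights 1..4 land in their own bins; absent pairs in bin 0
  ids2 <- paste0("n", 1:6)
  set.seed(3)
  emb2 <- matrix(rnorm(6 * 8), nrow = 6, dimnames = list(ids2, NULL))
  emb2 <- emb2 / sqrt(rowSums(emb2^2))
  g2 <- el_graph(c("n1", "n1", "n1", "n1"), c("n2", "n3", "n4", "n5"),
                 w = 1:4)
  tab2 <- distance_by_engagement_bins(g2, emb2, seed = 1)
  expect_equal(tab2$n_pairs[match(c("1", "2", "3", "4"), tab2$bin)],
               rep(1L, 4))
  # n6 never engages, so it is absent from the graph: 5 nodes, 4 edges
  expect_equal(tab2$n_pairs[tab2$bin == "0"], choose(5, 2) - 4)
  expect_true(all(tab2$ci_low <= tab2$mean_distance, na.rm = TRUE))

  # zero-bin subsampling caps the pair count deterministically
  tab3 <- distance_by_engagement_bins(g2, emb2, max_zero_pairs = 5, seed = 2)
  expect_equal(tab3$n_pairs[tab3$bin == "0"], 5)
  tab3b <- distance_by_engagement_bins(g2, emb2, max_zero_pairs = 5, seed = 2)
  expect_equal(tab3, tab3b)
})

test_that("mrqap detects perfect dependence and respects node order", {
  set.seed(8)
  n <- 12
  w <- matrix(rpois(n * n, 2), n)
  w <- w + t(w); diag(w) <- 0
  d_aff <- 2 - 0.1 * w # affine transform of w
  rownames(w) <- colnames(w) <- rownames(d_aff) <- colnames(d_aff) <-
    paste0("a", 1:n)
  q <- mrqap_correlation(w, d_aff, n_permutations = 100, seed = 1)
  expect_equal(abs(q$r), 1, tolerance = 1e-12)
  expect_equal(q$p, 1 / 100)
  # invariance under simultaneous reordering of both matrices
  perm <- sample(n)
  q2 <- mrqap_correlation(w[perm, perm], d_aff[perm, perm],
                          n_permutations = 100, seed = 1)
  expect_equal(q2$r, q$r, tolerance = 1e-12)
  expect_equal(q2$p, q$p)
  expect_error(mrqap_correlation(w, matrix(1, n, n)), "constant")
  expect_error(mrqap_correlation(w[1:3, 1:3], d_aff[1:3, 1:3]), "n >= 4")
  wa <- w; wa[1, 2] <- wa[1, 2] + 1
  expect_error(mrqap_correlation(wa, d_aff), "symmetric")
})

test_that("QAP p-values are roughly uniform under independence", {
  ps <- vapply(1:200, function(s) {
    set.seed(5000 + s)
    n <- 30
    mk <- function() {
      m <- matrix(rnorm(n * n), n)
      m <- m + t(m); diag(m) <- 0
      m
    }
    mrqap_correlation(mk(), mk(), n_permutations = 200, n_boot = 0,
                      seed = s)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(ps <= 0.05), 0.11)
})
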