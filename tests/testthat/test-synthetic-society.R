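test_that("society_config rejects invalid fields by name", {
  expect_error(society_config(n_agents = 0), "n_agents")
  expect_error(society_config(100, language_props = c(a = 0.5, b = 0.4)),
               "language_props")
  expect_error(society_config(100, lang_homophily = 1.2), "lang_homophily")
  expect_error(society_config(100, content_homophily = -1),
               "content_homophily")
  expect_error(society_config(100, embed_dim = 1), "embed_dim")
  expect_error(society_config(100, activity_shape = 0), "activity_shape")
})

test_that("generation is deterministic given the seed", {
  cfg <- society_config(n_agents = 80, seed = 42)
  s1 <- generate_society(cfg)
  s2 <- generate_society(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$agents, s2$agents)
  expect_identical(s1$embeddings, s2$embeddings)
  s3 <- generate_society(society_config(n_agents = 80, seed = 43))
  expect_false(identical(s1$events, s3$events))
})

test_that("structural invariants hold on generated societies", {
  soc <- tiny_society(n = 150, seed = 3, growth_rate = 0.1)
  a <- soc$agents
  ev <- soc$events
  expect_equal(nrow(a), 150)
  expect_true(all(sort(unique(a$join_day)) >= 1))
  expect_gt(max(a$join_day), 1) # population actually grows
  # every event endpoint exists and had joined by the event day
  jd <- setNames(a$join_day, a$agent_id)
  expect_true(all(ev$source %in% a$agent_id))
  expect_true(all(ev$target %in% a$agent_id))
  expect_true(all(jd[ev$source] <= ev$day))
  expect_true(all(jd[ev$target] <= ev$day))
  expect_true(all(ev$source != ev$target))
  expect_true(all(ev$type %in% c("follow", "like", "dislike", "mention")))
  expect_equal(unname(sqrt(rowSums(soc$embeddings^2))),
               rep(1, nrow(a)), tolerance = 1e-9)
})

test_that("h_L = 1 forbids cross-language engagement entirely", {
  soc <- generate_society(society_config(
    n_agents = 200, language_props = c(en = 0.5, zh = 0.5),
    lang_homophily = 1, seed = 5
  ))
  lang <- setNames(soc$agents$language, soc$agents$agent_id)
  expect_gt(nrow(soc$events), 0)
  expect_true(all(lang[soc$events$source] == lang[soc$events$target]))
})

test_that("h_L = 0 gives near-zero language assortativity (20 seeds)", {
  # random mixing: |r| < 0.05 at n = 2000 for every seed
  rs <- vapply(1:20, function(s) {
    soc <- generate_society(society_config(
      n_agents = 2000, language_props = c(en = 0.5, zh = 0.5), seed = s
    ))
    g <- build_graph(soc$events, 28)
    attribute_assortativity(g, lang_labels(soc))
  }, numeric(1))
  expect_true(all(abs(rs) < 0.05))
})

test_that("language assortativity is monotone in h_L", {
  hl <- c(0, 0.25, 0.5, 0.75, 1)
  for (s in 1:3) {
    rs <- vapply(hl, function(h) {
      soc <- generate_society(society_config(
        n_agents = 1000, lang_homophily = h, seed = s
      ))
      g <- build_graph(soc$events, 28)
      attribute_assortativity(g, lang_labels(soc))
    }, numeric(1))
    expect_true(all(diff(rs) > -0.02)) # non-decreasing up to sampling noise
    expect_lt(rs[1], 0.1)
    expect_gt(rs[5], 0.9)
  }
})

test_that("degree heavy-tailedness grows as activity_shape shrinks", {
  ratio <- function(shape) {
    r <- vapply(1:5, function(s) {
      soc <- generate_society(society_config(
        n_agents = 400, activity_shape = shape, events_per_day = 1, seed = s
      ))
      g <- build_graph(soc$events, 28)
      d <- igraph::degree(g)
      max(d) / stats::median(d)
    }, numeric(1))
    mean(r)
  }
  expect_gt(ratio(0.8), ratio(3))
})

test_that("planted_partition returns ground truth at both levels", {
  soc <- generate_society(society_config(
    n_agents = 300, language_props = c(en = 0.5, zh = 0.5),
    n_topics_per_language = 3, seed = 9
  ))
  pl <- planted_partition(soc, "language")
  expect_equal(n_communities(pl), 2)
  pt <- planted_partition(soc, "topic")
  expect_equal(n_communities(pt), 6)
  expect_equal(sum(community_sizes(pt)), 300)
  expect_equal(sum(community_sizes(pl)), 300)
  expect_true(all(attr(pl, "consistency") == 1))
  expect_error(planted_partition(soc, "colour"))
})

test_that("event and agent files round-trip in csv and jsonl", {
  soc <- tiny_society(n = 40, seed = 2)
  td <- withr::local_tempdir()
  csv <- file.path(td, "ev.csv")
  jsonl <- file.path(td, "ev.jsonl")
  write_events(soc$events, csv)
  write_events(soc$events, jsonl)
  ev1 <- read_events(csv)
  ev2 <- read_events(jsonl)
  expect_equal(ev1, soc$events, ignore_attr = TRUE)
  expect_equal(ev2, soc$events, ignore_attr = TRUE)
  # foreign column names through a mapping
  foreign <- soc$events
  names(foreign) <- c("d", "actor", "object", "kind")
  f3 <- file.path(td, "foreign.csv")
  utils::write.csv(foreign, f3, row.names = FALSE)
  ev3 <- read_events(f3, col_map = c(day = "d", source = "actor",
                                     target = "object", type = "kind"))
  expect_equal(ev3, soc$events, ignore_attr = TRUE)

  ag <- file.path(td, "agents.csv")
  em <- file.path(td, "emb.csv")
  write_agents(soc$agents, ag)
  write_embeddings(soc$embeddings, em)
  expect_equal(read_agents(ag), soc$agents, ignore_attr = TRUE)
  expect_equal(read_embeddings(em), soc$embeddings, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("rendered toy posts exercise the cleaning path", {
  soc <- tiny_society(n = 30, seed = 4)
  posts <- render_posts(soc)
  expect_named(posts)
  expect_equal(names(posts), soc$agents$agent_id)
  # punctuation present before cleaning, absent after
  raw <- paste(posts[[1]], collapse = " ")
  expect_match(raw, "[,!]")
  expect_false(grepl("[,!]", clean_text(raw)))
})
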