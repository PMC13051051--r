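#' Configure an end-to-end analysis run
#'
#' Describes one full analysis: cumulative graphs at each `day_cutoffs`
#' snapshot, for a "full" scope (all agents, clustered by label
#' propagation) and an optional attribute-restricted scope (e.g. the
#' English-language subset, clustered by fast-greedy modularity), with
#' consistency filtering, rewiring nulls and content-alignment analyses.
#' Inputs are either a [society_config()] (synthetic mode) or paths to
#' event / agent / embedding files written by [write_events()] and friends.
#'
#' @param society a [society_config()] for synthetic mode, or `NULL`.
#' @param events_path,agents_path,embeddings_path input files when
#'   `society` is `NULL`.
#' @param day_cutoffs strictly increasing day snapshots (default
#'   `c(7, 14, 21, 28)`).
#' @param subset_language language label defining the restricted scope, or
#'   `NULL` to skip it (default `"english"`).
#' @param n_consistency re-clustering iterations for the stability filter.
#' @param n_null rewiring iterations for null distributions.
#' @param min_neighbors node-degree filter threshold.
#' @param min_community_frac community size filter threshold.
#' @param consistency_threshold minimum mean overlap rate to keep a
#'   community.
#' @param max_zero_pairs 0-engagement bin subsample cap.
#' @param seed master seed; all stage seeds derive from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(society = NULL, events_path = NULL,
                       agents_path = NULL, embeddings_path = NULL,
                       day_cutoffs = c(7, 14, 21, 28),
                       subset_language = "english",
                       n_consistency = 1000, n_null = 1000,
                       min_neighbors = 2, min_community_frac = 0.01,
                       consistency_threshold = 0.80,
                       max_zero_pairs = 1e6, seed = 1L) {
  if (is.null(society) && is.null(events_path)) {
    stop("either a society config or an events path is required",
         call. = FALSE)
  }
  if (any(diff(day_cutoffs) <= 0)) {
    stop("day_cutoffs must be strictly increasing", call. = FALSE)
  }
  if (!is_count(n_null) || !is_count(n_consistency)) {
    stop("n_null and n_consistency must be >= 1", call. = FALSE)
  }
  structure(
    list(society = society, events_path = events_path,
         agents_path = agents_path, embeddings_path = embeddings_path,
         day_cutoffs = day_cutoffs, subset_language = subset_language,
         n_consistency = n_consistency, n_null = n_null,
         min_neighbors = min_neighbors,
         min_community_frac = min_community_frac,
         consistency_threshold = consistency_threshold,
         max_zero_pairs = max_zero_pairs, seed = as.integer(seed)),
    class = "run_config"
  )
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(config[setdiff(names(config), "society")],
                           auto_unbox = TRUE, force = TRUE, digits = NA)
  if (!is.null(config$society)) {
    json <- paste0(json, jsonlite::toJSON(unclass(config$society),
                                          auto_unbox = TRUE, digits = NA))
  }
  codes <- utf8ToInt(json)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full homophily analysis pipeline
#'
#' For every day cutoff: build the cumulative graph, prune weakly engaged
#' nodes, detect communities (label propagation on the full scope,
#' fast-greedy on the language subset; restriction precedes pruning), drop
#' sub-1% communities, score community consistency, compute modularity and
#' community assortativity with rewiring nulls (re-clustered per
#' iteration), language assortativity overall and per language pair with
#' fixed-label nulls, the community-language contingency test, and - on the
#' subset scope with embeddings - the centroid-distance test, the
#' engagement-bin distance table and the MRQAP engagement-distance
#' correlation. Fully deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @param progress print stage log lines to stderr.
#' @return Object of class `run_report`: nested per-day results plus
#'   provenance (`config`, `config_hash`).
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_line <- function(...) if (progress) message(sprintf(...))
  t0 <- Sys.time()

  if (!is.null(config$society)) {
    society <- generate_society(config$society)
    events <- society$events
    agents <- society$agents
    embeddings <- society$embeddings
  } else {
    events <- read_events(config$events_path)
    agents <- if (!is.null(config$agents_path)) {
      read_agents(config$agents_path)
    } else NULL
    embeddings <- if (!is.null(config$embeddings_path)) {
      read_embeddings(config$embeddings_path)
    } else NULL
  }
  languages <- if (!is.null(agents)) {
    setNames(agents$language, agents$agent_id)
  } else NULL

  # generous pool: consumption order (and hence the stream) is fully
  # determined by the seed-generated data, so runs are reproducible
  stage_seeds <- derive_seeds(config$seed, 64L * length(config$day_cutoffs))
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    stage_seeds[si]
  }

  days <- list()
  for (day in config$day_cutoffs) {
    log_line("day %d: building graphs", day)
    day_res <- list(day = day)

    ## ---- full scope: language communities --------------------------------
    g_full <- build_graph(events, day, agents = agents)
    g_full <- prune_low_degree(g_full, config$min_neighbors)
    full <- list(n_nodes = vcount(g_full), n_edges = ecount(g_full))
    if (ecount(g_full) > 0) {
      part <- label_propagation(g_full, seed = next_seed())
      part_f <- filter_small_communities(part, g_full,
                                         config$min_community_frac)
      full$n_communities <- n_communities(part_f)
      full$partition <- part_f
      if (n_communities(part_f) > 0) {
        full$stats <- partition_stats(g_full, part_f)
        full$modularity_null <- null_distribution(
          g_full, "modularity",
          clustering = function(g, s) label_propagation(g, seed = s),
          base_partition = part_f, n_iterations = config$n_null,
          seed = next_seed(), statistic_name = "modularity"
        )
      } else {
        next_seed()
        full$no_communities <- TRUE
      }
      if (!is.null(languages)) {
        lab <- languages[V(g_full)$name]
        if (length(unique(lab)) > 1) {
          full$language_assortativity <- null_distribution(
            g_full, "assortativity", labels = languages,
            n_iterations = config$n_null, seed = next_seed(),
            statistic_name = "language_assortativity"
          )
          pairs_present <- sort(unique(lab))
          pair_tabs <- combn(pairs_present, 2, simplify = FALSE)
          full$pairwise_assortativity <- lapply(pair_tabs, function(pr) {
            res <- tryCatch({
              sub <- induced_subgraph(
                g_full, V(g_full)$name[lab %in% pr]
              )
              null_distribution(
                sub, "assortativity", labels = languages,
                n_iterations = config$n_null, seed = next_seed(),
                statistic_name = paste(pr, collapse = "-")
              )
            }, error = function(e) NULL)
            res
          })
          names(full$pairwise_assortativity) <-
            vapply(pair_tabs, paste, character(1), collapse = "-")
          if (n_communities(part_f) >= 2) {
            full$contingency <- tryCatch(
              contingency_alignment(part_f, languages),
              error = function(e) NULL
            )
          }
        }
      }
    } else {
      full$no_communities <- TRUE
    }
    day_res$full <- full

    ## ---- subset scope: content communities -------------------------------
    if (!is.null(config$subset_language) && !is.null(languages)) {
      sub_agents <- agents[agents$language == config$subset_language, ,
                           drop = FALSE]
      sub_events <- events[events$source %in% sub_agents$agent_id &
                             events$target %in% sub_agents$agent_id, ,
                           drop = FALSE]
      g_sub <- build_graph(sub_events, day, agents = sub_agents)
      g_sub <- prune_low_degree(g_sub, config$min_neighbors)
      subset <- list(language = config$subset_language,
                     n_nodes = vcount(g_sub), n_edges = ecount(g_sub))
      if (ecount(g_sub) > 0) {
        part_s <- greedy_modularity(g_sub)
        part_sf <- filter_small_communities(part_s, g_sub,
                                            config$min_community_frac)
        cons <- consistency_check(
          g_sub, part_sf, algorithm = "greedy_modularity",
          n_iterations = config$n_consistency,
          threshold = config$consistency_threshold, seed = next_seed()
        )
        part_k <- keep_consistent(part_sf, cons)
        subset$n_communities <- n_communities(part_sf)
        subset$n_consistent <- length(cons$kept)
        subset$consistency <- cons
        subset$partition <- part_k
        if (n_communities(part_k) > 0) {
          subset$stats <- partition_stats(g_sub, part_k)
          subset$modularity_null <- null_distribution(
            g_sub, "modularity",
            clustering = function(g, s) greedy_modularity(g),
            base_partition = part_k, n_iterations = config$n_null,
            seed = next_seed(), statistic_name = "modularity"
          )
          if (n_communities(part_k) >= 2) {
            comm_labels <- part_k$membership
            subset$assortativity_null <- null_distribution(
              restrict_to_assigned(g_sub, comm_labels)$graph,
              "assortativity", labels = comm_labels,
              n_iterations = config$n_null, seed = next_seed(),
              statistic_name = "community_assortativity"
            )
          }
        } else {
          subset$no_communities <- TRUE
        }
        if (!is.null(embeddings) && n_communities(part_k) > 0) {
          emb_ids <- intersect(V(g_sub)$name, rownames(embeddings))
          emb <- embeddings[emb_ids, , drop = FALSE]
          subset$centroid_test <- tryCatch(
            suppressWarnings(centroid_distance_test(emb, part_k)),
            error = function(e) NULL
          )
          subset$bins <- distance_by_engagement_bins(
            induced_subgraph(g_sub, emb_ids), emb,
            max_zero_pairs = config$max_zero_pairs, seed = next_seed()
          )
          subset$qap <- tryCatch({
            wmat <- engagement_matrix(induced_subgraph(g_sub, emb_ids))
            dmat <- cosine_distance_matrix(emb, rownames(wmat))
            mrqap_correlation(wmat, dmat,
                              n_permutations = config$n_null,
                              seed = next_seed())
          }, error = function(e) NULL)
        }
      } else {
        subset$no_communities <- TRUE
      }
      day_res$subset <- subset
    }
    days[[as.character(day)]] <- day_res
  }

  structure(
    list(days = days, config = config, config_hash = config_hash(config),
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d day snapshots (config %s)\n",
              length(x$days), x$config_hash))
  for (d in x$days) {
    full <- d$full
    cat(sprintf(
      "  day %2d: full %d nodes / %d edges, %s communities\n",
      d$day, full$n_nodes, full$n_edges,
      if (isTRUE(full$no_communities)) "no" else
        as.character(full$n_communities %||% 0)
    ))
  }
  invisible(x)
}

report_rows <- function(report) {
  rows <- list()
  add <- function(day, scope, statistic, nr) {
    if (is.null(nr)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      day = day, scope = scope, statistic = statistic,
      observed = nr$observed, ci_low = nr$ci_low, ci_high = nr$ci_high,
      p_boot = nr$p_boot, n_iterations = nr$n_iterations,
      stringsAsFactors = FALSE
    )
  }
  for (d in report$days) {
    add(d$day, "full", "modularity", d$full$modularity_null)
    add(d$day, "full", "language_assortativity",
        d$full$language_assortativity)
    for (nm in names(d$full$pairwise_assortativity %||% list())) {
      add(d$day, "full", paste0("assortativity_", nm),
          d$full$pairwise_assortativity[[nm]])
    }
    if (!is.null(d$subset)) {
      add(d$day, "subset", "modularity", d$subset$modularity_null)
      add(d$day, "subset", "community_assortativity",
          d$subset$assortativity_null)
    }
  }
  if (!length(rows)) {
    return(data.frame(day = integer(), scope = character(),
                      statistic = character(), observed = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_boot = numeric(), n_iterations = integer()))
  }
  do.call(rbind, rows)
}

#' Emit machine-readable report tables
#'
#' Writes the run report as CSV tables: `structure_stats.csv` (one row per
#' day, scope and statistic: observed value, SD-based 95% CI, bootstrapped
#' p), `consistency.csv`, `contingency.csv`, `centroid.csv`, `bins.csv`,
#' `qap.csv`, plus a `schema.json` documenting every column. Re-emitting
#' the same report produces byte-identical files.
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
emit_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  wr(report_rows(report), "structure_stats.csv")

  cons <- list(); cont <- list(); cent <- list(); bins <- list()
  qap <- list()
  for (d in report$days) {
    if (!is.null(d$subset$consistency)) {
      tb <- d$subset$consistency$table
      if (nrow(tb)) cons[[length(cons) + 1]] <- cbind(day = d$day, tb)
    }
    if (!is.null(d$full$contingency)) {
      x <- d$full$contingency
      cont[[length(cont) + 1]] <- data.frame(
        day = d$day, chi2 = x$chi2, df = x$df, n = x$n, p = x$p,
        cramers_v = x$cramers_v
      )
    }
    if (!is.null(d$subset$centroid_test)) {
      x <- d$subset$centroid_test
      cent[[length(cent) + 1]] <- data.frame(
        day = d$day, t = x$t, df = x$df, p = x$p, cohens_d = x$cohens_d,
        ci_d_low = x$ci_d[1], ci_d_high = x$ci_d[2], n = x$n,
        degenerate = x$degenerate
      )
    }
    if (!is.null(d$subset$bins)) {
      bins[[length(bins) + 1]] <- cbind(day = d$day, d$subset$bins)
    }
    if (!is.null(d$subset$qap)) {
      x <- d$subset$qap
      qap[[length(qap) + 1]] <- data.frame(
        day = d$day, r = x$r, p = x$p, ci_low = x$ci[1], ci_high = x$ci[2],
        n_permutations = x$n_permutations, n_nodes = x$n_nodes
      )
    }
  }
  if (length(cons)) wr(do.call(rbind, cons), "consistency.csv")
  if (length(cont)) wr(do.call(rbind, cont), "contingency.csv")
  if (length(cent)) wr(do.call(rbind, cent), "centroid.csv")
  if (length(bins)) wr(do.call(rbind, bins), "bins.csv")
  if (length(qap)) wr(do.call(rbind, qap), "qap.csv")

  schema <- list(
    structure_stats = list(
      day = "day cutoff (inclusive)", scope = "full or subset",
      statistic = "statistic name (null mode: re-clustered for modularity, fixed labels for *_assortativity)",
      observed = "observed value", ci_low = "observed - 1.96 sd(null)",
      ci_high = "observed + 1.96 sd(null)",
      p_boot = "share of null >= observed (0 means < 1/n_iterations)",
      n_iterations = "rewiring iterations"
    ),
    consistency = list(day = "day cutoff", community = "community id",
                       size = "members", mean_overlap = "mean o(A)",
                       kept = "mean o(A) >= threshold"),
    contingency = list(day = "day cutoff", chi2 = "Pearson chi-squared",
                       df = "(R-1)(C-1)", n = "agents in table",
                       p = "p-value", cramers_v = "Cramer's V"),
    centroid = list(day = "day cutoff", t = "paired t", df = "n - 1",
                    p = "p-value", cohens_d = "t / sqrt(n)",
                    n = "agents tested"),
    bins = list(day = "day cutoff", bin = "engagement count bin",
                n_pairs = "pairs in bin (0-bin possibly subsampled)",
                mean_distance = "mean pairwise cosine distance",
                ci_low = "mean - 1.96 SE", ci_high = "mean + 1.96 SE"),
    qap = list(day = "day cutoff", r = "dyadic Pearson r",
               p = "QAP two-sided p (floor 1/n_permutations)",
               ci_low = "dyadic bootstrap 2.5%",
               ci_high = "dyadic bootstrap 97.5%")
  )
  schema_path <- file.path(out_dir, "schema.json")
  jsonlite::write_json(schema, schema_path, auto_unbox = TRUE,
                       pretty = TRUE)
  files <- c(files, schema_path)
  invisible(files)
}

#' Serialize a run report to JSON
#'
#' Drops the bulky per-iteration null samples; everything else (observed
#' statistics, CIs, p-values, consistency tables, provenance) is retained.
#'
#' @param report a [run_pipeline()] result.
#' @param path output JSON path, or `NULL` to return the JSON string.
#' @export
report_json <- function(report, path = NULL) {
  slim_null <- function(nr) {
    if (is.null(nr)) return(NULL)
    nr$null_scores <- NULL
    unclass(nr)
  }
  days <- lapply(report$days, function(d) {
    out <- list(day = d$day)
    slim_scope <- function(sc) {
      if (is.null(sc)) return(NULL)
      sc$partition <- if (!is.null(sc$partition)) {
        as.list(table(sc$partition$membership, useNA = "no"))
      } else NULL
      sc$consistency <- if (!is.null(sc$consistency)) {
        sc$consistency$table
      } else NULL
      sc$contingency <- if (!is.null(sc$contingency)) {
        x <- sc$contingency
        list(chi2 = x$chi2, df = x$df, n = x$n, p = x$p,
             cramers_v = x$cramers_v)
      } else NULL
      for (f in c("modularity_null", "language_assortativity",
                  "assortativity_null")) {
        sc[[f]] <- slim_null(sc[[f]])
      }
      sc$pairwise_assortativity <- lapply(
        sc$pairwise_assortativity %||% NULL, slim_null
      )
      sc$centroid_test <- if (!is.null(sc$centroid_test)) {
        unclass(sc$centroid_test)
      } else NULL
      sc$stats <- if (!is.null(sc$stats)) unclass(sc$stats) else NULL
      sc$qap <- if (!is.null(sc$qap)) unclass(sc$qap) else NULL
      sc
    }
    out$full <- slim_scope(d$full)
    out$subset <- slim_scope(d$subset)
    out
  })
  obj <- list(config_hash = report$config_hash, days = days)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
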