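#' Configure a synthetic agent society
#'
#' Describes a growing population of posting agents with planted homophily:
#' language blocks (same-language engagement boost `lang_homophily`) and
#' topic-structured content embeddings (engagement probability decaying with
#' cosine distance at rate `content_homophily`). Defaults emulate a
#' month-long observation window on a chatbot micro-blogging platform: four
#' language groups dominated by English, ~6% daily population growth, and a
#' heavy-tailed per-agent activity distribution.
#'
#' @param n_agents total number of agents ever joining (final population).
#' @param n_days number of observation days (default 28).
#' @param language_props named probability vector over language labels;
#'   must sum to 1.
#' @param n_topics_per_language number of content topics within each language.
#' @param lang_homophily `h_L` in `[0,1]`: same-language target weight is
#'   multiplied by `1 + 9 * h_L`, cross-language weight by `1 - h_L`, so 0 is
#'   no language preference and 1 is absolute segregation.
#' @param content_homophily `h_C >= 0`: target weight is multiplied by
#'   `exp(-h_C * d_cos)` where `d_cos` is the cosine distance between the
#'   source and candidate embeddings; 0 disables content homophily.
#' @param activity_shape Pareto shape of per-agent activity; smaller values
#'   give heavier tails (more extreme activity inequality).
#' @param events_per_day expected number of engagement events per active
#'   agent per day.
#' @param growth_rate fraction of the current population joining per day.
#' @param embed_dim dimension of the synthetic content embeddings (>= 2).
#' @param noise_sd within-topic embedding spread before renormalisation.
#' @param seed RNG seed; the whole society is deterministic given the seed.
#' @return An object of class `society_config`.
#' @export
society_config <- function(n_agents,
                           n_days = 28,
                           language_props = c(english = 0.55, chinese = 0.20,
                                              japanese = 0.15, other = 0.10),
                           n_topics_per_language = 3,
                           lang_homophily = 0,
                           content_homophily = 0,
                           activity_shape = 1.5,
                           events_per_day = 0.35,
                           growth_rate = 0.06,
                           embed_dim = 16,
                           noise_sd = 0.3,
                           seed = 1L) {
  if (!is_count(n_agents)) stop_config("n_agents", "must be a count >= 1")
  if (!is_count(n_days)) stop_config("n_days", "must be a count >= 1")
  if (!is.numeric(language_props) || is.null(names(language_props)) ||
      any(language_props < 0)) {
    stop_config("language_props", "must be a named non-negative vector")
  }
  if (abs(sum(language_props) - 1) > 1e-9) {
    stop_config("language_props", "must sum to 1")
  }
  if (!is_count(n_topics_per_language)) {
    stop_config("n_topics_per_language", "must be a count >= 1")
  }
  if (!is_scalar_num(lang_homophily) || lang_homophily < 0 ||
      lang_homophily > 1) {
    stop_config("lang_homophily", "must lie in [0, 1]")
  }
  if (!is_scalar_num(content_homophily) || content_homophily < 0) {
    stop_config("content_homophily", "must be >= 0")
  }
  if (!is_scalar_num(activity_shape) || activity_shape <= 0) {
    stop_config("activity_shape", "must be a positive real")
  }
  if (!is_scalar_num(events_per_day) || events_per_day <= 0) {
    stop_config("events_per_day", "must be a positive real")
  }
  if (!is_scalar_num(growth_rate) || growth_rate < 0) {
    stop_config("growth_rate", "must be >= 0")
  }
  if (!is_count(embed_dim, min = 2L)) stop_config("embed_dim", "must be >= 2")
  if (!is_scalar_num(noise_sd) || noise_sd < 0) {
    stop_config("noise_sd", "must be >= 0")
  }
  if (!is_count(seed, min = 0L)) stop_config("seed", "must be an integer seed")
  structure(
    list(n_agents = as.integer(n_agents), n_days = as.integer(n_days),
         language_props = language_props,
         n_topics_per_language = as.integer(n_topics_per_language),
         lang_homophily = lang_homophily,
         content_homophily = content_homophily,
         activity_shape = activity_shape, events_per_day = events_per_day,
         growth_rate = growth_rate, embed_dim = as.integer(embed_dim),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "society_config"
  )
}

# Daily join counts: start from the size that reaches n_agents after
# compounding at growth_rate, then add round(growth_rate * current) per day,
# topping up the final day so the total is exactly n_agents.
join_schedule <- function(n_agents, n_days, growth_rate) {
  n0 <- max(1L, round(n_agents / (1 + growth_rate)^(n_days - 1)))
  joins <- integer(n_days)
  joins[1] <- min(n0, n_agents)
  cur <- joins[1]
  if (n_days > 1) {
    for (d in 2:n_days) {
      add <- round(growth_rate * cur)
      add <- min(add, n_agents - cur)
      joins[d] <- add
      cur <- cur + add
    }
  }
  if (cur < n_agents) {
    joins[n_days] <- joins[n_days] + (n_agents - cur)
  }
  joins
}

#' Generate a synthetic agent society with planted homophily
#'
#' Agents join over `n_days` days, each with a language label, a topic within
#' the language, and a unit-norm content embedding (topic centroid plus
#' Gaussian noise). Per-agent event rates are Pareto-distributed
#' (heavy-tailed); each day the number of events is Poisson with mean
#' `events_per_day` times the active population. Event sources are drawn
#' proportionally to activity; the target of each event is drawn among other
#' active agents with weight
#' `exp(-h_C * d_cos(source, target)) * L`, where `L = 1 + 9 * h_L` for
#' same-language pairs and `L = 1 - h_L` otherwise. Event types are uniform
#' over follow / like / dislike / mention.
#'
#' @param config a [society_config()].
#' @return An object of class `synthetic_society`: a list with `agents`
#'   (data.frame: agent_id, language, topic, join_day), `events` (data.frame:
#'   day, source, target, type), `embeddings` (matrix, rows named by
#'   agent_id, unit L2 norm), and `config`.
#' @export
generate_society <- function(config) {
  if (!inherits(config, "society_config")) {
    stop("config must be created by society_config()", call. = FALSE)
  }
  with_seed(config$seed, {
    n <- config$n_agents
    langs <- names(config$language_props)
    joins <- join_schedule(n, config$n_days, config$growth_rate)
    agent_id <- sprintf("a%06d", seq_len(n))
    join_day <- rep(seq_len(config$n_days), times = joins)
    language <- sample(langs, n, replace = TRUE,
                       prob = config$language_props)
    topic <- sample.int(config$n_topics_per_language, n, replace = TRUE)

    # topic centroids: one random unit vector per (language, topic)
    d <- config$embed_dim
    centroid_key <- paste(language, topic, sep = ":")
    keys <- unique(centroid_key)
    centroids <- matrix(rnorm(length(keys) * d), nrow = length(keys),
                        dimnames = list(keys, NULL))
    centroids <- centroids / sqrt(rowSums(centroids^2))
    emb <- centroids[centroid_key, , drop = FALSE] +
      matrix(rnorm(n * d, sd = config$noise_sd), nrow = n)
    emb <- emb / sqrt(rowSums(emb^2))
    rownames(emb) <- agent_id

    # heavy-tailed activity: Pareto(xm = 1, shape = activity_shape)
    activity <- runif(n)^(-1 / config$activity_shape)

    # same-language boost factors
    hL <- config$lang_homophily
    hC <- config$content_homophily
    same_w <- 1 + 9 * hL
    cross_w <- 1 - hL

    # full cosine similarity only needed when content homophily is on
    sim <- if (hC > 0) tcrossprod(emb) else NULL

    ev_day <- list()
    types <- c("follow", "like", "dislike", "mention")
    for (day in seq_len(config$n_days)) {
      active <- which(join_day <= day)
      n_active <- length(active)
      if (n_active < 2) next
      n_ev <- rpois(1, config$events_per_day * n_active)
      if (n_ev == 0) next
      src <- sample(active, n_ev, replace = TRUE,
                    prob = activity[active])
      tgt <- integer(n_ev)
      keep <- rep(TRUE, n_ev)
      for (s in unique(src)) {
        idx <- which(src == s)
        w <- if (is.null(sim)) rep(1, n_active) else
          exp(-hC * (1 - sim[active, s]))
        w <- w * ifelse(language[active] == language[s], same_w, cross_w)
        w[active == s] <- 0
        if (sum(w) <= 0) {           # e.g. h_L = 1 and s is the only
          keep[idx] <- FALSE         # active member of its language
          next
        }
        tgt[idx] <- sample(active, length(idx), replace = TRUE, prob = w)
      }
      if (!any(keep)) next
      ev_day[[day]] <- data.frame(
        day = day,
        source = agent_id[src[keep]],
        target = agent_id[tgt[keep]],
        type = sample(types, sum(keep), replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    events <- if (length(ev_day)) do.call(rbind, ev_day) else
      data.frame(day = integer(), source = character(),
                 target = character(), type = character(),
                 stringsAsFactors = FALSE)
    rownames(events) <- NULL

    structure(
      list(
        agents = data.frame(agent_id = agent_id, language = language,
                            topic = topic, join_day = join_day,
                            stringsAsFactors = FALSE),
        events = events,
        embeddings = emb,
        config = config
      ),
      class = "synthetic_society"
    )
  })
}

#' @export
print.synthetic_society <- function(x, ...) {
  cat(sprintf(
    "<synthetic_society> %d agents over %d days, %d events (h_L = %.2f, h_C = %.2f)\n",
    nrow(x$agents), x$config$n_days, nrow(x$events),
    x$config$lang_homophily, x$config$content_homophily
  ))
  invisible(x)
}

#' Ground-truth partition of a synthetic society
#'
#' @param society a [generate_society()] result.
#' @param level `"language"` for the planted language blocks, `"topic"` for
#'   the finer language:topic blocks.
#' @return A [new_partition()] with algorithm `"planted"`; planted
#'   communities are exact, so their consistency score is 1 by construction
#'   (stored in attribute `consistency`).
#' @export
planted_partition <- function(society, level = c("language", "topic")) {
  stopifnot(inherits(society, "synthetic_society"))
  level <- match.arg(level)
  a <- society$agents
  m <- switch(level,
    language = setNames(a$language, a$agent_id),
    topic = setNames(paste(a$language, a$topic, sep = ":"), a$agent_id)
  )
  p <- new_partition(m, "planted", seed = society$config$seed)
  attr(p, "consistency") <- setNames(
    rep(1, length(unique(m))), sort(unique(m))
  )
  p
}

#' Render toy posts for a synthetic society
#'
#' Produces short keyword posts from a per-(language, topic) pseudo-word
#' vocabulary, with punctuation sprinkled in, for exercising the
#' text-cleaning and hashing-encoder path without any real text model.
#' Non-English languages get non-roman glyphs appended so cleaning is
#' observable.
#'
#' @param society a [generate_society()] result.
#' @param n_posts posts per agent.
#' @param words_per_post words per post.
#' @return Named list (by agent id) of character vectors of posts.
#' @export
render_posts <- function(society, n_posts = 3, words_per_post = 8) {
  stopifnot(inherits(society, "synthetic_society"))
  a <- society$agents
  with_seed(society$config$seed + 104729L, {
    vocab_for <- function(lang, topic) {
      paste0(substr(lang, 1, 3), topic, "w", 1:20)
    }
    glyphs <- c(english = "", chinese = "你好",
                japanese = "こん", other = "éß")
    posts <- vector("list", nrow(a))
    names(posts) <- a$agent_id
    for (i in seq_len(nrow(a))) {
      v <- vocab_for(a$language[i], a$topic[i])
      posts[[i]] <- vapply(seq_len(n_posts), function(j) {
        w <- sample(v, words_per_post, replace = TRUE)
        extra <- glyphs[a$language[i]] %||% ""
        if (is.na(extra)) extra <- ""
        paste0(paste(w, collapse = " "), ", well! ", extra)
      }, character(1))
    }
    posts
  })
}

#' Write / read society artefacts as plain text
#'
#' Events go to CSV or JSONL (one object per line) with columns
#' `day, source, target, type`; agents to CSV with
#' `agent_id, language, topic, join_day`; embeddings to CSV with an
#' `agent_id` index column followed by the coordinate columns.
#'
#' @param events events data.frame.
#' @param path output file.
#' @param format `"csv"` or `"jsonl"`; default guessed from the extension.
#' @export
write_events <- function(events, path, format = NULL) {
  format <- format %||% if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  if (format == "csv") {
    write.csv(events, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(events))) {
      writeLines(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE),
                 con)
    }
  }
  invisible(path)
}

#' @rdname write_events
#' @param col_map optional named character vector mapping the canonical
#'   column names (`day`, `source`, `target`, `type`) to the names used in a
#'   foreign log, e.g. `c(source = "actor", target = "object")`.
#' @export
read_events <- function(path, format = NULL, col_map = NULL) {
  format <- format %||% if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  df <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    do.call(rbind, lapply(lines, function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  need <- c("day", "source", "target", "type")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("event file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df[need]
}

#' @rdname write_events
#' @param agents agents data.frame.
#' @export
write_agents <- function(agents, path) {
  write.csv(agents, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_agents <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_events
#' @param embeddings numeric matrix with agent ids as row names.
#' @export
write_embeddings <- function(embeddings, path) {
  df <- data.frame(agent_id = rownames(embeddings), embeddings,
                   stringsAsFactors = FALSE, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_embeddings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$agent_id
  m
}
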