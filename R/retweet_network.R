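#' Extract directed mention edges from tweet text
#'
#' Every `@handle` occurring in a tweet (whether as a retweet marker
#' `"RT @handle"` or a bare mention) contributes one directed edge from the
#' tweet's author to the mentioned user, at most once per distinct handle per
#' tweet. Self-mentions are dropped. Handles are lower-cased.
#'
#' @param corpus a [tweet_corpus()].
#' @param retweets_only only count mentions in tweets whose text starts with
#'   `"RT @"`.
#' @return tibble: `source`, `target`, `tweet_id`, one row per (tweet,
#'   distinct mentioned handle).
#' @export
extract_mention_edges <- function(corpus, retweets_only = FALSE) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  tw <- corpus$tweets
  rows <- lapply(seq_len(nrow(tw)), function(i) {
    text <- tw$text[i]
    if (retweets_only && !grepl("^\\s*RT\\s+@", text, ignore.case = TRUE)) {
      return(NULL)
    }
    m <- regmatches(text, gregexpr("@([A-Za-z0-9_]+)", text))[[1]]
    if (length(m) == 0L) return(NULL)
    handles <- unique(tolower(sub("^@", "", m)))
    handles <- setdiff(handles, tolower(tw$user[i]))
    if (length(handles) == 0L) return(NULL)
    tibble::tibble(source = tolower(tw$user[i]), target = handles,
                   tweet_id = tw$id[i])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(tibble::tibble(source = character(0), target = character(0),
                          tweet_id = character(0)))
  }
  do.call(rbind, rows)
}

#' Build a directed mention network from an edge list
#'
#' Parallel mentions are accumulated into integer edge weights; the node set
#' is the union of all edge endpoints.
#'
#' @param edges tibble/data frame with `source` and `target` columns (e.g.
#'   from [extract_mention_edges()]).
#' @param query_term optional query term attached as a graph attribute.
#' @return a directed weighted [igraph::igraph] graph.
#' @export
build_network <- function(edges, query_term = NULL) {
  if (nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  } else {
    key <- paste(edges$source, edges$target, sep = "\r")
    counts <- table(key)
    ends <- strsplit(names(counts), "\r", fixed = TRUE)
    el <- data.frame(from = vapply(ends, `[`, "", 1L),
                     to = vapply(ends, `[`, "", 2L),
                     weight = as.numeric(counts))
    g <- igraph::graph_from_data_frame(el, directed = TRUE)
  }
  if (!is.null(query_term)) g <- igraph::set_graph_attr(g, "query_term", query_term)
  g
}

#' Network-level topology metrics
#'
#' The metric battery computed per retweet network: node and edge counts,
#' diameter and average path length (computed undirected on the largest
#' weakly connected component, over connected pairs — fragmented mention
#' graphs only admit per-component path statistics), density on the simple
#' directed graph (`edges / n(n-1)`), weak and strong component counts, the
#' fraction of nodes in the giant weak component, the number of Louvain
#' modularity communities on the undirected weighted projection, and the
#' per-node ratios of weak components and communities.
#'
#' @param net a directed [build_network()] graph.
#' @param seed seed for the Louvain community step.
#' @return list of class `network_metrics` with fields `n_nodes`, `n_edges`,
#'   `diameter`, `avg_path_length`, `density`, `n_wcc`, `n_scc`,
#'   `giant_fraction`, `n_modularity_communities`, `wcc_per_node`,
#'   `communities_per_node`.
#' @export
network_metrics <- function(net, seed = 1L) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("network is empty")
  n_edges <- igraph::ecount(net)
  wcc <- igraph::components(net, mode = "weak")
  scc <- igraph::components(net, mode = "strong")
  giant_id <- which.max(wcc$csize)
  giant <- igraph::induced_subgraph(net, which(wcc$membership == giant_id))
  giant_u <- igraph::as_undirected(giant, mode = "collapse")
  diameter <- if (igraph::vcount(giant_u) == 1L) 0L else
    igraph::diameter(giant_u, directed = FALSE, weights = NA)
  apl <- if (igraph::vcount(giant_u) == 1L) 0 else
    igraph::mean_distance(giant_u, directed = FALSE, unconnected = TRUE,
                          weights = NA)
  density <- if (n > 1L) n_edges / (n * (n - 1)) else 0
  undirected <- igraph::as_undirected(net, mode = "collapse",
                                      edge.attr.comb = list(weight = "sum"))
  communities <- louvain_communities(undirected, seed = seed)
  structure(list(
    n_nodes = n, n_edges = n_edges,
    diameter = as.integer(diameter), avg_path_length = apl,
    density = density, n_wcc = wcc$no, n_scc = scc$no,
    giant_fraction = max(wcc$csize) / n,
    n_modularity_communities = communities$n_communities,
    wcc_per_node = wcc$no / n,
    communities_per_node = communities$n_communities / n
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<network_metrics> %d nodes, %d edges | diameter %d, avg path %.2f, ",
    "density %.4f\n  WCC %d (giant %.1f%%), SCC %d, communities %d ",
    "(%.2f per node)\n"),
    x$n_nodes, x$n_edges, x$diameter, x$avg_path_length, x$density,
    x$n_wcc, 100 * x$giant_fraction, x$n_scc, x$n_modularity_communities,
    x$communities_per_node))
  invisible(x)
}

#' Node degree centralities with network-level summaries
#'
#' In/out/total degree on the simple directed graph (parallel mentions
#' collapsed), plus each centrality's maximum and median.
#'
#' @param net a directed [build_network()] graph.
#' @return list with `nodes` (tibble: `user`, `in_degree`, `out_degree`,
#'   `total_degree`) and `summary` (tibble: `metric`, `max`, `median`).
#' @export
degree_stats <- function(net) {
  din <- igraph::degree(net, mode = "in")
  dout <- igraph::degree(net, mode = "out")
  dtot <- igraph::degree(net, mode = "all")
  nodes <- tibble::tibble(user = igraph::V(net)$name, in_degree = unname(din),
                          out_degree = unname(dout), total_degree = unname(dtot))
  summary <- tibble::tibble(
    metric = c("in_degree", "out_degree", "total_degree"),
    max = c(max(din), max(dout), max(dtot)),
    median = c(stats::median(din), stats::median(dout), stats::median(dtot))
  )
  list(nodes = nodes, summary = summary)
}

#' Compare two networks' degree-centrality distributions
#'
#' Two-sided Mann-Whitney U rank test between two degree-score vectors, with
#' the mean difference, the normal-approximation Z (tie-corrected), and the
#' rank-test effect size `|Z| / sqrt(n_a + n_b)`. For small untied samples
#' (both sizes < 50) the p-value uses the exact U distribution; otherwise the
#' normal approximation.
#'
#' @param scores_a,scores_b numeric degree vectors from two networks.
#' @return list of class `comparison_result`: `mean_difference`
#'   (`mean(a) - mean(b)`), `U`, `z`, `p`, `effect_size`.
#' @export
compare_networks <- function(scores_a, scores_b) {
  if (length(scores_a) == 0L || length(scores_b) == 0L) {
    stop("both score vectors must be nonempty")
  }
  n_a <- length(scores_a); n_b <- length(scores_b)
  ranks <- rank(c(scores_a, scores_b))
  r_a <- sum(ranks[seq_len(n_a)])
  U <- r_a - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  n <- n_a + n_b
  ties <- table(c(scores_a, scores_b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * (n + 1 - tie_term)
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  has_ties <- any(ties > 1)
  if (!has_ties && n_a < 50L && n_b < 50L) {
    p <- 2 * min(stats::pwilcox(U, n_a, n_b),
                 stats::pwilcox(U - 1, n_a, n_b, lower.tail = FALSE))
    p <- min(1, p)
  } else {
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  }
  structure(list(mean_difference = mean(scores_a) - mean(scores_b),
                 U = U, z = z, p = p, effect_size = abs(z) / sqrt(n)),
            class = "comparison_result")
}

#' Sample user timelines from a mention network
#'
#' Mirrors the timeline-sampling protocol: from the users of the mention
#' network who authored a mention/retweet tweet containing the query term,
#' sample `n_users` uniformly without replacement (all of them when fewer are
#' eligible) and keep up to `per_user` most recent tweets of each from the
#' pool, breaking timestamp ties by id, descending.
#'
#' @param net a [build_network()] graph built from `corpus`.
#' @param pool a [tweet_corpus()] holding the users' available tweets.
#' @param n_users number of users to sample.
#' @param per_user maximum tweets kept per sampled user.
#' @param seed sampling seed.
#' @param query_term term an authored mention tweet must contain for
#'   eligibility; defaults to the pool's query term.
#' @return a [tweet_corpus()] of the sampled timelines.
#' @export
sample_user_timelines <- function(net, pool, n_users = 100L, per_user = 100L,
                                  seed = 1L, query_term = NULL) {
  stopifnot(inherits(pool, "tweet_corpus"))
  if (is.null(query_term)) query_term <- pool$query_term
  tw <- pool$tweets
  has_mention <- grepl("@[A-Za-z0-9_]+", tw$text)
  has_query <- grepl(paste0("(?i)(?<![a-z0-9'])", query_term, "(?![a-z0-9'])"),
                     tw$text, perl = TRUE)
  eligible <- intersect(igraph::V(net)$name,
                        tolower(tw$user[has_mention & has_query]))
  if (length(eligible) == 0L) stop("no eligible users in the network")
  sampled <- withr::with_seed(seed, {
    sample(sort(eligible), min(n_users, length(eligible)))
  })
  keep <- unlist(lapply(sampled, function(u) {
    idx <- which(tolower(tw$user) == u)
    ord <- idx[order(tw$timestamp_utc[idx], tw$id[idx], decreasing = TRUE)]
    utils::head(ord, per_user)
  }))
  tweet_corpus(tw[sort(keep), , drop = FALSE], query_term = query_term,
               provenance = pool$provenance)
}

#' Term frequency report relative to a reference term
#'
#' Whole-token (substring-free) occurrence counts of each term over all tweet
#' texts, case-insensitive, with each term's rate relative to the reference
#' term rounded to 2 decimals (the reference's own rate is exactly 1).
#'
#' @param corpus a [tweet_corpus()].
#' @param terms character vector of terms to count.
#' @param reference_term the denominator term; must occur in the corpus.
#' @return tibble: `term`, `frequency`, `proportion_to_reference`.
#' @export
term_frequency_report <- function(corpus, terms, reference_term) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  count_term <- function(term) {
    pat <- paste0("(?i)(?<![a-z0-9'])",
                  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term),
                  "(?![a-z0-9'])")
    sum(vapply(gregexpr(pat, corpus$tweets$text, perl = TRUE), function(m) {
      if (m[1] == -1L) 0L else length(m)
    }, integer(1)))
  }
  ref <- count_term(reference_term)
  if (ref == 0L) stop("reference term '", reference_term, "' not found")
  terms <- union(reference_term, terms)
  freq <- vapply(terms, count_term, integer(1))
  tibble::tibble(term = terms, frequency = unname(freq),
                 proportion_to_reference = round(unname(freq) / ref, 2))
}

#' Share of tweets involved in retweet networks
#'
#' Numerator: tweets contributing at least one mention edge; denominator: all
#' tweets across the supplied corpora.
#'
#' @param corpora a [tweet_corpus()] or list of them.
#' @return list: `n_involved`, `n_total`, `percent` (0-100, rounded to 2
#'   decimals).
#' @export
involvement_report <- function(corpora) {
  if (inherits(corpora, "tweet_corpus")) corpora <- list(corpora)
  n_total <- 0L
  n_involved <- 0L
  for (corpus in corpora) {
    n_total <- n_total + nrow(corpus$tweets)
    edges <- extract_mention_edges(corpus)
    n_involved <- n_involved + length(unique(edges$tweet_id))
  }
  if (n_total == 0L) stop("no tweets supplied")
  list(n_involved = n_involved, n_total = n_total,
       percent = round(100 * n_involved / n_total, 2))
}
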