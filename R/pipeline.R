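#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> content -> sentiment -> geo-temporal -> network
#' from one configuration, writing CSV reports plus a machine-readable
#' `summary.json` to the output directory. Every reported value is the direct
#' result of the corresponding exported function, and runs are deterministic
#' given the seed.
#'
#' @param config a named list, or path to a YAML file with the same structure:
#'   \describe{
#'     \item{seed}{integer; mandatory (all stochastic stages flow from it).}
#'     \item{out_dir}{output directory (created if needed).}
#'     \item{corpus_path}{optional JSON-lines/CSV corpus to load instead of
#'       simulating.}
#'     \item{generator}{named list of [generator_config()] overrides used when
#'       no `corpus_path` is given.}
#'     \item{stages}{character subset of `c("content", "sentiment",
#'       "geotemporal", "network")`; default all.}
#'     \item{lexicon_path, emoticon_path}{optional lexicon TSV overrides.}
#'     \item{covariates_path}{optional city covariate CSV for correlations.}
#'     \item{k_features}{Naive Bayes feature count (default 2000).}
#'     \item{louvain_resolution}{Louvain resolution (default 1).}
#'     \item{negation_window}{rule-scorer window (default 5).}
#'     \item{top_k}{rows in top-term/top-edge reports (default 25).}
#'   }
#' @return the summary list, invisibly; reports are written to `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(out_dir = "painstream-report", generator = list(),
                   stages = c("content", "sentiment", "geotemporal", "network"),
                   k_features = 2000L, louvain_resolution = 1.0,
                   negation_window = 5L, top_k = 25L)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$seed)) stop("config error: 'seed' is mandatory")
  bad <- setdiff(config$stages, c("content", "sentiment", "geotemporal", "network"))
  if (length(bad) > 0L) stop("config error: unknown stage(s) ", paste(bad, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  summary <- list(seed = config$seed,
                  parameters = config[c("k_features", "louvain_resolution",
                                        "negation_window", "stages")])

  # --- simulate / load ------------------------------------------------------
  truth <- NULL
  corpus <- run_stage("simulate", {
    if (!is.null(config$corpus_path)) {
      parse_tweets(config$corpus_path)
    } else {
      gen <- do.call(generator_config,
                     utils::modifyList(list(seed = config$seed), config$generator))
      sim <- generate_corpus(gen)
      truth <- sim$truth
      sim$corpus
    }
  })
  summary$n_tweets <- nrow(corpus$tweets)
  lexicon <- run_stage("lexicon", {
    if (is.null(config$lexicon_path)) default_lexicon() else {
      sentiment_lexicon(
        weights = read_lexicon_tsv(config$lexicon_path),
        emoticon_weights = if (is.null(config$emoticon_path)) integer(0) else
          read_lexicon_tsv(config$emoticon_path))
    }
  })

  # --- content: reduction, term graph, communities --------------------------
  reduced <- run_stage("content", deduplicate(corpus))
  summary$n_reduced <- nrow(reduced$tweets)
  if ("content" %in% config$stages) {
    run_stage("content", {
      graph <- build_cooccurrence_graph(reduced)
      partition <- louvain_communities(graph, seed = config$seed,
                                       resolution = config$louvain_resolution)
      terms <- top_terms(graph, config$top_k)
      edges <- top_edges(graph, config$top_k)
      sizes <- community_size_report(partition, m = 10L)
      utils::write.csv(terms, file.path(config$out_dir, "top_terms.csv"),
                       row.names = FALSE)
      utils::write.csv(edges, file.path(config$out_dir, "top_edges.csv"),
                       row.names = FALSE)
      utils::write.csv(sizes$table,
                       file.path(config$out_dir, "community_sizes.csv"),
                       row.names = FALSE)
      export_graphml(graph, file.path(config$out_dir, "term_graph.graphml"),
                     partition)
      summary$content <- list(
        n_terms = igraph::vcount(graph), n_term_edges = igraph::ecount(graph),
        n_communities = partition$n_communities, modularity = partition$Q,
        top10_community_fraction = sizes$top_m_fraction)
    })
  }

  # --- sentiment ------------------------------------------------------------
  results <- NULL
  if (any(c("sentiment", "geotemporal") %in% config$stages)) {
    results <- run_stage("sentiment", {
      nb <- NULL
      labels <- corpus$tweets$label
      if (!anyNA(labels) && length(unique(labels)) == 2L) {
        streams <- tokenize(corpus$tweets$text, query_term = corpus$query_term,
                            drop_query = FALSE)
        nb <- train_nb(streams, labels, k_features = config$k_features)
      }
      classify_corpus(corpus, lexicon, nb_model = nb,
                      negation_window = config$negation_window)
    })
    if ("sentiment" %in% config$stages) {
      utils::write.csv(results, file.path(config$out_dir, "sentiment.csv"),
                       row.names = FALSE)
      summary$sentiment <- list(percent_positive = percent_positive(results))
    }
  }

  # --- geo-temporal ---------------------------------------------------------
  if ("geotemporal" %in% config$stages) {
    run_stage("geotemporal", {
      offsets <- if (!is.null(truth)) {
        gen_cities <- do.call(generator_config,
                              utils::modifyList(list(seed = config$seed),
                                                config$generator))$cities
        stats::setNames(gen_cities$utc_offset, gen_cities$city)
      } else if (!is.null(config$utc_offsets)) {
        unlist(config$utc_offsets)
      } else {
        stop("no UTC offsets available for localization")
      }
      localized <- localize_timestamps(corpus, offsets)
      res <- classify_corpus(localized, lexicon,
                             negation_window = config$negation_window)
      by_city <- proportion_by_group(res, "city")
      by_hour <- proportion_by_group(res, "hour")
      utils::write.csv(by_city$table,
                       file.path(config$out_dir, "sentiment_by_city.csv"),
                       row.names = FALSE)
      utils::write.csv(by_hour$table,
                       file.path(config$out_dir, "sentiment_by_hour.csv"),
                       row.names = FALSE)
      city_test <- homogeneity_test(by_city$table)
      hour_test <- homogeneity_test(by_hour$table)
      summary$geotemporal <- list(
        city_median_percent = by_city$median_percent,
        hour_median_percent = by_hour$median_percent,
        city_chisq = city_test$statistic, city_p = city_test$p,
        hour_chisq = hour_test$statistic, hour_p = hour_test$p)
      if (!is.null(config$covariates_path)) {
        cov <- utils::read.csv(config$covariates_path, stringsAsFactors = FALSE)
        correlations <- correlate_covariates(by_city$table, cov)
        utils::write.csv(correlations,
                         file.path(config$out_dir, "covariate_correlations.csv"),
                         row.names = FALSE)
      }
    })
  }

  # --- network --------------------------------------------------------------
  if ("network" %in% config$stages) {
    run_stage("network", {
      net_cfg <- do.call(generator_config,
                         utils::modifyList(list(seed = config$seed + 1L),
                                           utils::modifyList(
                                             config$generator,
                                             list(network = utils::modifyList(
                                               list(topology = "planted_partition"),
                                               config$generator$network %||% list())))))
      sim <- generate_mention_corpus(net_cfg)
      edges <- extract_mention_edges(sim$corpus)
      net <- build_network(edges, query_term = sim$corpus$query_term)
      metrics <- network_metrics(net, seed = config$seed)
      involvement <- involvement_report(sim$corpus)
      degrees <- degree_stats(net)
      utils::write.csv(degrees$nodes,
                       file.path(config$out_dir, "node_degrees.csv"),
                       row.names = FALSE)
      export_graphml(net, file.path(config$out_dir, "mention_network.graphml"))
      summary$network <- c(unclass(metrics),
                            list(involvement_percent = involvement$percent))
    })
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
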