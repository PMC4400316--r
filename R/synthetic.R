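#' Configuration for the synthetic tweet generator
#'
#' Bundles every knob of the generator with validation. Defaults emulate the
#' statistical structure the downstream analyses consume: each tweet contains
#' the query term, a planted positive/negative sentiment mixture realized
#' through lexicon marker tokens, planted topic word-communities, city and
#' hour-of-day strata, and (for mention corpora) a controllable retweet
#' topology.
#'
#' @param n_tweets number of tweets to generate.
#' @param query_term query term embedded in every tweet.
#' @param p_positive baseline probability that a tweet's true polarity is
#'   positive.
#' @param topic_communities list of pairwise-disjoint character vectors; each
#'   tweet draws its topic words from exactly one community.
#' @param words_per_tweet integer range `c(min, max)` of filler tokens.
#' @param cities data frame with columns `city`, `utc_offset`,
#'   `p_positive_offset` (added to `p_positive` per city, clamped to \[0,1\]),
#'   and optionally `lat`, `lon`, `weight`.
#' @param hour_profile 24 nonnegative sampling weights for local hour bins
#'   1..24.
#' @param negation_rate probability that a positive tweet has "not" injected
#'   immediately before a positive marker (and its truth label flipped).
#' @param positive_markers,negative_markers lexicon tokens planted to realize
#'   the true polarity; they must carry weights of the matching sign in the
#'   lexicon used downstream.
#' @param filler_vocab neutral filler vocabulary (no lexicon weight, not
#'   stopworded).
#' @param network list describing the mention topology: `topology` one of
#'   `"none"`, `"star"`, `"chain"`, `"planted_partition"`; `n_users`;
#'   `n_blocks`, `p_in`, `p_out` (planted partition); `p_retweet` (share of
#'   mention tweets using the "RT @user" form rather than a bare "@user").
#' @param seed integer seed; all generator randomness flows from it.
#' @return validated `generator_config` list.
#' @export
generator_config <- function(n_tweets = 1500L,
                             query_term = "pain",
                             p_positive = 0.3,
                             topic_communities = default_topic_communities(),
                             words_per_tweet = c(2L, 5L),
                             cities = default_cities(),
                             hour_profile = rep(1, 24),
                             negation_rate = 0,
                             positive_markers = c("love", "great", "happy",
                                                  "wonderful", "amazing",
                                                  "glad", "excited", "joy"),
                             negative_markers = c("hurt", "sad", "awful",
                                                  "terrible", "miserable",
                                                  "worst", "hate", "sick"),
                             filler_vocab = default_filler_vocab(),
                             network = list(topology = "none"),
                             seed = 1L) {
  stopifnot(n_tweets >= 1, length(words_per_tweet) == 2,
            words_per_tweet[1] <= words_per_tweet[2])
  probs <- c(p_positive, negation_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(hour_profile) != 24L || any(hour_profile < 0)) {
    stop("hour_profile must be 24 nonnegative weights")
  }
  all_topic <- unlist(topic_communities)
  if (anyDuplicated(all_topic)) stop("topic communities must be pairwise disjoint")
  stopifnot(is.data.frame(cities), all(c("city", "utc_offset") %in% names(cities)))
  if (is.null(cities$p_positive_offset)) cities$p_positive_offset <- 0
  if (is.null(cities$weight)) cities$weight <- 1
  if (is.null(cities$lat)) cities$lat <- 0
  if (is.null(cities$lon)) cities$lon <- 0
  network <- utils::modifyList(
    list(topology = "none", n_users = 50L, n_blocks = 4L,
         p_in = 0.3, p_out = 0.01, p_retweet = 0.7),
    network)
  stopifnot(network$topology %in% c("none", "star", "chain", "planted_partition"))
  structure(list(
    n_tweets = as.integer(n_tweets), query_term = query_term,
    p_positive = p_positive, topic_communities = topic_communities,
    words_per_tweet = as.integer(words_per_tweet), cities = cities,
    hour_profile = hour_profile, negation_rate = negation_rate,
    positive_markers = positive_markers, negative_markers = negative_markers,
    filler_vocab = filler_vocab, network = network, seed = as.integer(seed)
  ), class = "generator_config")
}

#' @rdname generator_config
#' @export
default_topic_communities <- function() {
  list(
    run     = c("running", "marathon", "miles", "race", "training"),
    tech    = c("iphone", "carriers", "temper", "margin", "video"),
    film    = c("movie", "watching", "theater", "popcorn", "screen"),
    morning = c("coffee", "breakfast", "kitchen", "toast", "bagel")
  )
}

#' @rdname generator_config
#' @export
default_filler_vocab <- function() {
  c("today", "tomorrow", "tonight", "week", "month", "game", "school",
    "work", "home", "car", "bus", "music", "song", "phone", "dinner",
    "lunch", "rain", "sun", "dog", "cat")
}

#' @rdname generator_config
#' @export
default_cities <- function() {
  data.frame(
    city = c("Los Angeles", "Chicago", "New York", "London", "Manila"),
    utc_offset = c(-8, -6, -5, 0, 8),
    p_positive_offset = c(0.15, 0.05, 0, -0.05, -0.15),
    lat = c(34.05, 41.88, 40.71, 51.51, 14.60),
    lon = c(-118.24, -87.63, -74.01, -0.13, 120.98),
    weight = 1
  )
}

#' Generate a synthetic tweet corpus with ground truth
#'
#' Every tweet contains the query term; true-positive tweets carry at least
#' one positive marker token, true-negative ones a negative marker; topic
#' words are drawn from a single community per tweet; city and hour follow the
#' configured strata. With `negation_rate > 0`, a fraction of positive tweets
#' gets "not" injected directly before a positive marker and their truth
#' labels flipped, exercising the negation-reversal rule end to end. The run
#' is fully reproducible from `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list with `corpus` (a [tweet_corpus()], `provenance = "synthetic"`)
#'   and `truth` (list: per-tweet tibble `tweets`, named `term_communities`,
#'   named planted `term_counts` excluding the query term).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  n <- config$n_tweets
  cities <- config$cities
  city_idx <- sample.int(nrow(cities), n, replace = TRUE,
                         prob = cities$weight / sum(cities$weight))
  hour_bin <- sample.int(24L, n, replace = TRUE, prob = config$hour_profile)
  p_city <- pmin(1, pmax(0, config$p_positive + cities$p_positive_offset[city_idx]))
  positive <- stats::runif(n) < p_city
  topic_id <- sample.int(length(config$topic_communities), n, replace = TRUE)
  n_users <- max(10L, ceiling(n / 3))
  users <- sprintf("u%05d", sample.int(n_users, n, replace = TRUE))

  texts <- character(n)
  negated <- logical(n)
  planted <- vector("list", n)
  for (i in seq_len(n)) {
    markers_pool <- if (positive[i]) config$positive_markers else config$negative_markers
    markers <- sample(markers_pool, min(length(markers_pool), sample(1:2, 1)))
    comm <- config$topic_communities[[topic_id[i]]]
    topic <- sample(comm, min(length(comm), sample(2:3, 1)))
    rng <- config$words_per_tweet
    n_fill <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
    filler <- if (n_fill > 0) sample(config$filler_vocab, n_fill, replace = TRUE)
              else character(0)
    toks <- sample(c(config$query_term, markers, topic, filler))
    if (positive[i] && config$negation_rate > 0 &&
        stats::runif(1) < config$negation_rate) {
      pos_at <- which(toks %in% config$positive_markers)[1]
      toks <- append(toks, "not", after = pos_at - 1L)
      negated[i] <- TRUE
      positive[i] <- FALSE
    }
    planted[[i]] <- toks
    texts[i] <- paste(toks, collapse = " ")
  }

  local_hour <- ifelse(hour_bin == 24L, 0L, hour_bin)
  utc_hour <- (local_hour - cities$utc_offset[city_idx]) %% 24
  ts <- as.POSIXct("2012-09-15 00:00:00", tz = "UTC") +
    utc_hour * 3600 + sample.int(60, n, replace = TRUE) - 1 +
    (sample.int(60, n, replace = TRUE) - 1) * 60

  tweets <- tibble::tibble(
    id = sprintf("t%06d", seq_len(n)), user = users, text = texts,
    timestamp_utc = ts, city = cities$city[city_idx],
    lat = cities$lat[city_idx], lon = cities$lon[city_idx],
    label = ifelse(positive, "positive", "negative")
  )
  corpus <- tweet_corpus(tweets, query_term = config$query_term,
                         provenance = "synthetic")

  all_planted <- unlist(planted, use.names = FALSE)
  all_planted <- all_planted[all_planted != config$query_term]
  term_counts <- table(all_planted)
  term_communities <- stats::setNames(
    rep(seq_along(config$topic_communities),
        lengths(config$topic_communities)),
    unlist(config$topic_communities))
  truth <- list(
    tweets = tibble::tibble(id = tweets$id,
                            polarity = ifelse(positive, "positive", "negative"),
                            city = tweets$city, hour_bin = hour_bin,
                            topic = topic_id, negated = negated),
    term_communities = term_communities,
    term_counts = stats::setNames(as.integer(term_counts), names(term_counts))
  )
  list(corpus = corpus, truth = truth)
}

#' Generate a synthetic mention/retweet corpus with planted topology
#'
#' Plants a directed user-to-user edge list according to the configured
#' topology and realizes each edge as exactly one tweet whose text begins with
#' `"RT @target"` (with probability `p_retweet`) or `"@target"`, followed by
#' the query term and filler. Star topologies point every spoke at the hub
#' (one high in-degree node); chains give a path graph; planted partitions
#' draw within-block pairs with probability `p_in` and cross-block pairs with
#' `p_out` (warning when `p_in <= p_out`: communities are unrecoverable).
#' Remaining tweets up to `n_tweets` are mention-free.
#'
#' @param config a [generator_config()] whose `network$topology != "none"`.
#' @return list with `corpus` and `truth` (planted `edges` tibble,
#'   `user_blocks`, per-tweet `has_mention`, per-user authored-tweet counts).
#' @export
generate_mention_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$network$topology == "none") {
    stop("generate_mention_corpus requires a network topology")
  }
  withr::with_seed(config$seed, generate_mention_corpus_impl(config))
}

generate_mention_corpus_impl <- function(config) {
  net <- config$network
  n_users <- as.integer(net$n_users)
  users <- sprintf("u%03d", seq_len(n_users))
  blocks <- rep(NA_integer_, n_users)
  edges <- switch(net$topology,
    star = {
      if (n_users < 2L) stop("star topology needs >= 2 users")
      cbind(2:n_users, 1L)
    },
    chain = {
      if (n_users < 2L) stop("chain topology needs >= 2 users")
      cbind(1:(n_users - 1L), 2:n_users)
    },
    planted_partition = {
      if (net$p_in <= net$p_out) {
        warning("p_in <= p_out: planted communities are unrecoverable")
      }
      blocks <- rep(seq_len(net$n_blocks), length.out = n_users)
      pairs <- utils::combn(n_users, 2L)
      same <- blocks[pairs[1L, ]] == blocks[pairs[2L, ]]
      p <- ifelse(same, net$p_in, net$p_out)
      keep <- stats::runif(ncol(pairs)) < p
      pr <- pairs[, keep, drop = FALSE]
      if (ncol(pr) == 0L) {
        matrix(integer(0), ncol = 2L)
      } else {
        flip <- stats::runif(ncol(pr)) < 0.5
        cbind(ifelse(flip, pr[2L, ], pr[1L, ]), ifelse(flip, pr[1L, ], pr[2L, ]))
      }
    }
  )
  n_edges <- nrow(edges)
  n_total <- max(config$n_tweets, n_edges)
  if (config$n_tweets < n_edges) {
    warning(sprintf("n_tweets (%d) < planted edges (%d); emitting %d tweets",
                    config$n_tweets, n_edges, n_edges))
  }

  texts <- character(n_total)
  authors <- character(n_total)
  has_mention <- logical(n_total)
  edge_tweet <- character(n_edges)
  filler_text <- function() {
    paste(sample(config$filler_vocab, sample(2:5, 1), replace = TRUE),
          collapse = " ")
  }
  for (e in seq_len(n_edges)) {
    src <- users[edges[e, 1L]]
    dst <- users[edges[e, 2L]]
    prefix <- if (stats::runif(1) < net$p_retweet) paste0("RT @", dst) else paste0("@", dst)
    texts[e] <- paste(prefix, config$query_term, filler_text())
    authors[e] <- src
    has_mention[e] <- TRUE
    edge_tweet[e] <- sprintf("m%06d", e)
  }
  if (n_total > n_edges) {
    idx <- (n_edges + 1L):n_total
    authors[idx] <- users[sample.int(n_users, length(idx), replace = TRUE)]
    texts[idx] <- vapply(idx, function(i) paste(config$query_term, filler_text()),
                         character(1))
  }
  ts <- as.POSIXct("2013-03-10 00:00:00", tz = "UTC") + seq_len(n_total) * 60
  tweets <- tibble::tibble(
    id = sprintf("m%06d", seq_len(n_total)), user = authors, text = texts,
    timestamp_utc = ts
  )
  corpus <- tweet_corpus(tweets, query_term = config$query_term,
                         provenance = "synthetic")
  truth <- list(
    edges = tibble::tibble(source = users[edges[, 1L]],
                           target = users[edges[, 2L]],
                           tweet_id = edge_tweet),
    user_blocks = stats::setNames(blocks, users),
    has_mention = stats::setNames(has_mention, tweets$id),
    user_tweet_counts = table(authors)
  )
  list(corpus = corpus, truth = truth)
}

#' Generate a timeline corpus with exact planted term occurrence counts
#'
#' Builds a pool of user timelines (as collected when sampling users from a
#' mention network and pulling their recent tweets) in which each tracked term
#' occurs exactly the requested number of times, surrounded by neutral filler.
#' Useful for validating occurrence counting and relative-rate reports against
#' known totals.
#'
#' @param term_counts named integer vector, term -> exact occurrence count.
#' @param n_tweets total tweets in the pool (must be >= 1).
#' @param n_users number of distinct authors, assigned round-robin.
#' @param seed integer seed.
#' @return a [tweet_corpus()] whose whole-token occurrence counts of
#'   `names(term_counts)` equal `term_counts` exactly.
#' @export
generate_timeline_corpus <- function(term_counts, n_tweets, n_users = 100L,
                                     seed = 1L) {
  stopifnot(!is.null(names(term_counts)), n_tweets >= 1)
  withr::with_seed(seed, {
    filler <- setdiff(default_filler_vocab(), tolower(names(term_counts)))
    base <- vapply(seq_len(n_tweets), function(i) {
      paste(sample(filler, sample(3:6, 1), replace = TRUE), collapse = " ")
    }, character(1))
    for (term in names(term_counts)) {
      k <- term_counts[[term]]
      if (k == 0) next
      at <- sample.int(n_tweets, k, replace = TRUE)
      for (i_at in at) base[i_at] <- paste(base[i_at], term)
    }
    tweets <- tibble::tibble(
      id = sprintf("s%06d", seq_len(n_tweets)),
      user = sprintf("u%03d", rep_len(seq_len(n_users), n_tweets)),
      text = base,
      timestamp_utc = as.POSIXct("2013-03-20 00:00:00", tz = "UTC") +
        seq_len(n_tweets) * 60
    )
    tweet_corpus(tweets, query_term = names(term_counts)[1],
                 provenance = "synthetic")
  })
}
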