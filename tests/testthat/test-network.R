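test_that("mention edges point from author to each distinct mentioned handle", {
  corpus <- make_corpus(c("RT @b ouch pain", "no mentions here pain",
                          "@b @c @b pain", "@a self pain"),
                        users = c("a", "x", "d", "a"))
  edges <- extract_mention_edges(corpus)
  expect_equal(edges$source, c("a", "d", "d"))
  expect_equal(edges$target, c("b", "b", "c"))      # dedup within tweet, self dropped

  rt_only <- extract_mention_edges(corpus, retweets_only = TRUE)
  expect_equal(nrow(rt_only), 1L)

  empty <- extract_mention_edges(make_corpus("nothing at all"))
  expect_equal(nrow(empty), 0L)
})

test_that("build_network accumulates multiplicity into weights", {
  edges <- tibble::tibble(source = c("a", "a", "b"), target = c("b", "b", "c"),
                          tweet_id = c("1", "2", "3"))
  net <- build_network(edges)
  expect_equal(igraph::ecount(net), 2L)
  el <- igraph::as_data_frame(net)
  expect_equal(el$weight[el$from == "a" & el$to == "b"], 2)
  expect_equal(igraph::vcount(build_network(edges[0, ])), 0L)
})

test_that("network metrics match closed forms on chains and dyads", {
  chain <- build_network(tibble::tibble(source = c("a", "b", "c", "d"),
                                        target = c("b", "c", "d", "e")))
  m <- network_metrics(chain)
  expect_equal(m$diameter, 4L)
  expect_equal(m$n_wcc, 1L)
  expect_equal(m$n_scc, 5L)
  expect_equal(m$giant_fraction, 1.0)
  expect_gte(m$n_scc, m$n_wcc)

  dyads <- build_network(tibble::tibble(source = c("a", "c"), target = c("b", "d")))
  m2 <- network_metrics(dyads)
  expect_equal(m2$n_wcc, 2L)
  expect_equal(m2$giant_fraction, 0.5)
  expect_equal(m2$density, 2 / 12)
  expect_error(network_metrics(build_network(tibble::tibble(source = character(0),
                                                            target = character(0)))),
               "empty")
})

test_that("metrics agree with Floyd-Warshall/DFS brute force on random digraphs", {
  withr::with_seed(53, {
    for (rep in 1:10) {
      n <- sample(5:25, 1)
      edges <- random_digraph_edges(n, stats::runif(1, 0.03, 0.2))
      if (nrow(edges) == 0) next
      nodes <- sort(unique(c(edges$source, edges$target)))
      net <- build_network(edges)
      mine <- network_metrics(net)
      oracle <- bf_digraph_metrics(edges, nodes)
      expect_equal(mine$n_nodes, oracle$n_nodes)
      expect_equal(mine$n_edges, oracle$n_edges)
      expect_equal(mine$diameter, as.integer(oracle$diameter))
      expect_equal(mine$avg_path_length, oracle$avg_path_length)
      expect_equal(mine$density, oracle$density)
      expect_equal(mine$n_wcc, oracle$n_wcc)
      expect_equal(mine$n_scc, oracle$n_scc)
      expect_equal(mine$giant_fraction, oracle$giant_fraction)
    }
  })
})

test_that("edge reversal preserves undirected metrics and swaps degrees", {
  withr::with_seed(57, {
    edges <- random_digraph_edges(15, 0.12)
  })
  net <- build_network(edges)
  rev_net <- build_network(tibble::tibble(source = edges$target,
                                          target = edges$source))
  m <- network_metrics(net)
  mr <- network_metrics(rev_net)
  expect_equal(mr$n_wcc, m$n_wcc)
  expect_equal(mr$density, m$density)
  expect_equal(mr$diameter, m$diameter)
  d <- degree_stats(net)$nodes
  dr <- degree_stats(rev_net)$nodes
  dr <- dr[match(d$user, dr$user), ]
  expect_equal(d$in_degree, dr$out_degree)
  expect_equal(d$out_degree, dr$in_degree)
})

test_that("degree summaries capture hubs", {
  star <- build_network(tibble::tibble(source = paste0("s", 1:5),
                                       target = rep("hub", 5)))
  d <- degree_stats(star)
  hub <- d$nodes[d$nodes$user == "hub", ]
  expect_equal(hub$in_degree, 5)
  expect_equal(hub$out_degree, 0)
  expect_equal(d$summary$max[d$summary$metric == "in_degree"], 5)
})

test_that("network comparison matches the exact U distribution at n=5+5", {
  same <- compare_networks(c(1, 5, 3, 9, 2), c(1, 5, 3, 9, 2))
  expect_equal(same$mean_difference, 0)
  expect_lt(same$effect_size, 1e-12)

  # completely separated samples: extreme U and effect size
  sep <- compare_networks(c(1, 2, 3, 4, 5), c(10, 20, 30, 40, 50))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, bf_mwu_exact(c(1, 2, 3, 4, 5), c(10, 20, 30, 40, 50))$p)

  withr::with_seed(67, {
    for (rep in 1:20) {
      v <- sample(1:1000, 10)                # distinct values -> exact path
      a <- v[1:5]
      b <- v[6:10]
      oracle <- bf_mwu_exact(a, b)
      mine <- compare_networks(a, b)
      expect_equal(mine$U, oracle$U)
      expect_equal(mine$p, oracle$p, tolerance = 1e-12)
    }
  })

  # tied/large samples fall back to the tie-corrected normal approximation
  withr::with_seed(68, {
    a <- sample(0:3, 60, replace = TRUE)
    b <- sample(0:4, 55, replace = TRUE)
  })
  mine <- compare_networks(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(unname(mine$U), unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  expect_equal(mine$effect_size, abs(mine$z) / sqrt(115))
})

test_that("timeline sampling clamps, is seeded, and keeps most recent tweets", {
  sim <- generate_mention_corpus(generator_config(
    n_tweets = 40, seed = 3, network = list(topology = "chain", n_users = 4)))
  net <- build_network(extract_mention_edges(sim$corpus))
  # pool of 3 eligible users (chain sources), n_users large -> all sampled
  sampled <- sample_user_timelines(net, sim$corpus, n_users = 100,
                                   per_user = 100, seed = 5)
  expect_setequal(unique(sampled$tweets$user),
                  unique(sim$truth$edges$source))
  counts <- table(sim$corpus$tweets$user)[unique(sampled$tweets$user)]
  expect_equal(sort(as.integer(table(sampled$tweets$user))),
               sort(as.integer(counts)))

  again <- sample_user_timelines(net, sim$corpus, n_users = 2, per_user = 3,
                                 seed = 5)
  again2 <- sample_user_timelines(net, sim$corpus, n_users = 2, per_user = 3,
                                  seed = 5)
  expect_identical(again$tweets, again2$tweets)
  expect_true(all(table(again$tweets$user) <= 3))
  # per_user cap keeps the most recent tweets of each sampled user
  u <- again$tweets$user[1]
  pool_u <- sim$corpus$tweets[sim$corpus$tweets$user == u, ]
  newest <- utils::head(pool_u[order(pool_u$timestamp_utc, pool_u$id,
                                     decreasing = TRUE), ], 3)
  expect_setequal(again$tweets$id[again$tweets$user == u], newest$id)

  expect_error(sample_user_timelines(net, make_corpus("no mentions")),
               "eligible")
})

test_that("term frequency report counts whole tokens and scales to reference", {
  corpus <- make_corpus(c("pain and more pain today", "happy happy joy",
                          "painful is not pain", "nothing"))
  rep <- term_frequency_report(corpus, c("happy", "joy", "absent"), "pain")
  expect_equal(rep$frequency[rep$term == "pain"], 3L)   # 'painful' not counted
  expect_equal(rep$frequency[rep$term == "happy"], 2L)
  expect_equal(rep$frequency[rep$term == "absent"], 0L)
  expect_equal(rep$proportion_to_reference[rep$term == "pain"], 1)
  expect_equal(rep$proportion_to_reference[rep$term == "happy"], 0.67)
  expect_error(term_frequency_report(corpus, "x", "missing"), "not found")

  # planted counts come back exactly
  counts <- c(pain = 35L, happy = 73L, sad = 30L)
  pool <- generate_timeline_corpus(counts, n_tweets = 500, seed = 9)
  rep2 <- term_frequency_report(pool, names(counts), "pain")
  expect_equal(stats::setNames(rep2$frequency, rep2$term), counts)
})

test_that("involvement percentage counts mention-bearing tweets", {
  corpus <- make_corpus(c("@b hello pain", "plain pain", "more pain", "zzz"),
                        users = c("a", "b", "c", "d"))
  out <- involvement_report(corpus)
  expect_equal(out$percent, 25.00)
  expect_equal(involvement_report(make_corpus("quiet"))$percent, 0)
  # generator truth agreement
  sim <- generate_mention_corpus(generator_config(
    n_tweets = 120, seed = 31, network = list(topology = "star", n_users = 41)))
  out2 <- involvement_report(sim$corpus)
  expect_equal(out2$n_involved, sum(sim$truth$has_mention))
  expect_equal(out2$n_total, 120L)
})
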