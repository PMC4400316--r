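toy_lexicon <- function() {
  sentiment_lexicon(c(great = 3, good = 3, pain = -2, awful = -3),
                    emoticon_weights = c(":)" = 2, ":(" = -2))
}

test_that("rule scorer sums weights with negation reversal to a unit score", {
  lex <- toy_lexicon()
  # the positive exemplar: negated 'pain' reverses -2 to +1
  toks <- tokenize("Exercise was great! No pain, no gain!", drop_query = FALSE)[[1]]
  res <- rule_score(toks, lex)
  expect_equal(res$score, 4)            # great +3, pain reversed to +1
  expect_equal(res$polarity, "positive")
  expect_true(res$matches$negated[res$matches$term == "pain"])

  # no matches -> neutral with zero confidence
  empty <- rule_score(c("table", "chair"), lex)
  expect_equal(empty$score, 0)
  expect_equal(empty$polarity, "neutral")
  expect_equal(empty$confidence, 0)

  # reversal-to-unit: 'not good' contributes -1, not -3
  ng <- rule_score(c("not", "good"), lex)
  expect_equal(ng$score, -1)
  expect_equal(ng$polarity, "negative")

  # negator acts only within the 5 preceding tokens
  far <- rule_score(c("not", "a", "b", "c", "d", "e", "good"), lex)
  expect_equal(far$score, 3)

  # emoticons are weighted but never negated
  emo <- rule_score(c("not", ":)"), lex)
  expect_equal(emo$score, 2)

  expect_equal(rule_score(c("great", "good"), lex)$confidence, 1)  # capped
  expect_equal(rule_score("good", lex)$confidence, 3 / 5)
})

test_that("rule scorer agrees with a brute-force window scan on random streams", {
  lex <- default_lexicon()
  vocab <- c(names(lex$weights)[1:30], lex$negators[1:10],
             names(lex$emoticon_weights)[1:5], paste0("neutral", 1:20))
  withr::with_seed(12, {
    for (i in 1:1000) {
      toks <- sample(vocab, sample(0:12, 1), replace = TRUE)
      mine <- rule_score(toks, lex)
      oracle <- bf_rule_score(toks, lex)
      expect_identical(mine$score, oracle$score)
      expect_identical(nrow(mine$matches), oracle$n_matches)
    }
  })
})

test_that("rule score is antisymmetric under lexicon negation (no negators)", {
  lex <- sentiment_lexicon(c(up = 2, down = -3, hi = 4), negators = character(0))
  neg <- sentiment_lexicon(c(up = -2, down = 3, hi = -4), negators = character(0))
  withr::with_seed(40, {
    for (i in 1:50) {
      toks <- sample(c("up", "down", "hi", "zz"), sample(1:8, 1), replace = TRUE)
      expect_equal(rule_score(toks, lex)$score, -rule_score(toks, neg)$score)
    }
  })
})

test_that("risk-ratio ranking prefers class-pure terms and mirrors symmetrically", {
  docs <- list(c("wolf", "moon"), c("wolf", "sun"), c("wolf", "moon"),
               c("moon", "sun"), c("sun", "tree"), c("sun", "moon"))
  labels <- c("positive", "positive", "positive", "negative", "negative", "negative")
  ranked <- risk_ratio_rank(docs, labels)
  # 'wolf' only in positive docs; 'moon' appears in both classes equally often
  expect_lt(match("wolf", ranked$term), match("moon", ranked$term))

  # hand-computed: wolf d_pos=3 d_neg=0, s=0.5, N=3 each:
  # RR = (3.5/4) / (0.5/4) = 7
  expect_equal(ranked$rr[ranked$term == "wolf"], 7)

  # mirrored corpus: the RR of a positive marker is 1/RR of its negative mirror
  mirrored <- risk_ratio_rank(docs, rev(labels))
  expect_equal(ranked$rr[ranked$term == "wolf"],
               1 / mirrored$rr[mirrored$term == "wolf"])

  expect_error(risk_ratio_rank(docs, rep("positive", 6)), "both classes")
})

test_that("naive Bayes separates separable corpora and matches exact Bayes", {
  docs <- list("yes", "yes", "no", "no")
  labels <- c("positive", "positive", "negative", "negative")
  model <- train_nb(docs, labels, k_features = 2)
  acc <- mean(vapply(seq_along(docs), function(i) {
    (nb_predict(model, docs[[i]]) > 0.5) == (labels[i] == "positive")
  }, logical(1)))
  expect_equal(acc, 1.0)

  # uninformative corpus: posterior equals the prior for any input
  same <- list(c("a", "b"), c("a", "b"))
  uninfo <- train_nb(same, c("positive", "negative"), k_features = 2)
  expect_equal(nb_predict(uninfo, c("a", "a", "b")), 0.5, tolerance = 1e-12)
  expect_equal(nb_predict(uninfo, character(0)), 0.5, tolerance = 1e-12)

  # brute-force Bayes enumeration on tiny corpora, tolerance 1e-12
  withr::with_seed(77, {
    vocab <- c("v1", "v2", "v3", "v4", "v5")
    for (rep in 1:10) {
      docs <- lapply(1:6, function(i) sample(vocab, sample(1:4, 1), replace = TRUE))
      labels <- c("positive", "positive", "positive",
                  "negative", "negative", "negative")
      k <- sample(1:5, 1)
      model <- suppressWarnings(train_nb(docs, labels, k_features = k))
      newdoc <- sample(vocab, 3, replace = TRUE)
      expect_equal(nb_predict(model, newdoc),
                   suppressWarnings(bf_nb_posterior(docs, labels, k, newdoc)),
                   tolerance = 1e-12)
    }
  })
})

test_that("naive Bayes is invariant to duplicating the training corpus", {
  docs <- list(c("a", "b"), c("b", "c"), c("c", "c"), c("a", "d"))
  labels <- c("positive", "positive", "negative", "negative")
  m1 <- train_nb(docs, labels, k_features = 4)
  m2 <- train_nb(c(docs, docs), c(labels, labels), k_features = 4)
  expect_equal(m1$prior_positive, m2$prior_positive)
  expect_equal(m1$lik_positive, m2$lik_positive, tolerance = 1e-12)
  for (toks in list("a", c("b", "c"), c("a", "b", "c", "d"))) {
    expect_equal(nb_predict(m1, toks), nb_predict(m2, toks), tolerance = 1e-12)
  }

  # k_features beyond the vocabulary clamps with a warning
  expect_warning(train_nb(docs, labels, k_features = 99), "clamp")
})

test_that("hybrid arbitration: rule first, NB fallback, 0.5 tie is negative", {
  lex <- toy_lexicon()
  strong_rule <- rule_score(c("great", "good"), lex)        # score > 0
  res <- hybrid_classify(strong_rule, nb_posterior = 0.1)
  expect_equal(res$hybrid_polarity, "positive")
  expect_equal(res$source, "rule")

  zero_rule <- rule_score("table", lex)
  res2 <- hybrid_classify(zero_rule, nb_posterior = 0.9)
  expect_equal(res2$hybrid_polarity, "positive")
  expect_equal(res2$source, "nb")
  expect_equal(res2$confidence, 0.8)

  res3 <- hybrid_classify(zero_rule, nb_posterior = 0.5)
  expect_equal(res3$hybrid_polarity, "negative")

  # invariant: source is "rule" iff the rule score is nonzero
  expect_equal(hybrid_classify(strong_rule, 0.5)$source, "rule")
  expect_equal(hybrid_classify(zero_rule, 0.99)$source, "nb")
})

test_that("percent_positive counts hybrid verdicts", {
  fake <- tibble::tibble(hybrid_polarity = c(rep("positive", 42),
                                             rep("negative", 58)))
  expect_equal(percent_positive(fake), 42)
  expect_error(percent_positive(tibble::tibble()), "no sentiment")
})

test_that("hybrid recovers a planted sentiment mixture within binomial error", {
  sim <- generate_corpus(generator_config(
    n_tweets = 10000, p_positive = 0.3, seed = 19,
    cities = data.frame(city = "X", utc_offset = 0, p_positive_offset = 0)))
  res <- classify_corpus(sim$corpus, default_lexicon())
  expect_lt(abs(percent_positive(res) - 30), 100 * 3 * sqrt(0.3 * 0.7 / 10000))
  # classification agrees with truth tweet by tweet on clean markers
  expect_equal(res$hybrid_polarity, sim$truth$tweets$polarity)
})

test_that("the negation rule beats a no-negation ablation under injection", {
  sim <- generate_corpus(generator_config(n_tweets = 1500, p_positive = 0.6,
                                          negation_rate = 0.4, seed = 29))
  lex <- default_lexicon()
  ablated <- sentiment_lexicon(lex$weights, lex$emoticon_weights,
                               negators = character(0))
  truth <- sim$truth$tweets$polarity
  acc <- function(l) {
    res <- classify_corpus(sim$corpus, l)
    mean(res$hybrid_polarity == truth)
  }
  expect_gt(acc(lex), acc(ablated))
})

test_that("staged validation reports per-corpus percents and holdout kappas", {
  lex <- default_lexicon()
  train <- generate_corpus(generator_config(n_tweets = 400, seed = 51))
  streams <- tokenize(train$corpus$tweets$text, query_term = "pain",
                      drop_query = FALSE)
  nb <- train_nb(streams, train$truth$tweets$polarity, k_features = 50)
  aux <- list(
    happy = generate_corpus(generator_config(n_tweets = 100, query_term = "happy",
                                             p_positive = 0.9, seed = 52))$corpus,
    sad = generate_corpus(generator_config(n_tweets = 100, query_term = "sad",
                                           p_positive = 0.2, seed = 53))$corpus)
  holdout <- generate_corpus(generator_config(n_tweets = 100, seed = 54))
  out <- staged_validation(lex, nb, aux, holdout$corpus,
                           human_labels = holdout$truth$tweets$polarity)
  expect_equal(out$stage1$corpus, c("happy", "sad"))
  expect_gt(out$stage1$pct_rule_positive[1], out$stage1$pct_rule_positive[2])
  expect_true(all(c("kappa_rule_nb", "kappa_human_hybrid") %in%
                    names(out$stage2)))
  expect_true(abs(out$stage2$kappa_rule_nb) <= 1)
})

test_that("NB models survive JSON serialization", {
  docs <- list(c("a", "b"), c("b", "c"), c("c", "c"), c("a", "d"))
  model <- train_nb(docs, c("positive", "positive", "negative", "negative"),
                    k_features = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_nb_model(model, path)
  back <- read_nb_model(path)
  expect_equal(nb_predict(back, c("a", "c")), nb_predict(model, c("a", "c")),
               tolerance = 1e-12)
})
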