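#' Rule-based lexicon sentiment score
#'
#' Sums the signed lexicon weights of matched tokens. A weighted keyword whose
#' 5 preceding tokens contain a negator has its contribution reversed to a
#' unit score of the opposite sign (weight +3 under negation contributes -1).
#' Emoticons contribute their weights and are never negated. Polarity is the
#' sign of the total; confidence is `min(1, |score|/5)` and is 0 exactly when
#' nothing matched.
#'
#' @param tokens an ordered token stream (character vector), e.g. one element
#'   of [tokenize()] run with `drop_query = FALSE`.
#' @param lexicon a [sentiment_lexicon()].
#' @param negation_window how many preceding tokens a negator can act across.
#' @return list of class `rule_result`: `score`, `polarity` (`"positive"`,
#'   `"negative"`, `"neutral"`), `confidence`, and `matches` (tibble: `term`,
#'   `contribution`, `negated`).
#' @export
rule_score <- function(tokens, lexicon, negation_window = 5L) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"))
  n <- length(tokens)
  terms <- character(0); contribs <- numeric(0); negs <- logical(0)
  if (n > 0L) {
    is_negator <- tokens %in% lexicon$negators
    for (i in seq_len(n)) {
      tok <- tokens[i]
      w <- lexicon$emoticon_weights[tok]
      if (!is.na(w)) {                      # emoticons: weighted, never negated
        terms <- c(terms, tok); contribs <- c(contribs, w); negs <- c(negs, FALSE)
        next
      }
      w <- lexicon$weights[tok]
      if (is.na(w)) next
      lo <- max(1L, i - negation_window)
      negated <- i > 1L && any(is_negator[lo:(i - 1L)])
      contrib <- if (negated) -sign(w) else as.numeric(w)
      terms <- c(terms, tok); contribs <- c(contribs, contrib)
      negs <- c(negs, negated)
    }
  }
  score <- sum(contribs)
  polarity <- if (score > 0) "positive" else if (score < 0) "negative" else "neutral"
  confidence <- if (length(contribs) == 0L) 0 else min(1, abs(score) / 5)
  structure(list(score = score, polarity = polarity, confidence = confidence,
                 matches = tibble::tibble(term = terms, contribution = contribs,
                                          negated = negs)),
            class = "rule_result")
}

#' Rank features by risk ratio
#'
#' For each term, the smoothed risk ratio of document frequencies
#' `RR(t) = [(d_pos(t)+s)/(N_pos+2s)] / [(d_neg(t)+s)/(N_neg+2s)]` is computed
#' over the labeled documents; features are ranked by `max(RR, 1/RR)`
#' descending, so the most class-discriminative terms (in either direction)
#' come first. Ties are broken lexicographically.
#'
#' @param tokens_list list of token streams, one per document.
#' @param labels character vector, `"positive"`/`"negative"`, one per document.
#' @param smoothing additive smoothing constant `s` (default 0.5).
#' @return tibble with columns `term`, `rr`, `discriminativeness`, ranked.
#' @export
risk_ratio_rank <- function(tokens_list, labels, smoothing = 0.5) {
  stopifnot(length(tokens_list) == length(labels))
  labels <- as.character(labels)
  if (!all(c("positive", "negative") %in% labels)) {
    stop("both classes must be present in the labels")
  }
  docsets <- lapply(tokens_list, unique)
  vocab <- sort(unique(unlist(docsets, use.names = FALSE)))
  pos <- labels == "positive"
  d_pos <- table(factor(unlist(docsets[pos], use.names = FALSE), levels = vocab))
  d_neg <- table(factor(unlist(docsets[!pos], use.names = FALSE), levels = vocab))
  n_pos <- sum(pos); n_neg <- sum(!pos)
  rr <- ((as.numeric(d_pos) + smoothing) / (n_pos + 2 * smoothing)) /
        ((as.numeric(d_neg) + smoothing) / (n_neg + 2 * smoothing))
  disc <- pmax(rr, 1 / rr)
  ord <- order(-disc, vocab)
  tibble::tibble(term = vocab[ord], rr = rr[ord], discriminativeness = disc[ord])
}

#' Train the Naive Bayes sentiment model
#'
#' Multinomial Naive Bayes with "smoothed relative frequency" features: the
#' top `k_features` terms by [risk_ratio_rank()] are selected; each training
#' document contributes its term relative frequencies (term count / document
#' token count) restricted to the selected features; class-conditional
#' likelihoods are add-one-smoothed multinomial estimates over the class-mean
#' relative frequencies (invariant to duplicating the training corpus), and
#' priors are the class proportions.
#'
#' @param tokens_list list of token streams, one per document.
#' @param labels `"positive"`/`"negative"` per document.
#' @param k_features number of features to keep (clamped to the vocabulary
#'   size with a warning).
#' @param smoothing risk-ratio smoothing passed to [risk_ratio_rank()].
#' @return object of class `nb_model`: `prior_positive`, `features`,
#'   `lik_positive`, `lik_negative` (named, each summing to 1), `k`.
#' @export
train_nb <- function(tokens_list, labels, k_features = 2000L, smoothing = 0.5) {
  stopifnot(k_features >= 1)
  labels <- as.character(labels)
  ranked <- risk_ratio_rank(tokens_list, labels, smoothing = smoothing)
  if (k_features > nrow(ranked)) {
    warning(sprintf("k_features (%d) exceeds vocabulary size (%d); clamping",
                    k_features, nrow(ranked)))
    k_features <- nrow(ranked)
  }
  features <- ranked$term[seq_len(k_features)]
  pos <- labels == "positive"
  relfreq_total <- function(docs) {
    acc <- stats::setNames(numeric(length(features)), features)
    for (toks in docs) {
      if (length(toks) == 0L) next
      counts <- table(factor(toks[toks %in% features], levels = features))
      acc <- acc + as.numeric(counts) / length(toks)
    }
    acc
  }
  # class-mean relative frequencies: invariant to duplicating the corpus
  f_pos <- relfreq_total(tokens_list[pos]) / sum(pos)
  f_neg <- relfreq_total(tokens_list[!pos]) / sum(!pos)
  lik <- function(f) (f + 1) / (sum(f) + length(features))
  structure(list(
    prior_positive = mean(pos),
    features = features,
    lik_positive = lik(f_pos),
    lik_negative = lik(f_neg),
    k = k_features
  ), class = "nb_model")
}

#' Naive Bayes posterior for a token stream
#'
#' Multinomial posterior over the model's selected features; tokens outside
#' the feature set are ignored, and a stream matching no feature returns the
#' prior.
#'
#' @param model an [train_nb()] model.
#' @param tokens a token stream (character vector).
#' @return `P(positive | tokens)`, a probability.
#' @export
nb_predict <- function(model, tokens) {
  stopifnot(inherits(model, "nb_model"))
  counts <- table(factor(tokens[tokens %in% model$features],
                         levels = model$features))
  counts <- as.numeric(counts)
  log_pos <- log(model$prior_positive) + sum(counts * log(model$lik_positive))
  log_neg <- log(1 - model$prior_positive) + sum(counts * log(model$lik_negative))
  1 / (1 + exp(log_neg - log_pos))
}

#' Combine rule and Naive Bayes verdicts into the hybrid classification
#'
#' The rule decides whenever it matched anything with a nonzero total
#' (`source = "rule"`); otherwise the Naive Bayes posterior decides
#' (`source = "nb"`), positive iff the posterior exceeds 0.5 (an exact 0.5 tie
#' is classified negative). Hybrid confidence is the rule confidence or
#' `|2 posterior - 1|` respectively.
#'
#' @param rule a [rule_score()] result.
#' @param nb_posterior `P(positive | tokens)` from [nb_predict()]; defaults to
#'   an uninformative 0.5 when no model is available.
#' @return list of class `sentiment_result`: `rule`, `nb_posterior_positive`,
#'   `hybrid_polarity`, `source`, `confidence`.
#' @export
hybrid_classify <- function(rule, nb_posterior = 0.5) {
  stopifnot(inherits(rule, "rule_result"))
  if (rule$score != 0) {
    polarity <- if (rule$score > 0) "positive" else "negative"
    source <- "rule"
    confidence <- rule$confidence
  } else {
    polarity <- if (nb_posterior > 0.5) "positive" else "negative"
    source <- "nb"
    confidence <- abs(2 * nb_posterior - 1)
  }
  structure(list(rule = rule, nb_posterior_positive = nb_posterior,
                 hybrid_polarity = polarity, source = source,
                 confidence = confidence),
            class = "sentiment_result")
}

#' Classify every tweet in a corpus
#'
#' Tokenizes with the query term retained (the lexicon may weight it), applies
#' the rule scorer, the Naive Bayes model when supplied, and the hybrid
#' arbitration.
#'
#' @param corpus a [tweet_corpus()].
#' @param lexicon a [sentiment_lexicon()].
#' @param nb_model optional [train_nb()] model for the statistical fallback.
#' @param negation_window negation window for the rule scorer.
#' @return tibble with one row per tweet: `id`, `rule_score`, `rule_polarity`,
#'   `nb_posterior_positive`, `hybrid_polarity`, `source`, `confidence`, plus
#'   `city` and `local_hour_bin` when present on the corpus.
#' @export
classify_corpus <- function(corpus, lexicon = default_lexicon(),
                            nb_model = NULL, negation_window = 5L) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  streams <- tokenize(corpus$tweets$text, query_term = corpus$query_term,
                      drop_query = FALSE)
  rows <- lapply(seq_along(streams), function(i) {
    rr <- rule_score(streams[[i]], lexicon, negation_window = negation_window)
    post <- if (is.null(nb_model)) 0.5 else nb_predict(nb_model, streams[[i]])
    hy <- hybrid_classify(rr, post)
    tibble::tibble(id = corpus$tweets$id[i], rule_score = rr$score,
                   rule_polarity = rr$polarity,
                   nb_posterior_positive = post,
                   hybrid_polarity = hy$hybrid_polarity, source = hy$source,
                   confidence = hy$confidence)
  })
  out <- do.call(rbind, rows)
  for (extra in c("city", "local_hour_bin")) {
    if (!is.null(corpus$tweets[[extra]])) out[[extra]] <- corpus$tweets[[extra]]
  }
  out
}

#' Percentage of positive classifications
#'
#' @param results a [classify_corpus()] tibble (or anything with a
#'   `hybrid_polarity` column).
#' @return percentage of rows classified positive (0-100 scale).
#' @export
percent_positive <- function(results) {
  if (!"hybrid_polarity" %in% names(results) ||
      length(results$hybrid_polarity) == 0L) {
    stop("no sentiment results supplied")
  }
  pol <- results$hybrid_polarity
  100 * mean(pol == "positive")
}

#' Staged classifier validation harness
#'
#' Stage 1 runs the rule-based and Naive Bayes components separately over a
#' set of auxiliary corpora (e.g. searches for "happy", "sad", "apple") and
#' reports the percent classified positive by each component. Stage 2 runs
#' both components and the hybrid over a holdout corpus and reports
#' chance-corrected agreement: rule vs NB, hybrid vs each component, and
#' (when human labels are given) human vs hybrid.
#'
#' @param lexicon a [sentiment_lexicon()].
#' @param nb_model a trained [train_nb()] model.
#' @param aux_corpora named list of [tweet_corpus()] objects for stage 1.
#' @param holdout a [tweet_corpus()] for stage 2.
#' @param human_labels optional character vector of `"positive"`/`"negative"`
#'   holdout annotations.
#' @return list with `stage1` (tibble: corpus, pct_rule_positive,
#'   pct_nb_positive) and `stage2` (tibble of kappas plus percent positive per
#'   component).
#' @export
staged_validation <- function(lexicon, nb_model, aux_corpora, holdout,
                              human_labels = NULL) {
  component_labels <- function(corpus) {
    streams <- tokenize(corpus$tweets$text, query_term = corpus$query_term,
                        drop_query = FALSE)
    rule <- vapply(streams, function(s) rule_score(s, lexicon)$score, numeric(1))
    post <- vapply(streams, function(s) nb_predict(nb_model, s), numeric(1))
    list(rule = ifelse(rule > 0, "positive", "negative"),
         nb = ifelse(post > 0.5, "positive", "negative"),
         hybrid = vapply(seq_along(streams), function(i) {
           hybrid_classify(rule_score(streams[[i]], lexicon), post[i])$hybrid_polarity
         }, character(1)))
  }
  stage1 <- do.call(rbind, lapply(names(aux_corpora), function(nm) {
    lab <- component_labels(aux_corpora[[nm]])
    tibble::tibble(corpus = nm,
                   pct_rule_positive = 100 * mean(lab$rule == "positive"),
                   pct_nb_positive = 100 * mean(lab$nb == "positive"))
  }))
  lab <- component_labels(holdout)
  stage2 <- tibble::tibble(
    pct_rule_positive = 100 * mean(lab$rule == "positive"),
    pct_nb_positive = 100 * mean(lab$nb == "positive"),
    pct_hybrid_positive = 100 * mean(lab$hybrid == "positive"),
    kappa_rule_nb = cohens_kappa(lab$rule, lab$nb)$kappa,
    kappa_hybrid_rule = cohens_kappa(lab$hybrid, lab$rule)$kappa,
    kappa_hybrid_nb = cohens_kappa(lab$hybrid, lab$nb)$kappa,
    kappa_human_hybrid = if (is.null(human_labels)) NA_real_ else
      cohens_kappa(human_labels, lab$hybrid)$kappa
  )
  list(stage1 = stage1, stage2 = stage2)
}
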