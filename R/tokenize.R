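#' Default English stopword list
#'
#' A fixed ~120-word list of high-frequency English function words. Negators
#' (no, not, never, don't, can't, ...) are deliberately excluded: they are
#' among the most frequent terms in emotive microblog corpora and they drive
#' the sentiment negation-reversal rule, so removing them would destroy both
#' the term graph and the classifier. The retweet marker "rt" is stopworded.
#'
#' @return character vector of stopwords.
#' @export
default_stopwords <- function() {
  c(
    "a", "about", "above", "after", "again", "all", "am", "an", "and", "any",
    "are", "as", "at", "be", "because", "been", "before", "being", "below",
    "between", "both", "but", "by", "did", "do", "does", "doing", "down",
    "during", "each", "few", "for", "from", "further", "had", "has", "have",
    "having", "he", "her", "here", "hers", "herself", "him", "himself", "his",
    "how", "i", "if", "in", "into", "is", "it", "its", "itself", "just", "me",
    "more", "most", "my", "myself", "now", "of", "off", "on", "once", "only",
    "or", "other", "our", "ours", "ourselves", "out", "over", "own", "rt",
    "same", "she", "so", "some", "such", "than", "that", "the", "their",
    "theirs", "them", "themselves", "then", "there", "these", "they", "this",
    "those", "through", "to", "too", "under", "until", "up", "very", "was",
    "we", "were", "what", "when", "where", "which", "while", "who", "whom",
    "why", "will", "with", "you", "your", "yours", "yourself", "yourselves"
  )
}

#' Tokenize tweet text
#'
#' Lowercases, removes URLs and @-mentions, folds `#hashtag` to `hashtag`,
#' strips punctuation except intra-word apostrophes (so contractions like
#' `don't` survive as single tokens), preserves emoticons as tokens, drops
#' stopwords and (optionally) the query term itself. Token order and
#' multiplicity are preserved.
#'
#' @param text character vector of raw tweet texts.
#' @param query_term query term to drop (ignored when `drop_query = FALSE`).
#' @param stopwords character vector of tokens to drop; negators must not be
#'   stopworded if the streams feed the sentiment rule.
#' @param emoticons character vector of emoticon strings to preserve verbatim.
#' @param drop_query drop the query term from the stream? `TRUE` for graph
#'   statistics (the query term would link everything), `FALSE` for sentiment
#'   scoring (the lexicon may weight it).
#' @return a list of character vectors, one ordered token stream per input text.
#' @export
tokenize <- function(text, query_term = NULL, stopwords = default_stopwords(),
                     emoticons = default_emoticons(), drop_query = TRUE) {
  query <- if (drop_query && !is.null(query_term)) tolower(query_term) else NULL
  lapply(text, tokenize_one, query = query, stopwords = stopwords,
         emoticons = emoticons)
}

tokenize_one <- function(text, query, stopwords, emoticons) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  text <- gsub("[’‘]", "'", text)          # curly -> straight quote
  text <- gsub("https?://\\S+|www\\.\\S+", " ", text)
  pieces <- strsplit(trimws(text), "\\s+")[[1]]
  out <- character(0)
  for (p in pieces) {
    if (p %in% emoticons) { out <- c(out, p); next }
    # emoticon glued to trailing punctuation, e.g. ":)!"
    stripped <- sub("[.,!?]+$", "", p)
    if (stripped %in% emoticons) { out <- c(out, stripped); next }
    if (grepl("^@", p)) next                          # mentions are edges, not terms
    w <- tolower(p)
    w <- sub("^#", "", w)                             # hashtag folds to its word
    w <- gsub("[^a-z0-9']+", " ", w)
    for (tok in strsplit(trimws(w), "\\s+")[[1]]) {
      tok <- gsub("^'+|'+$", "", tok)                 # trim quoting apostrophes
      if (!nzchar(tok)) next
      if (tok %in% stopwords) next
      if (!is.null(query) && tok == query) next
      out <- c(out, tok)
    }
  }
  out
}

#' Localize tweet timestamps to city wall-clock hour bins
#'
#' Adds a `local_hour_bin` column: the local hour of day in bins 1..24, where
#' bin h covers h:00-h:59 for h in 1..23 and bin 24 covers 00:00-00:59 (the
#' "at 2400" convention used on hourly sentiment axes). Offsets are fixed
#' per-city UTC offsets in hours; no daylight-saving adjustment is applied.
#'
#' @param corpus a [tweet_corpus()]; every tweet must have a `city`.
#' @param offsets named numeric vector, city -> UTC offset in hours.
#' @return the corpus with `local_hour_bin` (integer 1..24) and
#'   `local_timestamp` columns added.
#' @export
localize_timestamps <- function(corpus, offsets) {
  stopifnot(inherits(corpus, "tweet_corpus"), is.numeric(offsets))
  cities <- corpus$tweets$city
  missing <- setdiff(unique(cities), names(offsets))
  if (length(missing) > 0L || anyNA(cities)) {
    if (anyNA(cities)) missing <- c(missing, "<NA>")
    stop("no UTC offset for city/cities: ", paste(missing, collapse = ", "))
  }
  local <- corpus$tweets$timestamp_utc + offsets[cities] * 3600
  hour <- as.integer(format(local, "%H", tz = "UTC"))
  corpus$tweets$local_timestamp <- local
  corpus$tweets$local_hour_bin <- ifelse(hour == 0L, 24L, hour)
  corpus
}
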