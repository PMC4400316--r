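#' Construct a tweet corpus
#'
#' A corpus is an ordered collection of tweet records plus the query term the
#' collection was (notionally) searched for and a provenance tag. Tweets are
#' stored in a tibble with one row per tweet; optional columns (`city`, `lat`,
#' `lon`, `label`, `local_hour_bin`) are filled with `NA` when absent.
#'
#' @param tweets a data frame with at least columns `id`, `user`, `text`,
#'   `timestamp_utc` (`POSIXct`, UTC). Optional columns: `city`, `lat`, `lon`,
#'   `label` (`"positive"`/`"negative"`/`NA`).
#' @param query_term the search term the corpus is built around (scalar string).
#' @param provenance one of `"raw"`, `"reduced"`, `"synthetic"`.
#' @return an object of class `tweet_corpus`: a list with elements `tweets`
#'   (tibble), `query_term` and `provenance`.
#' @export
tweet_corpus <- function(tweets, query_term = "pain",
                         provenance = c("raw", "reduced", "synthetic")) {
  provenance <- match.arg(provenance)
  stopifnot(is.data.frame(tweets))
  required <- c("id", "user", "text", "timestamp_utc")
  missing <- setdiff(required, names(tweets))
  if (length(missing) > 0L) {
    stop("corpus is missing required column(s): ", paste(missing, collapse = ", "))
  }
  tweets <- tibble::as_tibble(tweets)
  tweets$id <- as.character(tweets$id)
  tweets$user <- as.character(tweets$user)
  tweets$text <- as.character(tweets$text)
  if (anyDuplicated(tweets$id)) {
    dup <- unique(tweets$id[duplicated(tweets$id)])
    stop("duplicate tweet id(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (!inherits(tweets$timestamp_utc, "POSIXct")) {
    tweets$timestamp_utc <- as.POSIXct(tweets$timestamp_utc, tz = "UTC")
  }
  attr(tweets$timestamp_utc, "tzone") <- "UTC"
  for (opt in c("city", "label")) {
    if (is.null(tweets[[opt]])) tweets[[opt]] <- NA_character_
  }
  for (opt in c("lat", "lon")) {
    if (is.null(tweets[[opt]])) tweets[[opt]] <- NA_real_
  }
  bad_lat <- !is.na(tweets$lat) & (tweets$lat < -90 | tweets$lat > 90)
  bad_lon <- !is.na(tweets$lon) & (tweets$lon < -180 | tweets$lon > 180)
  if (any(bad_lat) || any(bad_lon)) stop("latitude/longitude out of range")
  bad_label <- !is.na(tweets$label) & !tweets$label %in% c("positive", "negative")
  if (any(bad_label)) stop("label must be 'positive' or 'negative' (or NA)")
  structure(
    list(tweets = tweets, query_term = as.character(query_term)[1],
         provenance = provenance),
    class = "tweet_corpus"
  )
}

#' @export
print.tweet_corpus <- function(x, ...) {
  cat(sprintf("<tweet_corpus> %d tweets | query term: '%s' | provenance: %s\n",
              nrow(x$tweets), x$query_term, x$provenance))
  print(utils::head(x$tweets, 5L))
  invisible(x)
}

#' @export
length.tweet_corpus <- function(x) nrow(x$tweets)

#' Remove duplicate tweets
#'
#' Collapses the corpus to its "reduced" form: tweets whose text is identical
#' after case-folding and whitespace collapsing are counted once, keeping the
#' first occurrence in corpus order.
#'
#' @param corpus a [tweet_corpus()].
#' @return the reduced corpus (`provenance = "reduced"`).
#' @export
deduplicate <- function(corpus) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  key <- normalize_text(corpus$tweets$text)
  keep <- !duplicated(key)
  tweet_corpus(corpus$tweets[keep, , drop = FALSE],
               query_term = corpus$query_term, provenance = "reduced")
}

# case-folded, whitespace-collapsed text used as the dedup equality key
normalize_text <- function(text) {
  out <- tolower(text)
  out <- gsub("\\s+", " ", out)
  trimws(out)
}
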