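#' Read a tweet corpus from JSON-lines or CSV
#'
#' JSON-lines files carry one JSON object per line with keys `id`, `user`,
#' `text`, `timestamp_utc` (ISO-8601), and optionally `city`, `lat`, `lon`,
#' `label`. CSV files carry the same fields as columns with a header row.
#' Record order is preserved.
#'
#' @param path path to a `.jsonl`/`.ndjson` or `.csv` file (UTF-8).
#' @param query_term query term to attach to the corpus.
#' @param format `"auto"` (by file extension), `"jsonl"` or `"csv"`.
#' @return a [tweet_corpus()] with `provenance = "raw"`.
#' @export
parse_tweets <- function(path, query_term = "pain",
                         format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  df <- if (format == "csv") parse_tweets_csv(path) else parse_tweets_jsonl(path)
  tweet_corpus(df, query_term = query_term, provenance = "raw")
}

parse_tweets_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records in ", path)
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) {
                      stop(sprintf("malformed JSON record at line %d of %s: %s",
                                   i, path, conditionMessage(e)), call. = FALSE)
                    })
    for (field in c("id", "user", "text", "timestamp_utc")) {
      if (is.null(rec[[field]]) || length(rec[[field]]) != 1L || is.na(rec[[field]])) {
        stop(sprintf("record at line %d of %s is missing field '%s'",
                     i, path, field), call. = FALSE)
      }
    }
    records[[i]] <- tibble::tibble(
      id = as.character(rec$id),
      user = as.character(rec$user),
      text = as.character(rec$text),
      timestamp_utc = parse_iso8601(rec$timestamp_utc, i, path),
      city = if (is.null(rec$city)) NA_character_ else as.character(rec$city),
      lat = if (is.null(rec$lat)) NA_real_ else as.numeric(rec$lat),
      lon = if (is.null(rec$lon)) NA_real_ else as.numeric(rec$lon),
      label = if (is.null(rec$label)) NA_character_ else as.character(rec$label)
    )
  }
  do.call(rbind, records)
}

parse_tweets_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  for (field in c("id", "user", "text", "timestamp_utc")) {
    if (is.null(df[[field]])) stop("CSV is missing required column '", field, "'")
    bad <- which(is.na(df[[field]]) | !nzchar(as.character(df[[field]])))
    if (length(bad) > 0L) {
      stop(sprintf("record at line %d of %s is missing field '%s'",
                   bad[1] + 1L, path, field))  # +1 for the header row
    }
  }
  df$timestamp_utc <- parse_iso8601(df$timestamp_utc, NA, path)
  df
}

parse_iso8601 <- function(x, line, path) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  if (anyNA(out)) {
    where <- if (is.na(line)) "" else sprintf(" at line %d", line)
    stop(sprintf("unparseable timestamp%s of %s", where, path), call. = FALSE)
  }
  out
}

#' Write a corpus to JSON-lines
#'
#' Inverse of [parse_tweets()]: one JSON object per tweet, ISO-8601 UTC
#' timestamps, optional fields omitted when `NA`.
#'
#' @param corpus a [tweet_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(corpus, path) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  tw <- corpus$tweets
  lines <- vapply(seq_len(nrow(tw)), function(i) {
    rec <- list(
      id = tw$id[i], user = tw$user[i], text = tw$text[i],
      timestamp_utc = format(tw$timestamp_utc[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    )
    if (!is.na(tw$city[i])) rec$city <- tw$city[i]
    if (!is.na(tw$lat[i])) rec$lat <- tw$lat[i]
    if (!is.na(tw$lon[i])) rec$lon <- tw$lon[i]
    if (!is.na(tw$label[i])) rec$label <- tw$label[i]
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
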