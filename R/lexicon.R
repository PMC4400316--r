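#' Construct a sentiment lexicon
#'
#' A lexicon maps terms to signed integer weights in \[-5, 5\] (the AFINN
#' dialect: negative weights for negative affect), plus emoticon weights and a
#' set of negator terms/contractions used by the negation-reversal rule.
#' Zero weights are rejected, and negators may not carry weights.
#'
#' @param weights named integer vector, term -> weight in -5..5, no zeros.
#' @param emoticon_weights named integer vector, emoticon string -> weight.
#' @param negators character vector of negation terms.
#' @return object of class `sentiment_lexicon`.
#' @export
sentiment_lexicon <- function(weights, emoticon_weights = integer(0),
                              negators = default_negators()) {
  weights <- check_weights(weights, "weights")
  emoticon_weights <- check_weights(emoticon_weights, "emoticon_weights")
  negators <- tolower(as.character(negators))
  clash <- intersect(negators, names(weights))
  if (length(clash) > 0L) {
    stop("negators must not carry lexicon weights: ", paste(clash, collapse = ", "))
  }
  structure(list(weights = weights, emoticon_weights = emoticon_weights,
                 negators = negators),
            class = "sentiment_lexicon")
}

check_weights <- function(w, what) {
  if (length(w) == 0L) return(stats::setNames(integer(0), character(0)))
  if (is.null(names(w)) || any(!nzchar(names(w)))) stop(what, " must be named")
  w <- stats::setNames(as.integer(w), names(w))
  if (any(w == 0L, na.rm = TRUE) || anyNA(w)) stop(what, " must be nonzero integers")
  if (any(abs(w) > 5L)) stop(what, " must lie in -5..5")
  w
}

#' @export
print.sentiment_lexicon <- function(x, ...) {
  cat(sprintf("<sentiment_lexicon> %d terms, %d emoticons, %d negators\n",
              length(x$weights), length(x$emoticon_weights), length(x$negators)))
  invisible(x)
}

#' Default negation terms
#'
#' Negators and their common contractions; these reverse a nearby sentiment
#' keyword's contribution to a unit score of opposite sign.
#' @return character vector.
#' @export
default_negators <- function() {
  c("no", "not", "never", "none", "neither", "nor", "cannot", "without",
    "don't", "dont", "can't", "cant", "won't", "wont", "didn't", "didnt",
    "doesn't", "doesnt", "isn't", "isnt", "wasn't", "wasnt", "aren't", "arent",
    "weren't", "werent", "couldn't", "couldnt", "shouldn't", "shouldnt",
    "wouldn't", "wouldnt", "haven't", "havent", "hasn't", "hasnt", "ain't")
}

#' Read a lexicon TSV file
#'
#' The file format is `term<TAB>weight`, one entry per line, weights signed
#' integers in -5..5 (the format used by the AFINN word list and by emoticon
#' supplements).
#'
#' @param path TSV file path.
#' @return named integer vector term -> weight.
#' @export
read_lexicon_tsv <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, quote = "", comment.char = "",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  if (ncol(df) != 2L) stop("lexicon TSV must have exactly 2 columns: ", path)
  stats::setNames(as.integer(df[[2]]), as.character(df[[1]]))
}

#' The packaged sample lexicon
#'
#' Loads the ~130-term AFINN-dialect sample plus the 20-emoticon supplement
#' shipped with the package. This synthetic sample is sufficient for the
#' synthetic-data workflows and tests; a full AFINN-111 file can be loaded
#' with [read_lexicon_tsv()] and passed to [sentiment_lexicon()] instead.
#'
#' @return a [sentiment_lexicon()].
#' @export
default_lexicon <- function() {
  sentiment_lexicon(
    weights = read_lexicon_tsv(system.file("extdata", "afinn_sample.tsv",
                                           package = "painstream")),
    emoticon_weights = read_lexicon_tsv(system.file("extdata", "emoticons.tsv",
                                                    package = "painstream"))
  )
}

#' Default emoticon inventory
#'
#' Emoticon strings recognised by the tokenizer (the names of the packaged
#' emoticon lexicon).
#' @return character vector of emoticon strings.
#' @export
default_emoticons <- function() {
  if (is.null(.painstream_cache$emoticons)) {
    .painstream_cache$emoticons <- names(
      read_lexicon_tsv(system.file("extdata", "emoticons.tsv",
                                   package = "painstream")))
  }
  .painstream_cache$emoticons
}

.painstream_cache <- new.env(parent = emptyenv())
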