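#' Serialize / restore a Naive Bayes model as JSON
#'
#' @param model an [train_nb()] model.
#' @param path output JSON file.
#' @return `path` invisibly for `write_nb_model()`; an `nb_model` for
#'   `read_nb_model()`.
#' @export
write_nb_model <- function(model, path) {
  stopifnot(inherits(model, "nb_model"))
  jsonlite::write_json(list(
    prior_positive = model$prior_positive,
    features = model$features,
    lik_positive = unname(model$lik_positive),
    lik_negative = unname(model$lik_negative),
    k = model$k
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nb_model
#' @export
read_nb_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    prior_positive = raw$prior_positive,
    features = raw$features,
    lik_positive = stats::setNames(raw$lik_positive, raw$features),
    lik_negative = stats::setNames(raw$lik_negative, raw$features),
    k = as.integer(raw$k)
  ), class = "nb_model")
}
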