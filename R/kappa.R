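#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement from the raters' contingency table:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' expected-by-chance agreement `p_e` from the marginal rating frequencies.
#' When both raters are constant and identical (`p_o = p_e = 1`) kappa is 1 by
#' convention; a single constant rater against a varying one yields 0.
#'
#' @param ratings_a,ratings_b equal-length vectors of categorical ratings.
#' @return list of class `agreement_result`: `kappa`, `p_o`, `p_e`,
#'   `n_raters = 2`, `method = "cohen"`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating vectors must have equal length")
  }
  if (length(ratings_a) == 0L) stop("ratings must be nonempty")
  levels <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = levels)
  b <- factor(as.character(ratings_b), levels = levels)
  tab <- table(a, b) / length(a)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  kappa <- if (p_e >= 1) {
    if (p_o >= 1) 1 else 0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, n_raters = 2L,
                 method = "cohen"),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> %s: kappa = %.3f (p_o = %.3f, p_e = %.3f, %d raters)\n",
              x$method, x$kappa, x$p_o, x$p_e, x$n_raters))
  invisible(x)
}

#' Multi-rater agreement: mean pairwise Cohen's kappa and Fleiss' kappa
#'
#' Reported agreement for three or more raters is ambiguous between the two
#' common generalizations of Cohen's kappa, so both are returned labeled: the
#' mean of all pairwise Cohen's kappas, and Fleiss' kappa over the item-level
#' category counts.
#'
#' @param ratings matrix (or data frame) with one row per rater and one
#'   column per item.
#' @return list with elements `cohen_pairwise_mean` and `fleiss`, each an
#'   `agreement_result`.
#' @export
multi_rater_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  n_raters <- nrow(ratings)
  if (is.null(n_raters) || n_raters < 2L) stop("need at least 2 raters")
  n_items <- ncol(ratings)
  pairs <- utils::combn(n_raters, 2L)
  pairwise <- vapply(seq_len(ncol(pairs)), function(j) {
    cohens_kappa(ratings[pairs[1L, j], ], ratings[pairs[2L, j], ])$kappa
  }, numeric(1))
  levels <- sort(unique(as.character(ratings)))
  counts <- t(apply(ratings, 2L, function(col) {
    table(factor(as.character(col), levels = levels))
  }))
  if (length(levels) == 1L) counts <- matrix(counts, nrow = n_items)
  p_i <- (rowSums(counts^2) - n_raters) / (n_raters * (n_raters - 1))
  p_o <- mean(p_i)
  p_j <- colSums(counts) / (n_items * n_raters)
  p_e <- sum(p_j^2)
  fleiss <- if (p_e >= 1) {
    if (p_o >= 1) 1 else 0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  list(
    cohen_pairwise_mean = structure(
      list(kappa = mean(pairwise), p_o = NA_real_, p_e = NA_real_,
           n_raters = n_raters, method = "cohen_pairwise_mean"),
      class = "agreement_result"),
    fleiss = structure(
      list(kappa = fleiss, p_o = p_o, p_e = p_e, n_raters = n_raters,
           method = "fleiss"),
      class = "agreement_result")
  )
}
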